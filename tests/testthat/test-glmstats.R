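# outcome tables simulated from known logistic truths
simulate_outcome_table <- function(n, beta = c(S = 0, W = 0, M = 0,
                                               age = 0, gender = 0),
                                   intercept = 0, seed = 1) {
  set.seed(seed)
  tab <- data.frame(S = sample(c(FALSE, TRUE), n, TRUE),
                    W = sample(c(FALSE, TRUE), n, TRUE),
                    M = sample(c(FALSE, TRUE), n, TRUE),
                    age = stats::rnorm(n, 23, 4),
                    gender = sample(0:1, n, TRUE))
  eta <- intercept + beta[["S"]] * tab$S + beta[["W"]] * tab$W +
    beta[["M"]] * tab$M + beta[["age"]] * (tab$age - median(tab$age)) +
    beta[["gender"]] * tab$gender
  tab$chose_shortest <- stats::runif(n) < stats::plogis(eta)
  tab$changed_mind <- stats::runif(n) < 0.1
  tab
}

test_that("the exact binomial test uses the minimum-likelihood convention", {
  # an even split is exactly as expected under chance
  expect_equal(exact_binomial_test(29, 58, 0.5), 1)
  expect_equal(exact_binomial_test(0, 1, 0.5), 1)
  # all successes: only the two extreme outcomes are as unlikely
  expect_equal(exact_binomial_test(58, 58, 0.5), 2 * 0.5^58)

  # independent oracle: direct pmf summation over all outcomes at least as
  # extreme in point probability
  pmf_oracle <- function(k, n, p0) {
    probs <- dbinom(0:n, n, p0)
    sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
  }
  for (case in list(c(10, 40), c(3, 17), c(25, 30), c(0, 12))) {
    expect_equal(exact_binomial_test(case[1], case[2], 0.5),
                 pmf_oracle(case[1], case[2], 0.5), tolerance = 1e-12)
  }
  # symmetry at the even null
  expect_equal(exact_binomial_test(13, 40, 0.5),
               exact_binomial_test(27, 40, 0.5))
  expect_error(exact_binomial_test(5, 3), "counts")
  expect_error(exact_binomial_test(1, 3, 1), "probability")
})

test_that("likelihood-ratio p-values reproduce the chi-square tail", {
  # the two single-degree-of-freedom statistic/p pairs quoted for the
  # age-interaction tests
  expect_equal(round(pchisq(0.07, 1, lower.tail = FALSE), 2), 0.79)
  expect_equal(round(pchisq(0.21, 1, lower.tail = FALSE), 2), 0.65)

  tab <- simulate_outcome_table(400, seed = 2)
  full <- fit_binomial_glm(tab, "chose_shortest", interaction = "age:M")
  red <- fit_binomial_glm(tab, "chose_shortest")
  lrt <- likelihood_ratio_test(full, red)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value,
               pchisq(lrt$statistic, 1, lower.tail = FALSE))
  # identical fits: no evidence, p = 1
  same <- likelihood_ratio_test(red, red)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(likelihood_ratio_test(red, full), "non-nested")
})

test_that("Wald tests are two-sided normal tail probabilities", {
  tab <- simulate_outcome_table(500, beta = c(S = 0, W = -1, M = 0, age = 0,
                                              gender = 0), seed = 3)
  fit <- fit_binomial_glm(tab, "chose_shortest")
  co <- fit$coefficients
  z_w <- co$z[co$term == "W"]
  expect_equal(wald_single_parameter_test(fit, "W"),
               2 * pnorm(-abs(z_w)))
  expect_error(wald_single_parameter_test(fit, "nosuch"), "lookup")
  # z of 1.96 corresponds to p ~= 0.05 by construction of the test
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)
})

test_that("a constant outcome is reported as separation, not as a fit", {
  tab <- simulate_outcome_table(60, seed = 4)
  tab$chose_shortest <- FALSE
  fit <- fit_binomial_glm(tab, "chose_shortest", terms = character(0))
  expect_true(fit$separation)
})

test_that("null effects calibrate: Wald p-values are uniform, |z| < 4", {
  set.seed(11)
  pvals <- replicate(150, {
    tab <- simulate_outcome_table(464, seed = sample.int(1e6, 1))
    wald_single_parameter_test(fit_binomial_glm(tab, "chose_shortest"), "W")
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_gte(mean(abs(stats::qnorm(pvals / 2)) < 4), 0.99)
})

test_that("a known width effect is recovered at the study's sample size", {
  hits <- vapply(1:40, function(s) {
    tab <- simulate_outcome_table(
      464, beta = c(S = 0, W = -1, M = 0, age = 0, gender = 0), seed = s)
    fit <- fit_binomial_glm(tab, "chose_shortest")
    est <- fit$coefficients$estimate[fit$coefficients$term == "W"]
    abs(est - (-1)) <= 0.4
  }, logical(1))
  expect_gte(mean(hits), 0.95 - 0.05)  # 36 of 40
})

test_that("Wald and likelihood-ratio tests agree to first order in n", {
  # hold the signal fixed on the z scale (a local alternative) so the
  # first-order agreement of the two statistics is visible as n grows
  reldiff <- function(n, seed) {
    tab <- simulate_outcome_table(
      n, beta = c(S = 0, W = -8 / sqrt(n), M = 0, age = 0, gender = 0),
      intercept = 0.3, seed = seed)
    full <- fit_binomial_glm(tab, "chose_shortest")
    red <- fit_binomial_glm(tab, "chose_shortest",
                            terms = c("S", "M", "age", "gender"))
    z <- full$coefficients$z[full$coefficients$term == "W"]
    lrt <- likelihood_ratio_test(full, red)
    abs(z^2 - lrt$statistic) / lrt$statistic
  }
  small_n <- mean(vapply(1:6, reldiff, numeric(1), n = 400))
  large_n <- mean(vapply(1:6, reldiff, numeric(1), n = 25600))
  expect_lt(large_n, small_n)
  expect_lt(large_n, 0.01)
})

test_that("outcome proportions equal brute-force counting", {
  tab <- simulate_outcome_table(200, seed = 9)
  p <- outcome_proportions(tab)
  expect_equal(p[["p_shortest"]], sum(tab$chose_shortest) / 200)
  expect_equal(p[["p_change"]], sum(tab$changed_mind) / 200)
  expect_true(all(p >= 0 & p <= 1))
})
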