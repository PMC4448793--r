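test_that("the model family enumerates all 16 component subsets", {
  fam <- enumerate_model_family()
  expect_length(fam, 16)
  tags <- vapply(fam, `[[`, "", "tag")
  expect_equal(length(unique(tags)), 16)
  sizes <- vapply(fam, evacchoice:::spec_size, integer(1))
  expect_equal(unname(table(factor(sizes, levels = 0:4))),
               array(c(1L, 4L, 6L, 4L, 1L)))
  # the full model leads, sizes never increase along the enumeration
  expect_equal(unname(tags[1]), "QFWS")
  expect_true(all(diff(sizes) <= 0))
})

test_that("the linear predictor assembles exactly the included components", {
  row1 <- data.frame(q_adv = 3, f_adv = -1, w_adv = 0.5, s_vis = -1,
                     d_adv = 1.5, jam = 1L)
  all0 <- full_params()
  expect_equal(linear_predictor(row1, all0, model_spec(TRUE, TRUE, TRUE, TRUE)),
               0)
  # a single width term
  expect_equal(linear_predictor(
    data.frame(q_adv = 0, f_adv = 0, w_adv = 0.5, s_vis = 0, d_adv = 0,
               jam = 0L),
    c(p1 = 0, p3 = 1, p8 = 0, p9 = 0, p10 = 0), model_spec(W = TRUE)), 0.5)
  # proximity gate: |d_adv| below p9 contributes nothing
  expect_equal(linear_predictor(
    data.frame(q_adv = 0, f_adv = 0, w_adv = 0, s_vis = 0, d_adv = 1.5,
               jam = 0L),
    c(p1 = 0, p8 = 1, p9 = 2, p10 = 0), model_spec()), 0)
  # excluded components are absent from the parameter space
  expect_error(linear_predictor(row1, c(p1 = 0, p8 = 0, p9 = 0, p10 = 0),
                                model_spec(Q = TRUE)), "p4")
  expect_error(linear_predictor(row1, c(p1 = 0, p4 = 1, p5 = 1, p8 = 0,
                                        p9 = 0, p10 = 0),
                                model_spec(Q = TRUE)), "unknown")
})

test_that("choice probabilities are the logistic of the log-odds", {
  base <- data.frame(q_adv = 0, f_adv = 0, w_adv = 0, s_vis = 0, d_adv = 0,
                     jam = 0L)
  expect_equal(choice_probability(base, full_params(),
                                  model_spec(TRUE, TRUE, TRUE, TRUE)), 0.5)
  expect_equal(choice_probability(base, full_params(p1 = 0.5),
                                  model_spec(TRUE, TRUE, TRUE, TRUE)),
               0.6225, tolerance = 1e-4)
  jammed <- base; jammed$jam <- 1L
  expect_equal(choice_probability(jammed, full_params(p10 = 10),
                                  model_spec(TRUE, TRUE, TRUE, TRUE)),
               0.9999546, tolerance = 1e-7)
})

test_that("the likelihood matches an independent row-by-row oracle", {
  rows <- random_rows(60, seed = 3)
  spec <- model_spec(TRUE, TRUE, TRUE, TRUE)
  params <- full_params(p1 = 0.2, p2 = 0.5, p3 = -1, p4 = 0.3, p6 = 0.8,
                        p8 = 0.4, p9 = 1, p10 = 2)
  # oracle: recompute every row's probability independently and sum the logs
  oracle <- sum(vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    eta <- params[["p1"]] + params[["p2"]] * r$s_vis +
      params[["p3"]] * r$w_adv + params[["p4"]] * r$q_adv +
      params[["p6"]] * r$f_adv +
      params[["p8"]] * r$d_adv * (abs(r$d_adv) >= params[["p9"]]) +
      params[["p10"]] * r$jam
    p_top <- 1 / (1 + exp(-eta))
    log(if (r$choice == "top") p_top else 1 - p_top)
  }, numeric(1)))
  expect_equal(log_likelihood(rows, params, spec), oracle)

  # the precompiled closure agrees with the reference implementation
  ll_fun <- evacchoice:::build_loglik(rows, spec)
  theta <- params[param_names(spec)]
  expect_equal(ll_fun(unname(theta)), oracle)

  # all-zero parameters: every row contributes log(1/2)
  expect_equal(log_likelihood(rows, full_params(), spec),
               nrow(rows) * log(0.5))
  # a single row with P(top) = 0.8
  one <- random_rows(1, seed = 4)
  one[, c("q_adv", "f_adv", "w_adv", "s_vis", "d_adv", "jam")] <- 0
  one$choice <- "top"
  expect_equal(log_likelihood(one, full_params(p1 = qlogis(0.8)), spec),
               log(0.8))
  expect_error(log_likelihood(rows[0, ], full_params(), spec), "empty")
})

test_that("fixing an included coefficient at zero reproduces the sub-model", {
  rows <- random_rows(80, seed = 5)
  shared <- c(p1 = 0.1, p4 = 0.3, p8 = 0.5, p9 = 0.7, p10 = 1.2)
  big <- c(shared, p6 = 0)[c("p1", "p4", "p6", "p8", "p9", "p10")]
  expect_equal(log_likelihood(rows, big, model_spec(Q = TRUE, F = TRUE)),
               log_likelihood(rows, shared, model_spec(Q = TRUE)))
  big2 <- c(shared, p2 = 0, p3 = 0)
  expect_equal(
    log_likelihood(rows, big2, model_spec(Q = TRUE, W = TRUE, S = TRUE)),
    log_likelihood(rows, shared, model_spec(Q = TRUE)))
})

test_that("negating the signed features and p1 swaps the exit labels", {
  rows <- random_rows(50, seed = 6)
  spec <- model_spec(TRUE, TRUE, TRUE, TRUE)
  params <- full_params(p1 = 0.4, p2 = -0.5, p3 = 1, p4 = 0.2, p6 = -0.7,
                        p8 = 0.6, p9 = 1.5, p10 = 3)
  p_top <- choice_probability(rows, params, spec)
  neg <- rows
  for (v in c("q_adv", "f_adv", "w_adv", "s_vis", "d_adv", "jam"))
    neg[[v]] <- -neg[[v]]
  params_neg <- params; params_neg[["p1"]] <- -params[["p1"]]
  expect_equal(choice_probability(neg, params_neg, spec), 1 - p_top)
})

test_that("the generative participant is deterministic and follows its bias", {
  env <- control_env()
  spec <- model_spec()
  push_top <- c(p1 = 10, p8 = 0, p9 = 0, p10 = 0)
  exits <- vapply(1:5, function(s)
    simulate_participant(env, crowd_params(), spec, push_top,
                         seed = s)$trajectory$exit_used, "")
  expect_true(all(exits == "top"))

  s1 <- simulate_participant(env, crowd_params(), spec, push_top, seed = 9)
  s2 <- simulate_participant(env, crowd_params(), spec, push_top, seed = 9)
  expect_identical(s1$trajectory$pos, s2$trajectory$pos)
  expect_identical(s1$trajectory$pref, s2$trajectory$pref)
  expect_identical(s1$history$q, s2$history$q)
})
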