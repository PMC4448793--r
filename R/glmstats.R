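#' Fit a binomial GLM to outcome-level data
#'
#' Logit-link fit (iteratively reweighted least squares via
#' \code{stats::glm}) of a binary per-participant outcome - whether the
#' shortest route was chosen, or whether the participant changed their mind -
#' on the treatment flags and demographics.  Age is centred at the sample
#' median before fitting and gender is coded 0/1 (reference level 0), so the
#' intercept refers to an untreated median-age reference participant.
#' Perfect separation and non-convergence are detected and flagged rather
#' than silently reported.
#'
#' @param table Outcome table: one row per participant with logical columns
#'   \code{S}, \code{W}, \code{M}, numeric \code{age}, 0/1 \code{gender} and
#'   the logical outcome columns.
#' @param outcome \code{"chose_shortest"} or \code{"changed_mind"}.
#' @param terms Character vector of main-effect terms.
#' @param interaction Optional single interaction term such as
#'   \code{"age:M"}, mirroring the one-at-a-time extended models.
#' @return An object of class \code{evac_glm}: the underlying \code{glm}
#'   object plus \code{coefficients} (estimate, se, z, p), \code{logLik},
#'   \code{converged} and \code{separation} flags.
#' @export
fit_binomial_glm <- function(table,
                             outcome = c("chose_shortest", "changed_mind"),
                             terms = c("S", "W", "M", "age", "gender"),
                             interaction = NULL) {
  outcome <- match.arg(outcome)
  need <- unique(c(terms, outcome,
                   unlist(strsplit(interaction %||% character(0), ":"))))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("outcome table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(table)
  df$.y <- as.integer(df[[outcome]])
  if ("age" %in% names(df))
    df$age <- df$age - stats::median(df$age)
  for (tr in intersect(c("S", "W", "M", "gender"), names(df)))
    df[[tr]] <- as.integer(df[[tr]])
  rhs <- paste(c(terms, interaction), collapse = " + ")
  if (!nzchar(rhs)) rhs <- "1"
  form <- stats::as.formula(paste(".y ~", rhs))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  separation <- sep_warned || any(abs(co[, "Estimate"]) > 15) ||
    any(!is.finite(co[, "Std. Error"])) || any(co[, "Std. Error"] > 1e3)
  out <- list(glm = fit,
              coefficients = data.frame(
                term = rownames(co), estimate = co[, "Estimate"],
                se = co[, "Std. Error"], z = co[, "z value"],
                p = co[, "Pr(>|z|)"], row.names = NULL,
                stringsAsFactors = FALSE),
              logLik = as.numeric(stats::logLik(fit)),
              df = length(stats::coef(fit)),
              converged = fit$converged, separation = separation,
              outcome = outcome, terms = c(terms, interaction),
              n = nrow(df))
  class(out) <- "evac_glm"
  out
}

#' @export
print.evac_glm <- function(x, digits = 4, ...) {
  cat(sprintf("Binomial GLM for %s (n = %d)%s%s\n", x$outcome, x$n,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separation) " [SEPARATION SUSPECTED]" else ""))
  print(x$coefficients, digits = digits, row.names = FALSE)
  cat(sprintf("log-likelihood: %.*f\n", digits, x$logLik))
  invisible(x)
}

#' @export
coef.evac_glm <- function(object, ...) stats::coef(object$glm)

#' @export
logLik.evac_glm <- function(object, ...) stats::logLik(object$glm)

#' Wald single-parameter test
#'
#' Two-sided normal-approximation p-value for one coefficient of a fitted
#' binomial GLM: \code{p = 2 * pnorm(-|estimate / se|)}.
#'
#' @param fit An \code{evac_glm}.
#' @param term Coefficient name as it appears in the fit.
#' @return The p-value.
#' @export
wald_single_parameter_test <- function(fit, term) {
  stopifnot(inherits(fit, "evac_glm"))
  co <- fit$coefficients
  i <- match(term, co$term)
  if (is.na(i)) stop("lookup error: term '", term, "' not in fit (have: ",
                     paste(co$term, collapse = ", "), ")", call. = FALSE)
  2 * stats::pnorm(-abs(co$estimate[i] / co$se[i]))
}

#' Likelihood-ratio test between nested binomial GLMs
#'
#' \code{statistic = 2 * (logLik(full) - logLik(reduced))}, referred to the
#' chi-square upper tail with degrees of freedom equal to the difference in
#' parameter counts.
#'
#' @param fit_full,fit_reduced \code{evac_glm} fits of nested models on the
#'   same data (same outcome, same number of rows; the reduced model's terms
#'   must be a subset of the full model's).
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "evac_glm"), inherits(fit_reduced, "evac_glm"))
  if (fit_full$n != fit_reduced$n ||
      !identical(fit_full$outcome, fit_reduced$outcome))
    stop("non-nested models: fits use different data or outcomes",
         call. = FALSE)
  if (!all(fit_reduced$terms %in% fit_full$terms))
    stop("non-nested models: reduced terms are not a subset of full terms",
         call. = FALSE)
  df <- fit_full$df - fit_reduced$df
  if (df < 0) stop("non-nested models: reduced model has more parameters",
                   call. = FALSE)
  stat <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  # identical models compare trivially: no evidence against the reduced fit
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Exact two-sided binomial test
#'
#' Minimum-likelihood two-sided p-value: the sum of the probabilities of all
#' outcomes whose point mass does not exceed that of the observed count
#' (the convention implemented by \code{stats::binom.test}, which this
#' function wraps).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability (strictly inside (0, 1)).
#' @return The p-value.
#' @export
exact_binomial_test <- function(k, n, p0 = 0.5) {
  if (!is.numeric(k) || !is.numeric(n) || k < 0 || n < 1 || k > n ||
      k != round(k) || n != round(n))
    stop("invalid counts: need integer 0 <= k <= n", call. = FALSE)
  if (p0 <= 0 || p0 >= 1)
    stop("invalid null probability: need 0 < p0 < 1", call. = FALSE)
  stats::binom.test(round(k), round(n), p = p0,
                    alternative = "two.sided")$p.value
}

#' Outcome proportions with brute-force counting
#'
#' P(shortest route) and P(change) over an outcome table or a subset of it.
#'
#' @param table Outcome table (see \code{\link{fit_binomial_glm}}).
#' @return Named numeric vector \code{p_shortest}, \code{p_change}.
#' @export
outcome_proportions <- function(table) {
  c(p_shortest = mean(table$chose_shortest),
    p_change = mean(table$changed_mind))
}
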