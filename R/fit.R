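#' Fit one exit-choice model by tempered Bayesian estimation
#'
#' The central fitting function: given a decision dataset (one feature row
#' per sampled time point, with the displayed choice) and a model
#' specification, estimates the model's log marginal likelihood by
#' stepping-stone sampling and retains a posterior sample at temperature 1.
#' The returned object supports the usual modelling verbs: \code{print},
#' \code{summary}, \code{coef} (posterior means), \code{logLik} (at the
#' posterior mean), \code{predict} (choice probabilities for new feature
#' rows) and \code{simulate} (choice draws).
#'
#' @param data Feature data frame with columns \code{q_adv}, \code{f_adv},
#'   \code{w_adv}, \code{s_vis}, \code{d_adv}, \code{jam}, \code{choice}.
#' @param spec An \code{\link{model_spec}}; the full model by default.
#' @param prior A \code{\link{prior_spec}}; \code{\link{default_prior}} of
#'   the spec by default.
#' @param settings \code{\link{ss_settings}} controlling the estimator.
#' @param seed Integer seed.
#' @return An object of class \code{exit_choice_fit}.
#' @examples
#' \donttest{
#' env <- build_environment(evac_config())
#' sim <- simulate_participant(env, crowd_params(), model_spec(Q = TRUE),
#'                             c(p1 = 0, p4 = 0.4, p8 = 0, p9 = 0, p10 = 0),
#'                             seed = 1)
#' rows <- sample_decision_points(sim$trajectory, sim$history)
#' fit <- exit_choice_fit(rows, model_spec(Q = TRUE),
#'                        settings = ss_settings(n_rungs = 8, n_iter = 120,
#'                                               n_posterior = 200))
#' coef(fit)
#' }
#' @export
exit_choice_fit <- function(data, spec = model_spec(TRUE, TRUE, TRUE, TRUE),
                            prior = NULL, settings = ss_settings(),
                            seed = 1L) {
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(prior)) prior <- default_prior(spec)
  if (!setequal(prior$names, param_names(spec)))
    stop("prior does not cover the spec's parameters", call. = FALSE)
  loglik <- build_loglik(data, spec)
  ev <- log_marginal_likelihood(loglik, prior, settings, seed = seed,
                                return_chain = TRUE)
  samples <- ev$posterior$samples
  fit <- list(spec = spec, prior = prior, settings = settings, seed = seed,
              n_obs = nrow(data), log_marginal = ev$log_ml,
              samples = samples, sample_ll = ev$posterior$ll,
              coef = colMeans(samples), warnings = ev$warnings,
              data_columns = names(data))
  class(fit) <- "exit_choice_fit"
  fit
}

#' @export
print.exit_choice_fit <- function(x, digits = 3, ...) {
  cat("Exit-choice model fit [", x$spec$tag, "]\n", sep = "")
  cat(sprintf("  %d decision rows; log marginal likelihood = %.*f\n",
              x$n_obs, digits, x$log_marginal))
  cat("  posterior means:\n")
  print(round(x$coef, digits))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' @export
coef.exit_choice_fit <- function(object, ...) object$coef

#' @export
logLik.exit_choice_fit <- function(object, ...) {
  structure(object$sample_ll[which.max(object$sample_ll)],
            df = length(object$coef), nobs = object$n_obs,
            class = "logLik")
}

#' Posterior summary of a fitted exit-choice model
#'
#' Equal-tailed credible intervals for every parameter; the boundary
#' parameter p9 (a non-negative threshold) gets a one-sided interval from 0.
#'
#' @param object An \code{exit_choice_fit}.
#' @param level Credible level.
#' @param ... Unused.
#' @return An object of class \code{summary.exit_choice_fit} whose
#'   \code{table} holds mean, sd and interval bounds per parameter.
#' @export
summary.exit_choice_fit <- function(object, level = 0.95, ...) {
  s <- object$samples
  alpha <- 1 - level
  tab <- data.frame(
    mean = colMeans(s),
    sd = apply(s, 2L, stats::sd),
    lower = apply(s, 2L, stats::quantile, probs = alpha / 2),
    upper = apply(s, 2L, stats::quantile, probs = 1 - alpha / 2))
  if ("p9" %in% rownames(tab)) {
    tab["p9", "lower"] <- 0
    tab["p9", "upper"] <- stats::quantile(s[, "p9"], probs = level)
  }
  structure(list(table = tab, spec = object$spec, level = level,
                 log_marginal = object$log_marginal, n_obs = object$n_obs),
            class = "summary.exit_choice_fit")
}

#' @export
print.summary.exit_choice_fit <- function(x, digits = 3, ...) {
  cat("Exit-choice model [", x$spec$tag, "], ", x$n_obs, " rows, log ML = ",
      round(x$log_marginal, digits), "\n", sep = "")
  cat(sprintf("Posterior summary (%.0f%% credible intervals):\n",
              100 * x$level))
  print(round(x$table, digits))
  invisible(x)
}

#' @export
predict.exit_choice_fit <- function(object, newdata,
                                    type = c("prob", "link"), ...) {
  type <- match.arg(type)
  eta <- linear_predictor(newdata, object$coef, object$spec)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
simulate.exit_choice_fit <- function(object, nsim = 1, seed = NULL,
                                     newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata, type = "prob")
  out <- replicate(nsim, ifelse(stats::runif(length(pr)) < pr,
                                "top", "bottom"), simplify = FALSE)
  if (nsim == 1L) out[[1L]] else out
}

#' Bayesian selection across the 16-model family
#'
#' Runs replicated stepping-stone evidence estimation for every member of
#' the model family on one data stratum and ranks the results in the
#' four-block layout (see \code{\link{rank_models}}).
#'
#' @param data Feature data frame (one stratum: fit the treatment-M and
#'   non-M data separately).
#' @param n_rep Evidence replicates per model (default 5).
#' @param base_seed Integer; model m, replicate r runs on seed
#'   \code{base_seed + 1000 * m + r}.
#' @param settings \code{\link{ss_settings}} for the estimator.
#' @param room_height Metres; bounds the p9 prior.
#' @param stratum Label stored on every estimate.
#' @param verbose Print one line per model as it finishes?
#' @return An object of class \code{exit_model_selection} containing the
#'   \code{ranking} (\code{\link{rank_models}} output), all estimates and
#'   the call parameters.
#' @export
exit_model_selection <- function(data, n_rep = 5, base_seed = 1L,
                                 settings = ss_settings(),
                                 room_height = 10,
                                 stratum = NA_character_, verbose = FALSE) {
  family <- enumerate_model_family()
  estimates <- vector("list", length(family))
  names(estimates) <- names(family)
  for (m in seq_along(family)) {
    spec <- family[[m]]
    prior <- default_prior(spec, room_height = room_height)
    loglik <- build_loglik(data, spec)
    estimates[[m]] <- replicate_evidence(
      loglik, prior, settings, n_rep = n_rep,
      base_seed = base_seed + 1000L * m, tag = spec$tag, stratum = stratum)
    if (verbose)
      message(sprintf("  %s: %.2f (sd %.2f)", spec$tag,
                      estimates[[m]]$mean, estimates[[m]]$sd))
  }
  ranking <- rank_models(estimates, family)
  structure(list(ranking = ranking, estimates = estimates, n_rep = n_rep,
                 base_seed = base_seed, settings = settings,
                 stratum = stratum, n_obs = nrow(data)),
            class = "exit_model_selection")
}

#' @export
print.exit_model_selection <- function(x, ...) {
  cat(sprintf(
    "Exit-choice model selection: 16 models, %d replicates, %d rows%s\n",
    x$n_rep, x$n_obs,
    if (!is.na(x$stratum)) paste0(" (stratum ", x$stratum, ")") else ""))
  print(x$ranking, ...)
  invisible(x)
}

#' @export
plot.exit_model_selection <- function(x, ...) plot(x$ranking, ...)

#' @export
as.data.frame.exit_model_selection <- function(x, ...) x$ranking$table
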