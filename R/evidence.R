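#' Bounded-uniform prior specification
#'
#' Independent uniform densities, one per parameter, defined by lower and
#' upper bounds in the parameter's own physical units.  The prior integrates
#' to one over the model's parameter space, so the marginal likelihood
#' carries the usual dimensionality penalty: every added parameter dilutes
#' the prior mass available to any particular value.
#'
#' @param lower,upper Named numeric vectors with identical names;
#'   \code{lower < upper} elementwise.
#' @return An object of class \code{prior_spec}.
#' @export
prior_spec <- function(lower, upper) {
  stopifnot(length(lower) == length(upper),
            !is.null(names(lower)), identical(names(lower), names(upper)),
            all(is.finite(lower)), all(is.finite(upper)))
  if (any(lower >= upper))
    stop("prior error: 'lower' must be strictly below 'upper' for every ",
         "parameter", call. = FALSE)
  structure(list(lower = lower, upper = upper,
                 names = names(lower)), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Independent uniform priors:\n")
  for (nm in x$names)
    cat(sprintf("  %-4s ~ U(%g, %g)\n", nm, x$lower[[nm]], x$upper[[nm]]))
  invisible(x)
}

#' Default priors for an exit-choice model
#'
#' Bounds are set on the physical feature scales (persons, metres,
#' persons/second), so they are comparable across cohorts: dimensionless
#' effects (constant, shorter-route, jam) and the per-metre width effect get
#' wide \eqn{[-10, 10]} bounds; the per-person queue effect \eqn{[-2, 2]};
#' the per-(person/s) flow effect and the per-metre proximity effect
#' \eqn{[-5, 5]}; and the distance threshold p9 is uniform on
#' \eqn{[0, \mathrm{room\_height}]}.
#'
#' @param spec An \code{exit_model_spec}.
#' @param room_height Room height in metres (upper bound for p9).
#' @return A \code{prior_spec} covering exactly \code{param_names(spec)}.
#' @export
default_prior <- function(spec, room_height = 10) {
  lo <- c(p1 = -10, p2 = -10, p3 = -10, p4 = -2, p6 = -5,
          p8 = -5, p9 = 0, p10 = -10)
  hi <- c(p1 = 10, p2 = 10, p3 = 10, p4 = 2, p6 = 5,
          p8 = 5, p9 = room_height, p10 = 10)
  nms <- param_names(spec)
  prior_spec(lo[nms], hi[nms])
}

#' Stepping-stone estimator settings
#'
#' @param n_rungs Number of temperature rungs between prior and posterior.
#' @param n_iter MCMC iterations per rung.
#' @param burn_frac Fraction of each rung's chain discarded as burn-in
#'   (during which the proposal scale adapts towards ~25\% acceptance).
#' @param t_min Smallest positive temperature of the geometric ladder.
#' @param n_posterior Extra iterations at temperature 1 retained as posterior
#'   samples by \code{\link{exit_choice_fit}}.
#' @return A list of class \code{ss_settings}.
#' @export
ss_settings <- function(n_rungs = 32, n_iter = 500, burn_frac = 0.3,
                        t_min = 1e-5, n_posterior = 1500) {
  stopifnot(n_rungs >= 2, n_iter >= 20, burn_frac > 0, burn_frac < 1,
            t_min > 0, t_min < 1)
  structure(list(n_rungs = as.integer(n_rungs), n_iter = as.integer(n_iter),
                 burn_frac = burn_frac, t_min = t_min,
                 n_posterior = as.integer(n_posterior)),
            class = "ss_settings")
}

# geometric temperature ladder: 0, t_min, ..., 1
temperature_ladder <- function(settings) {
  K <- settings$n_rungs
  c(0, settings$t_min^(1 - (seq_len(K) - 1) / (K - 1)))
}

# Random-walk Metropolis on the power posterior prior * L^t.  Uniform priors
# make the prior log-density constant inside the box, so only the tempered
# likelihood and the bounds matter.  Proposals are Gaussian with a
# per-parameter scale vector `psd` (carried from rung to rung, where the
# tempered posteriors change slowly) times a global multiplier that adapts
# towards ~25% acceptance during burn-in and is frozen afterwards.  Returns
# the kept chain, its log-likelihood values, the final state, an updated
# per-parameter scale for the next rung, and the acceptance rate.
mcmc_rung <- function(loglik, prior, t, init, init_ll, settings, psd,
                      mult = 1) {
  p <- length(prior$lower)
  rng <- prior$upper - prior$lower
  n_iter <- settings$n_iter
  n_burn <- max(1L, floor(settings$burn_frac * n_iter))
  keep <- matrix(NA_real_, n_iter - n_burn, p)
  keep_ll <- numeric(n_iter - n_burn)
  theta <- init
  ll <- init_ll
  n_acc <- 0L
  for (i in seq_len(n_iter)) {
    prop <- theta + stats::rnorm(p) * (mult * psd)
    if (all(prop >= prior$lower) && all(prop <= prior$upper)) {
      ll_prop <- loglik(prop)
      if (is.finite(ll_prop) &&
          log(stats::runif(1)) < t * (ll_prop - ll)) {
        theta <- prop
        ll <- ll_prop
        n_acc <- n_acc + 1L
      }
    }
    if (i <= n_burn) {
      # Robbins-Monro drift towards ~25% acceptance, frozen afterwards
      acc <- n_acc / i
      mult <- exp(log(mult) + (acc - 0.25) / sqrt(i))
      mult <- min(max(mult, 1e-3), 10)
    } else {
      keep[i - n_burn, ] <- theta
      keep_ll[i - n_burn] <- ll
    }
  }
  # per-parameter spread of this rung's chain seeds the next rung's proposal
  spread <- apply(keep, 2L, stats::sd)
  psd_next <- pmax(2.4 / sqrt(p) * spread, 1e-4 * rng)
  list(samples = keep, ll = keep_ll, theta = theta, ll_final = ll,
       psd = psd_next, mult = mult, acc_rate = n_acc / n_iter)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Estimates \eqn{\log \int L(D \mid \theta)\, \pi(\theta)\, d\theta} by
#' stepping-stone sampling over a geometric temperature ladder: for each
#' consecutive pair of temperatures \eqn{t_k < t_{k+1}}, samples are drawn
#' from the power posterior \eqn{\pi(\theta) L^{t_k}} (i.i.d. from the prior
#' at \eqn{t_0 = 0}, random-walk Metropolis with burn-in adaptation at the
#' warmer rungs, each rung warm-started from the previous one) and the ratio
#' of normalising constants is estimated as the importance-sampling mean of
#' \eqn{L^{t_{k+1} - t_k}}.  The sum of the log ratios is the log evidence.
#' Because the prior integrates to one over the model's own parameter space,
#' models with more parameters are penalised exactly as the marginal
#' likelihood prescribes.
#'
#' @param loglik Function mapping a parameter vector (ordered as the prior's
#'   names) to a log-likelihood.
#' @param prior A \code{\link{prior_spec}}.
#' @param settings An \code{\link{ss_settings}} list.
#' @param seed Integer seed; identical inputs and seed give identical
#'   estimates.
#' @param return_chain Also return the temperature-1 posterior chain?
#' @return A list of class \code{ss_evidence}: \code{log_ml}, per-rung
#'   acceptance rates, the ladder, the seed, convergence \code{warnings}
#'   (a character vector, empty when diagnostics pass), and optionally
#'   \code{posterior} (samples and log-likelihood values at temperature 1).
#' @export
log_marginal_likelihood <- function(loglik, prior, settings = ss_settings(),
                                    seed = 1L, return_chain = FALSE) {
  set.seed(seed)
  ladder <- temperature_ladder(settings)
  K <- length(ladder)
  p <- length(prior$lower)
  rng <- prior$upper - prior$lower
  n_keep <- settings$n_iter - max(1L, floor(settings$burn_frac *
                                              settings$n_iter))
  log_ratios <- numeric(K - 1L)
  acc <- rep(NA_real_, K - 1L)
  warnings <- character(0)

  # rung at t = 0: i.i.d. draws from the uniform prior
  prior_draws <- matrix(stats::runif(n_keep * p), n_keep, p)
  prior_draws <- sweep(sweep(prior_draws, 2L, rng, "*"), 2L,
                       prior$lower, "+")
  ll0 <- apply(prior_draws, 1L, loglik)
  log_ratios[1L] <- log_mean_exp((ladder[2L] - ladder[1L]) * ll0)

  # warm start the chain from the best prior draw; proposal scales start at
  # the prior spread and then track each rung's chain
  best <- which.max(ll0)
  theta <- prior_draws[best, ]
  ll <- ll0[best]
  psd <- 2.4 / sqrt(p) * rng / sqrt(12)
  mult <- 1
  for (k in 2L:(K - 1L)) {
    out <- mcmc_rung(loglik, prior, ladder[k], theta, ll, settings, psd,
                     mult)
    log_ratios[k] <- log_mean_exp((ladder[k + 1L] - ladder[k]) * out$ll)
    theta <- out$theta
    ll <- out$ll_final
    psd <- out$psd
    mult <- out$mult
    acc[k] <- out$acc_rate
  }
  hot <- acc[-1L][is.finite(acc[-1L])]
  if (length(hot) && (mean(hot) < 0.05 || mean(hot) > 0.95))
    warnings <- c(warnings, sprintf(
      "poor MCMC mixing: mean acceptance rate %.2f across rungs", mean(hot)))
  posterior <- NULL
  if (return_chain) {
    post_settings <- settings
    post_settings$n_iter <- settings$n_posterior
    out <- mcmc_rung(loglik, prior, 1, theta, ll, post_settings, psd, mult)
    posterior <- list(samples = out$samples, ll = out$ll,
                      acc_rate = out$acc_rate)
    colnames(posterior$samples) <- prior$names
  }
  structure(list(log_ml = sum(log_ratios), log_ratios = log_ratios,
                 ladder = ladder, acc_rates = acc, seed = seed,
                 warnings = warnings, posterior = posterior),
            class = "ss_evidence")
}

#' @export
print.ss_evidence <- function(x, ...) {
  cat(sprintf("Stepping-stone evidence: log ML = %.3f (%d rungs, seed %d)\n",
              x$log_ml, length(x$ladder) - 1L, x$seed))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Replicated evidence estimation
#'
#' Runs \code{n_rep} independent-seed stepping-stone estimates (seeds
#' \code{base_seed + 1:n_rep}) and summarises them by their mean and
#' standard deviation, the replicate spread being the Monte-Carlo
#' uncertainty reported alongside every model's evidence.
#'
#' @inheritParams log_marginal_likelihood
#' @param n_rep Number of replicates (>= 2; 5 by default).
#' @param base_seed Integer; replicate r uses seed \code{base_seed + r}.
#' @param tag Optional label (model tag) stored on the estimate.
#' @param stratum Optional stratum label (\code{"M"} / \code{"nonM"}).
#' @return An object of class \code{evidence_estimate}: \code{replicates},
#'   \code{mean}, \code{sd}, \code{seeds}, \code{tag}, \code{stratum}.
#' @export
replicate_evidence <- function(loglik, prior, settings = ss_settings(),
                               n_rep = 5, base_seed = 1L, tag = NULL,
                               stratum = NA_character_) {
  stopifnot(n_rep >= 2)
  seeds <- base_seed + seq_len(n_rep)
  reps <- vapply(seeds, function(s)
    log_marginal_likelihood(loglik, prior, settings, seed = s)$log_ml,
    numeric(1))
  structure(list(replicates = reps, mean = mean(reps), sd = stats::sd(reps),
                 seeds = seeds, tag = tag, stratum = stratum),
            class = "evidence_estimate")
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat(sprintf("Evidence estimate%s: mean log ML = %.3f (sd %.3f, %d reps)\n",
              if (!is.null(x$tag)) paste0(" [", x$tag, "]") else "",
              x$mean, x$sd, length(x$replicates)))
  invisible(x)
}

#' Twice the log Bayes factor between two models
#'
#' \code{2 * (mean_i - mean_j)} on the natural-log scale, the quantity the
#' published evidence bands are expressed in.  Positive values favour the
#' first model.
#'
#' @param est_i,est_j \code{evidence_estimate} objects for the same data
#'   stratum.
#' @return A single number; antisymmetric in its arguments.
#' @export
two_log_bayes_factor <- function(est_i, est_j) {
  stopifnot(inherits(est_i, "evidence_estimate"),
            inherits(est_j, "evidence_estimate"))
  if (!identical(est_i$stratum, est_j$stratum))
    stop("comparison error: estimates come from different data strata (",
         est_i$stratum, " vs ", est_j$stratum, ")", call. = FALSE)
  2 * (est_i$mean - est_j$mean)
}

#' Evidence category of a 2 log(BF) value
#'
#' The conventional interpretation scale: |2log(BF)| of 0-6 is weak to
#' positive evidence, 6-10 strong, above 10 decisive.  Boundary values (6
#' and 10 exactly) fall in the lower band; the sign of the input indicates
#' direction and is preserved in the \code{"direction"} attribute.
#'
#' @param two_log_bf Finite numeric vector.
#' @return Character vector in \code{{"weak-to-positive", "strong",
#'   "decisive"}} with a \code{direction} attribute (+1, -1 or 0 per value).
#' @export
evidence_category <- function(two_log_bf) {
  stopifnot(all(is.finite(two_log_bf)))
  a <- abs(two_log_bf)
  out <- ifelse(a > 10, "decisive",
                ifelse(a > 6, "strong", "weak-to-positive"))
  attr(out, "direction") <- sign(two_log_bf)
  out
}

# block membership of a spec: the Q/F inclusion pattern, the unit of the
# left-to-right ranking layout
spec_block <- function(spec) {
  if (spec$include_Q && spec$include_F) "Q&F"
  else if (spec$include_Q) "Q-only"
  else if (spec$include_F) "F-only"
  else "neither"
}

block_levels <- c("Q&F", "Q-only", "F-only", "neither")

# canonical within-block order: both W and S, W only, S only, neither
spec_order_key <- function(spec) {
  c(match(spec_block(spec), block_levels),
    2L - spec$include_W, 2L - spec$include_S)
}

#' Rank the 16-model family by evidence
#'
#' Lays the family out in the four Q/F blocks (both Q and F, Q only, F only,
#' neither), ranks models by mean log marginal likelihood, and computes the
#' adjacent-block comparisons: for each pair of neighbouring blocks, twice
#' the log Bayes factor between the \emph{lowest}-evidence model of the left
#' (better) block and the \emph{highest}-evidence model of the block to its
#' right - the conservative comparison under which a positive value means
#' even the worst model of the left block beats the best model of the right
#' block.
#'
#' @param estimates A list of 16 \code{evidence_estimate} objects, one per
#'   family member, each carrying its model tag; input order is irrelevant.
#' @param specs Optional list of the matching \code{exit_model_spec}s; by
#'   default recovered from the tags.
#' @return An object of class \code{model_ranking}: \code{table} (tag,
#'   block, mean, sd, rank, in block order), \code{block_comparisons}
#'   (left block, right block, 2log(BF), category) and the estimates.
#' @export
rank_models <- function(estimates, specs = NULL) {
  tags <- vapply(estimates, function(e) e$tag %||% NA_character_, "")
  if (anyNA(tags)) stop("completeness error: every estimate needs its tag",
                        call. = FALSE)
  family <- enumerate_model_family()
  if (!setequal(tags, names(family)) || length(tags) != 16L)
    stop("completeness error: need exactly one estimate per family member; ",
         "missing: ", paste(setdiff(names(family), tags), collapse = ", "),
         call. = FALSE)
  if (is.null(specs)) specs <- family[tags]
  ord <- order(do.call(rbind, lapply(specs, spec_order_key))[, 1L] * 100 +
               do.call(rbind, lapply(specs, spec_order_key))[, 2L] * 10 +
               do.call(rbind, lapply(specs, spec_order_key))[, 3L])
  estimates <- estimates[ord]
  specs <- specs[ord]
  tab <- data.frame(
    tag = vapply(estimates, `[[`, "", "tag"),
    block = vapply(specs, spec_block, ""),
    mean = vapply(estimates, `[[`, 0, "mean"),
    sd = vapply(estimates, `[[`, 0, "sd"),
    stringsAsFactors = FALSE)
  tab$rank <- rank(-tab$mean, ties.method = "first")
  comps <- data.frame(left = character(0), right = character(0),
                      two_log_bf = numeric(0), category = character(0),
                      stringsAsFactors = FALSE)
  for (b in seq_len(length(block_levels) - 1L)) {
    lhs <- tab[tab$block == block_levels[b], ]
    rhs <- tab[tab$block == block_levels[b + 1L], ]
    bf <- 2 * (min(lhs$mean) - max(rhs$mean))
    comps <- rbind(comps, data.frame(
      left = block_levels[b], right = block_levels[b + 1L],
      two_log_bf = bf, category = as.character(evidence_category(bf)),
      stringsAsFactors = FALSE))
  }
  structure(list(table = tab, block_comparisons = comps,
                 estimates = estimates),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, digits = 3, ...) {
  cat("Model ranking by mean log marginal likelihood\n")
  print(x$table, digits = digits, row.names = FALSE)
  cat("\nAdjacent-block comparisons (worst of left vs best of right):\n")
  print(x$block_comparisons, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
plot.model_ranking <- function(x, ...) {
  tab <- x$table
  n <- nrow(tab)
  blocks <- factor(tab$block, levels = block_levels)
  shade <- as.integer(blocks) %% 2L == 0L
  ylim <- range(tab$mean - tab$sd, tab$mean + tab$sd)
  graphics::plot(seq_len(n), tab$mean, xaxt = "n", xlab = "",
                 ylab = "log marginal likelihood", ylim = ylim,
                 type = "n", ...)
  usr <- graphics::par("usr")
  for (b in which(shade[!duplicated(blocks)])) {
    idx <- which(as.integer(blocks) == b)
    graphics::rect(min(idx) - 0.5, usr[3], max(idx) + 0.5, usr[4],
                   col = "grey92", border = NA)
  }
  graphics::points(seq_len(n), tab$mean, pch = 19)
  graphics::arrows(seq_len(n), tab$mean - tab$sd, seq_len(n),
                   tab$mean + tab$sd, angle = 90, code = 3, length = 0.03)
  graphics::axis(1, at = seq_len(n), labels = tab$tag, las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
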