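#' Design of a synthetic cohort
#'
#' Describes the full factorial experiment the generator emulates: the eight
#' treatment conditions (control, S, W, M and all their combinations) with a
#' fixed number of participants per condition, demographics drawn from a
#' right-skewed age distribution (a shifted log-normal concentrated near 23
#' years with about 5\% of participants above 35) and a balanced gender
#' code, and participant choices generated from a known member of the
#' choice-model family.  The treatment-M stratum may use its own generating
#' parameter vector; by default its proximity and jam effects are doubled,
#' which makes decisions stickier and reproduces the qualitative reduction
#' in the change-of-mind rate under time pressure.
#'
#' @param n_per_condition Participants per condition (58 by default, for a
#'   464-participant cohort).
#' @param gen_spec Generating \code{\link{model_spec}} (queue length + flow
#'   by default).
#' @param gen_params Generating parameters for the non-M stratum.
#' @param gen_params_M Generating parameters for the M stratum.
#' @param age_median Median age in years of the shifted log-normal.
#' @param age_p35 Target proportion of participants older than 35.
#' @param gender_balance Proportion with gender code 1.
#' @param interval Preference sampling interval, seconds.
#' @param flow_window Flow feature window, seconds.
#' @param crowd \code{\link{crowd_params}} for every scripted crowd.
#' @param width_ratio Top/bottom exit width ratio under treatment W.
#' @param seed Integer master seed; everything (ages, genders, per-participant
#'   crowd seeds, choice draws) derives from it.
#' @return An object of class \code{cohort_design}.
#' @export
cohort_design <- function(n_per_condition = 58,
                          gen_spec = model_spec(Q = TRUE, F = TRUE),
                          gen_params = c(p1 = 0, p4 = 0.4, p6 = 1,
                                         p8 = 2, p9 = 0, p10 = 4),
                          gen_params_M = NULL,
                          age_median = 23, age_p35 = 0.05,
                          gender_balance = 0.5, interval = 0.7,
                          flow_window = 2, crowd = crowd_params(),
                          width_ratio = 1.5, seed = 1L) {
  check_params(gen_params, gen_spec)
  if (is.null(gen_params_M)) {
    gen_params_M <- gen_params
    gen_params_M[["p8"]] <- 2 * gen_params[["p8"]]
    gen_params_M[["p10"]] <- 2 * gen_params[["p10"]]
  }
  check_params(gen_params_M, gen_spec)
  design <- list(n_per_condition = as.integer(n_per_condition),
                 conditions = cohort_conditions(),
                 gen_spec = gen_spec, gen_params = gen_params,
                 gen_params_M = gen_params_M,
                 age_median = age_median, age_p35 = age_p35,
                 gender_balance = gender_balance, interval = interval,
                 flow_window = flow_window, crowd = crowd,
                 width_ratio = width_ratio, seed = as.integer(seed))
  class(design) <- "cohort_design"
  design
}

# the eight treatment combinations of the factorial design
cohort_conditions <- function() {
  grid <- expand.grid(S = c(FALSE, TRUE), W = c(FALSE, TRUE),
                      M = c(FALSE, TRUE))
  grid$condition <- apply(grid, 1L, function(r) {
    nm <- paste0(c("S", "W", "M")[as.logical(r)], collapse = "")
    if (nm == "") "control" else nm
  })
  grid[, c("condition", "S", "W", "M")]
}

# shifted log-normal ages: 18 + lognormal with the requested median and
# upper-tail mass above 35
draw_ages <- function(n, median = 23, p35 = 0.05, shift = 18) {
  meanlog <- log(median - shift)
  sdlog <- (log(35 - shift) - meanlog) / stats::qnorm(1 - p35)
  shift + stats::rlnorm(n, meanlog, sdlog)
}

condition_config <- function(cond_row, width_ratio) {
  evac_config(treatment_S = cond_row$S, treatment_W = cond_row$W,
              treatment_M = cond_row$M, width_ratio = width_ratio)
}

#' Generate a synthetic cohort
#'
#' For every participant: instantiate the condition's environment, run a
#' fresh scripted crowd (each participant experiences their own session),
#' simulate the participant from the generating choice model, extract the
#' per-sample decision rows and the behavioural summary.  Participants whose
#' simulation fails to produce a completed evacuation with at least one
#' decision row are regenerated under a derived seed; the count of
#' regenerations is reported on the cohort.  The generating truth is stored
#' alongside the outputs but never enters the analysis tables.
#'
#' @param design A \code{\link{cohort_design}}.
#' @param keep_trajectories Keep the per-participant trajectories (needed to
#'   re-derive behavioural summaries, but memory-heavy)?
#' @return An object of class \code{evac_cohort} with \code{decision_data}
#'   (all feature rows with participant, condition and stratum columns),
#'   \code{outcome_table} (one row per participant), \code{truth} (the
#'   generating spec, parameters and per-participant seeds), the <design>,
#'   and \code{n_regenerated}.
#' @export
generate_cohort <- function(design, keep_trajectories = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  conds <- design$conditions
  n_cond <- nrow(conds)
  n_total <- n_cond * design$n_per_condition
  set.seed(design$seed)
  ages <- draw_ages(n_total, design$age_median, design$age_p35)
  genders <- as.integer(stats::runif(n_total) < design$gender_balance)
  ped_seeds <- sample.int(.Machine$integer.max %/% 2L, n_total)

  envs <- lapply(seq_len(n_cond), function(i)
    build_environment(condition_config(conds[i, ], design$width_ratio)))

  decision <- vector("list", n_total)
  outcome <- vector("list", n_total)
  trajectories <- if (keep_trajectories) vector("list", n_total) else NULL
  n_regen <- 0L
  idx <- 0L
  for (ci in seq_len(n_cond)) {
    cond <- conds[ci, ]
    env <- envs[[ci]]
    params <- if (cond$M) design$gen_params_M else design$gen_params
    for (j in seq_len(design$n_per_condition)) {
      idx <- idx + 1L
      pid <- sprintf("%s_%02d", cond$condition, j)
      attempt <- 0L
      repeat {
        seed_j <- (ped_seeds[idx] + attempt * 9973L) %%
          (.Machine$integer.max %/% 2L)
        sim <- simulate_participant(
          env, design$crowd, design$gen_spec, params,
          interval = design$interval, flow_window = design$flow_window,
          seed = seed_j, participant_id = pid,
          condition = cond$condition, age = ages[idx],
          gender = genders[idx])
        rows <- sample_decision_points(sim$trajectory, sim$history,
                                       interval = design$interval,
                                       flow_window = design$flow_window)
        if (sim$trajectory$complete && nrow(rows) > 0L) break
        attempt <- attempt + 1L
        n_regen <- n_regen + 1L
        if (attempt > 5L)
          stop("simulation failure: participant ", pid,
               " could not be generated after 5 retries", call. = FALSE)
      }
      traj <- sim$trajectory
      decision[[idx]] <- cbind(
        data.frame(participant_id = pid, condition = cond$condition,
                   m_flag = cond$M, stringsAsFactors = FALSE),
        rows)
      outcome[[idx]] <- data.frame(
        participant_id = pid, condition = cond$condition,
        S = cond$S, W = cond$W, M = cond$M,
        age = ages[idx], gender = genders[idx],
        chose_shortest = chose_shortest_route(traj, env),
        changed_mind = detect_change_of_mind(traj, env),
        n_samples = nrow(rows), stringsAsFactors = FALSE)
      if (keep_trajectories) trajectories[[idx]] <- traj
    }
  }
  cohort <- list(
    decision_data = do.call(rbind, decision),
    outcome_table = do.call(rbind, outcome),
    trajectories = trajectories,
    truth = list(gen_spec = design$gen_spec,
                 gen_params = design$gen_params,
                 gen_params_M = design$gen_params_M,
                 seed = design$seed, ped_seeds = ped_seeds),
    design = design, n_regenerated = n_regen)
  class(cohort) <- "evac_cohort"
  cohort
}

#' @export
print.evac_cohort <- function(x, ...) {
  ot <- x$outcome_table
  cat(sprintf(
    "Synthetic cohort: %d participants, %d conditions, %d decision rows\n",
    nrow(ot), length(unique(ot$condition)), nrow(x$decision_data)))
  cat(sprintf(
    "  P(shortest) = %.3f, P(change) = %.3f, %.1f rows/participant",
    mean(ot$chose_shortest), mean(ot$changed_mind), mean(ot$n_samples)))
  if (x$n_regenerated > 0L)
    cat(sprintf(" (%d regenerated)", x$n_regenerated))
  cat("\n")
  invisible(x)
}

#' @export
summary.evac_cohort <- function(object, ...) {
  ot <- object$outcome_table
  agg <- do.call(rbind, lapply(split(ot, ot$condition), function(d)
    data.frame(condition = d$condition[1L], n = nrow(d),
               p_shortest = mean(d$chose_shortest),
               p_change = mean(d$changed_mind),
               mean_rows = mean(d$n_samples), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg
}

#' Truth report of a synthetic cohort
#'
#' The generating model, parameters and seeds, together with realised
#' summary statistics, for use in recovery studies.  Errors when the truth
#' has been stripped from the cohort.
#'
#' @param cohort An \code{evac_cohort}.
#' @return A list of class \code{truth_report}.
#' @export
truth_report <- function(cohort) {
  if (is.null(cohort$truth))
    stop("truth stripped: this cohort carries no generating record",
         call. = FALSE)
  ot <- cohort$outcome_table
  structure(list(
    gen_spec_tag = cohort$truth$gen_spec$tag,
    gen_params = cohort$truth$gen_params,
    gen_params_M = cohort$truth$gen_params_M,
    seed = cohort$truth$seed,
    n_participants = nrow(ot),
    mean_rows_per_participant = mean(ot$n_samples),
    p_shortest = mean(ot$chose_shortest),
    p_change = mean(ot$changed_mind),
    p_change_by_stratum = c(nonM = mean(ot$changed_mind[!ot$M]),
                            M = mean(ot$changed_mind[ot$M])),
    jammed_row_fraction = mean(cohort$decision_data$jam != 0)),
    class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  cat("Cohort truth report\n")
  cat(sprintf("  generating model %s, seed %d, %d participants\n",
              x$gen_spec_tag, x$seed, x$n_participants))
  cat("  parameters (non-M): ",
      paste(names(x$gen_params), round(x$gen_params, 3), sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  parameters (M):     ",
      paste(names(x$gen_params_M), round(x$gen_params_M, 3), sep = "=",
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  realised: %.2f rows/participant, P(shortest) = %.3f,\n",
              x$mean_rows_per_participant, x$p_shortest))
  cat(sprintf("  P(change) = %.3f (non-M %.3f, M %.3f), %.1f%% jammed rows\n",
              x$p_change, x$p_change_by_stratum[["nonM"]],
              x$p_change_by_stratum[["M"]], 100 * x$jammed_row_fraction))
  invisible(x)
}
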