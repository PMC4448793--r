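#' Write / read a decision dataset
#'
#' Tidy CSV with one row per sampled decision point: participant, condition,
#' stratum flag, sampling time and the feature/choice columns.  The
#' round-trip is exact for integers and categories and within 1e-12 for
#' reals.
#'
#' @param rows Decision data frame (as in \code{evac_cohort$decision_data}).
#' @param path File path.
#' @return \code{write_decision_dataset} returns the path invisibly;
#'   \code{read_decision_dataset} the data frame.
#' @export
write_decision_dataset <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_decision_dataset
#' @export
read_decision_dataset <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an outcome table
#'
#' One row per participant: condition flags, demographics and the two
#' behavioural outcomes.
#'
#' @param table Outcome table data frame.
#' @param path File path.
#' @export
write_outcome_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_outcome_table
#' @export
read_outcome_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a simulation history's queue series
#'
#' CSV with \code{time_s}, the two queue lengths and the two cumulative
#' exit counts at every recorded step.
#'
#' @param history A \code{sim_history}.
#' @param path File path.
#' @export
write_queue_series <- function(history, path) {
  df <- data.frame(time_s = history$times,
                   q_top = history$q[, "top"],
                   q_bottom = history$q[, "bottom"],
                   exited_top = history$exited[, "top"],
                   exited_bottom = history$exited[, "bottom"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_queue_series
#' @export
read_queue_series <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a participant trajectory
#'
#' CSV with \code{time_s}, position and the preferred exit at each recorded
#' step.
#'
#' @param traj A \code{participant_trajectory}.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(participant_id = traj$participant_id,
                   condition = traj$condition,
                   time_s = traj$times,
                   x_m = traj$pos[, 1L], y_m = traj$pos[, 2L],
                   preferred_exit = c("top", "bottom")[traj$pref])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an evidence report
#'
#' Three CSVs mirroring the ranking layout: per-replicate log marginal
#' likelihoods (\code{<stem>_replicates.csv}: tag, replicate, log_ml, seed),
#' the per-model summary (\code{<stem>_summary.csv}: tag, block, mean, sd,
#' rank) and the pairwise 2log(BF) comparison matrix
#' (\code{<stem>_bf_matrix.csv}).
#'
#' @param selection An \code{exit_model_selection}.
#' @param stem Path stem (no extension).
#' @return The three file paths, invisibly.
#' @export
write_evidence_report <- function(selection, stem) {
  est <- selection$estimates
  reps <- do.call(rbind, lapply(est, function(e)
    data.frame(tag = e$tag, replicate = seq_along(e$replicates),
               log_ml = e$replicates, seed = e$seeds,
               stringsAsFactors = FALSE)))
  p1 <- paste0(stem, "_replicates.csv")
  utils::write.csv(reps, p1, row.names = FALSE)
  p2 <- paste0(stem, "_summary.csv")
  utils::write.csv(selection$ranking$table, p2, row.names = FALSE)
  means <- vapply(est, `[[`, 0, "mean")
  bf <- outer(means, means, function(a, b) 2 * (a - b))
  dimnames(bf) <- list(names(est), names(est))
  p3 <- paste0(stem, "_bf_matrix.csv")
  utils::write.csv(as.data.frame(bf), p3, row.names = TRUE)
  invisible(c(p1, p2, p3))
}

#' Run manifest
#'
#' Records the files a pipeline stage produced with their MD5 digests plus
#' the seeds used, so that re-running a deterministic stage from the same
#' configuration can be verified to reproduce its outputs bit for bit.
#'
#' @param paths Character vector of output files (must exist).
#' @param seeds Named or unnamed integer vector of seeds used.
#' @param note Free-text description.
#' @return A data frame of class \code{run_manifest} (file, md5) with the
#'   seeds, note and timestamp stored as attributes.
#' @export
run_manifest <- function(paths, seeds = integer(0), note = "") {
  stopifnot(all(file.exists(paths)))
  m <- data.frame(file = basename(paths),
                  md5 = unname(tools::md5sum(paths)),
                  stringsAsFactors = FALSE)
  attr(m, "seeds") <- seeds
  attr(m, "note") <- note
  attr(m, "timestamp") <- format(Sys.time(), tz = "UTC")
  class(m) <- c("run_manifest", "data.frame")
  m
}

#' @rdname run_manifest
#' @param manifest A \code{run_manifest}.
#' @param dir Directory holding the listed files.
#' @return \code{verify_manifest}: logical vector, one per file, TRUE when
#'   the current digest matches the recorded one.
#' @export
verify_manifest <- function(manifest, dir = ".") {
  current <- unname(tools::md5sum(file.path(dir, manifest$file)))
  current == manifest$md5
}
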