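#' Participant trajectory container
#'
#' A participant's path through the central room, recorded at the simulation
#' step resolution, together with the exit preference displayed at each time.
#' Preferences are always defined: participants are assumed to prefer one of
#' the two exits at every retained sample and are never undecided.
#'
#' @param participant_id Identifier.
#' @param condition Condition label (one of the eight treatment combinations).
#' @param times Strictly increasing times, seconds.
#' @param pos \code{length(times) x 2} matrix of positions, metres.
#' @param pref Integer vector (1 = top, 2 = bottom), preference at each time.
#' @param exit_used \code{"top"}, \code{"bottom"}, or \code{NA} when the
#'   participant never left the room.
#' @param exit_time Seconds, or \code{NA}.
#' @param age,gender Demographics (years; 0/1 code).
#' @param complete Did the participant exit before the time cap?
#' @return An object of class \code{participant_trajectory}.
#' @export
participant_trajectory <- function(participant_id, condition, times, pos, pref,
                                   exit_used = NA_character_,
                                   exit_time = NA_real_, age = NA_real_,
                                   gender = NA_integer_, complete = TRUE) {
  stopifnot(nrow(pos) == length(times), length(pref) == length(times),
            all(diff(times) > 0))
  structure(list(participant_id = participant_id, condition = condition,
                 times = times, pos = pos, pref = as.integer(pref),
                 exit_used = exit_used, exit_time = exit_time, age = age,
                 gender = gender, complete = complete),
            class = "participant_trajectory")
}

#' @export
print.participant_trajectory <- function(x, ...) {
  cat(sprintf(
    "Participant %s (%s): %d recorded steps, exit %s at %.1f s\n",
    x$participant_id, x$condition, length(x$times),
    ifelse(is.na(x$exit_used), "none", x$exit_used), x$exit_time))
  invisible(x)
}

# signed indicator of which route is shorter when visible: +1 if the top
# route is shorter and visible, -1 if the bottom route is, 0 without S
s_vis_indicator <- function(env) {
  cfg <- env$config
  if (!cfg$treatment_S) return(0)
  if (cfg$corridor_top_length < cfg$corridor_bottom_length) 1 else -1
}

#' Jam indicator for a participant
#'
#' A participant queued at one exit is "jammed" when at least one scripted
#' pedestrian's disc blocks the straight segment from the participant to the
#' opposite exit's near edge.  The sign pushes towards the exit the
#' participant is queued at: +1 when jammed in the top queue, -1 in the
#' bottom queue, 0 elsewhere.
#'
#' @param ped_pos \code{n x 2} matrix of scripted pedestrian positions.
#' @param ped_active Logical vector: pedestrian still in the room?
#' @param env An \code{evac_env}.
#' @param participant Length-2 numeric position of the participant.
#' @param queue_exit \code{"top"}, \code{"bottom"} or \code{"none"}: which
#'   exit's queue zone the participant currently occupies.
#' @param r Scripted pedestrian disc radius, metres.
#' @return Integer in \{-1, 0, +1\}.
#' @export
detect_jam <- function(ped_pos, ped_active, env, participant,
                       queue_exit = c("none", "top", "bottom"), r = 0.25) {
  queue_exit <- match.arg(queue_exit)
  if (queue_exit == "none" || is.null(ped_pos) || !any(ped_active)) return(0L)
  opp <- if (queue_exit == "top") "bottom" else "top"
  # near edge of the opposite exit opening: the endpoint closest to the room
  # interior on the participant's side
  span <- env$exit_span[opp, ]
  edge_y <- span[which.min(abs(span - participant[2L]))]
  a <- participant
  b <- c(env$wall_x, edge_y)
  p <- ped_pos[ped_active, , drop = FALSE]
  if (point_segment_blocked(p, a, b, r)) {
    if (queue_exit == "top") 1L else -1L
  } else 0L
}

# TRUE when any point in p (n x 2) lies within r of segment a-b
point_segment_blocked <- function(p, a, b, r) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d2 <- (p[, 1L] - a[1L])^2 + (p[, 2L] - a[2L])^2
    return(any(d2 <= r^2))
  }
  tt <- ((p[, 1L] - a[1L]) * ab[1L] + (p[, 2L] - a[2L]) * ab[2L]) / len2
  tt <- pmin(1, pmax(0, tt))
  cx <- a[1L] + tt * ab[1L]
  cy <- a[2L] + tt * ab[2L]
  any((p[, 1L] - cx)^2 + (p[, 2L] - cy)^2 <= r^2)
}

# which exit's queue zone the participant is in, given its current preference
queue_zone_of <- function(env, R_capture, participant, pref) {
  exit_id <- c("top", "bottom")[pref]
  ctr <- env$exit_centre[exit_id, ]
  if (sqrt(sum((participant - ctr)^2)) <= R_capture) exit_id else "none"
}

#' Sample per-decision feature rows for a participant
#'
#' Walks the participant's trajectory at fixed sampling intervals, from the
#' first tick at which an initial preference is established (the first tick
#' whose displacement since the previous tick reduces the distance to one
#' exit by at least \code{eps}) until the participant passes an exit, and
#' extracts at each tick the information the choice models see.  All signed
#' features follow the "advantage of the top exit" convention:
#' \describe{
#'   \item{q_adv}{queue-length advantage of top, \code{q_bottom - q_top}, persons}
#'   \item{f_adv}{flow advantage of top, \code{flow_top - flow_bottom}, persons/s
#'     (0 while less than one flow window of history exists)}
#'   \item{w_adv}{width advantage of top, \code{w_top - w_bottom}, metres}
#'   \item{s_vis}{signed shorter-route visibility indicator in \{-1, 0, +1\}}
#'   \item{d_adv}{distance advantage of top, \code{dist_bottom - dist_top}, metres}
#'   \item{jam}{signed jam indicator, see \code{\link{detect_jam}}}
#'   \item{choice}{the preference displayed at the tick}
#' }
#'
#' @param traj A \code{participant_trajectory} sharing a clock with
#'   \code{history}.
#' @param history The \code{sim_history} the participant experienced.
#' @param interval Sampling interval, seconds.
#' @param flow_window Trailing window for the flow feature, seconds.
#' @param eps Preference-onset displacement gate, metres.
#' @return A data frame with one row per retained tick (possibly zero rows):
#'   \code{t_s} plus the feature and choice columns above.
#' @export
sample_decision_points <- function(traj, history, interval = 0.5,
                                   flow_window = 2, eps = 0.05) {
  env <- history$env
  empty <- data.frame(t_s = numeric(0), q_adv = numeric(0),
                      f_adv = numeric(0), w_adv = numeric(0),
                      s_vis = numeric(0), d_adv = numeric(0),
                      jam = integer(0), choice = character(0),
                      stringsAsFactors = FALSE)
  if (length(traj$times) == 0L) return(empty)
  # snap the tick grid to the recording resolution so sampled times coincide
  # with recorded states (and, for generated data, with the decision times)
  interval <- max(1L, round(interval / history$dt)) * history$dt
  end_t <- if (is.na(traj$exit_time)) max(traj$times) else traj$exit_time
  ticks <- seq(traj$times[1L], end_t + 1e-9, by = interval)
  if (length(ticks) < 2L) return(empty)
  ctr_top <- env$exit_centre["top", ]
  ctr_bot <- env$exit_centre["bottom", ]
  traj_at <- function(t) {
    i <- which.min(abs(traj$times - t))
    # pref is the preference displayed at the tick; pref_prev the one held
    # just before it, i.e. the state the decision was taken in
    list(pos = traj$pos[i, ], pref = traj$pref[i],
         pref_prev = traj$pref[max(1L, i - 1L)])
  }
  # preference onset: first tick approaching one exit by >= eps since the
  # previous tick
  onset <- NA_integer_
  prev <- traj_at(ticks[1L])$pos
  for (k in 2L:length(ticks)) {
    cur <- traj_at(ticks[k])$pos
    gain_top <- sqrt(sum((prev - ctr_top)^2)) - sqrt(sum((cur - ctr_top)^2))
    gain_bot <- sqrt(sum((prev - ctr_bot)^2)) - sqrt(sum((cur - ctr_bot)^2))
    if (max(gain_top, gain_bot) >= eps) { onset <- k; break }
    prev <- cur
  }
  if (is.na(onset)) return(empty)
  ticks <- ticks[ticks >= ticks[onset] - 1e-9 & ticks <= end_t + 1e-9]
  w_adv <- env$exit_width[["top"]] - env$exit_width[["bottom"]]
  s_vis <- s_vis_indicator(env)
  rows <- lapply(ticks, function(t) {
    at <- traj_at(t)
    hi <- history_index(history, min(t, max(history$times)))
    if (is.na(hi)) hi <- nrow(history$q)
    ht <- history$times[hi]
    q_adv <- history$q[hi, "bottom"] - history$q[hi, "top"]
    ft <- queue_flow(history, "top", ht, flow_window)
    fb <- queue_flow(history, "bottom", ht, flow_window)
    f_adv <- if (is.na(ft) || is.na(fb)) 0 else ft - fb
    d_adv <- sqrt(sum((at$pos - ctr_bot)^2)) - sqrt(sum((at$pos - ctr_top)^2))
    zone <- queue_zone_of(env, history$pars$R_capture, at$pos, at$pref_prev)
    jam <- if (!is.null(history$pos)) {
      active <- history$status[hi, ] != PED_EXITED
      detect_jam(matrix(history$pos[hi, , ], ncol = 2L), active, env,
                 at$pos, zone)
    } else 0L
    data.frame(t_s = t, q_adv = q_adv, f_adv = f_adv, w_adv = w_adv,
               s_vis = s_vis, d_adv = d_adv, jam = jam,
               choice = c("top", "bottom")[at$pref],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-exit maximal-run approach progress: at each step the participant is
# "walking towards" the exit whose distance it reduces the most; progress
# accumulates over consecutive such steps and resets otherwise
approach_progress <- function(traj, env) {
  d_top <- sqrt((traj$pos[, 1L] - env$exit_centre["top", 1L])^2 +
                (traj$pos[, 2L] - env$exit_centre["top", 2L])^2)
  d_bot <- sqrt((traj$pos[, 1L] - env$exit_centre["bottom", 1L])^2 +
                (traj$pos[, 2L] - env$exit_centre["bottom", 2L])^2)
  dec_top <- -diff(d_top)
  dec_bot <- -diff(d_bot)
  best <- c(top = 0, bottom = 0)
  run <- c(0, 0)
  for (i in seq_along(dec_top)) {
    towards_top <- dec_top[i] > 0 && dec_top[i] > dec_bot[i]
    towards_bot <- dec_bot[i] > 0 && dec_bot[i] > dec_top[i]
    run[1L] <- if (towards_top) run[1L] + dec_top[i] else 0
    run[2L] <- if (towards_bot) run[2L] + dec_bot[i] else 0
    best[1L] <- max(best[1L], run[1L])
    best[2L] <- max(best[2L], run[2L])
  }
  best
}

#' Detect a change of mind
#'
#' A participant changed their mind when they walked at least
#' \code{threshold} (one-fifth of the room height by default) towards one
#' exit before changing direction and exiting through the opposite exit.
#' Progress towards an exit is the reduction in Euclidean distance to its
#' centre accumulated over consecutive approach segments (a step counts as
#' approaching the exit whose distance it reduces the most).
#'
#' @param traj A \code{participant_trajectory} that terminates beyond an exit.
#' @param env The \code{evac_env} the trajectory was recorded in.
#' @param threshold Progress threshold, metres; defaults to
#'   \code{room_height / 5}.
#' @return \code{TRUE}/\code{FALSE}, or \code{NA} when the trajectory never
#'   reaches an exit.
#' @export
detect_change_of_mind <- function(traj, env,
                                  threshold = env$config$room_height / 5) {
  if (is.na(traj$exit_used)) return(NA)
  opp <- if (traj$exit_used == "top") "bottom" else "top"
  prog <- approach_progress(traj, env)
  unname(prog[opp] >= threshold)
}

#' Did the participant choose the shortest route?
#'
#' TRUE iff the exit actually used leads into the shorter corridor (the
#' bottom corridor under this layout).
#'
#' @inheritParams detect_change_of_mind
#' @return \code{TRUE}/\code{FALSE}, or \code{NA} when the trajectory never
#'   reaches an exit.
#' @export
chose_shortest_route <- function(traj, env) {
  if (is.na(traj$exit_used)) return(NA)
  traj$exit_used == env$shorter_route
}

#' Per-participant behavioural summary
#'
#' @param traj A \code{participant_trajectory}.
#' @param env The environment it was recorded in.
#' @param rows The participant's feature rows (from
#'   \code{\link{sample_decision_points}}).
#' @return One-row data frame: \code{chose_shortest}, \code{changed_mind},
#'   \code{n_samples}.
#' @export
behavioural_summary <- function(traj, env, rows) {
  data.frame(chose_shortest = chose_shortest_route(traj, env),
             changed_mind = detect_change_of_mind(traj, env),
             n_samples = nrow(rows))
}
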