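#' Environment configuration for the two-exit evacuation room
#'
#' Describes the virtual environment: a rectangular central room whose right
#' wall carries two exits, each leading into a corridor towards the final
#' target.  The top exit feeds the longer corridor, so the bottom route is
#' always the shorter one.  Treatments mirror the experimental manipulations:
#' \code{treatment_S} makes the global layout (and hence the shorter route)
#' visible, \code{treatment_W} widens the top exit by \code{width_ratio}, and
#' \code{treatment_M} displays a motivational time-pressure message (it does
#' not change the geometry, only how downstream data are stratified).
#'
#' @param room_width,room_height Room dimensions in metres.  \code{room_height}
#'   is the H of the change-of-mind rule (threshold H/5).
#' @param exit_bottom_width Width of the bottom exit in metres.
#' @param exit_top_width Width of the top exit in metres.  Defaults to the
#'   bottom width, or \code{width_ratio} times it under \code{treatment_W}.
#' @param corridor_top_length,corridor_bottom_length Corridor lengths in
#'   metres; the top corridor must be strictly longer.
#' @param exit_offset Vertical distance of each exit centre from the wall
#'   midpoint, metres.
#' @param treatment_S,treatment_W,treatment_M Logical treatment flags.
#' @param width_ratio Top/bottom width ratio enforced under \code{treatment_W}.
#'
#' @return An object of class \code{evac_config} (a validated list).
#' @examples
#' cfg <- evac_config()                      # control: equal exits
#' cfg_w <- evac_config(treatment_W = TRUE)  # top exit 1.5x wider
#' cfg_w$exit_top_width / cfg_w$exit_bottom_width
#' @export
evac_config <- function(room_width = 10, room_height = 10,
                        exit_bottom_width = 1,
                        exit_top_width = NULL,
                        corridor_top_length = 15,
                        corridor_bottom_length = 10,
                        exit_offset = room_height / 4,
                        treatment_S = FALSE, treatment_W = FALSE,
                        treatment_M = FALSE, width_ratio = 1.5) {
  if (is.null(exit_top_width)) {
    exit_top_width <- if (treatment_W) width_ratio * exit_bottom_width
                      else exit_bottom_width
  }
  cfg <- list(room_width = room_width, room_height = room_height,
              exit_top_width = exit_top_width,
              exit_bottom_width = exit_bottom_width,
              corridor_top_length = corridor_top_length,
              corridor_bottom_length = corridor_bottom_length,
              exit_offset = exit_offset,
              treatment_S = isTRUE(treatment_S),
              treatment_W = isTRUE(treatment_W),
              treatment_M = isTRUE(treatment_M),
              width_ratio = width_ratio)
  class(cfg) <- "evac_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("room_width", "room_height", "exit_top_width", "exit_bottom_width",
           "corridor_top_length", "corridor_bottom_length", "exit_offset",
           "width_ratio")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("configuration error: '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (cfg$corridor_top_length <= cfg$corridor_bottom_length)
    stop("configuration error: 'corridor_top_length' must exceed ",
         "'corridor_bottom_length' (the top route is the longer one)",
         call. = FALSE)
  if (!cfg$treatment_W &&
      abs(cfg$exit_top_width - cfg$exit_bottom_width) > 1e-12)
    stop("configuration error: 'exit_top_width' must equal ",
         "'exit_bottom_width' without treatment W", call. = FALSE)
  if (cfg$treatment_W &&
      abs(cfg$exit_top_width / cfg$exit_bottom_width - cfg$width_ratio) > 1e-9)
    stop("configuration error: 'exit_top_width' must be 'width_ratio' times ",
         "'exit_bottom_width' under treatment W", call. = FALSE)
  # openings must fit on the wall and not overlap
  h2 <- cfg$room_height / 2
  if (cfg$exit_offset + cfg$exit_top_width / 2 > h2)
    stop("configuration error: 'exit_top_width' exceeds the wall segment",
         call. = FALSE)
  if (cfg$exit_offset + cfg$exit_bottom_width / 2 > h2)
    stop("configuration error: 'exit_bottom_width' exceeds the wall segment",
         call. = FALSE)
  if (cfg$exit_offset - cfg$exit_top_width / 2 <=
      -cfg$exit_offset + cfg$exit_bottom_width / 2)
    stop("configuration error: 'exit_offset' too small, exit openings overlap",
         call. = FALSE)
  invisible(cfg)
}

#' Build the environment geometry from a configuration
#'
#' Places the two exits on the shared wall between the central room and the
#' corridors (the right wall, at \code{x = room_width/2}), the top exit
#' feeding the longer corridor.  Coordinates are Cartesian metres with the
#' origin at the room centre.
#'
#' @param config An \code{\link{evac_config}}.
#' @return An object of class \code{evac_env} with the validated config, the
#'   wall abscissa, exit centre points, opening extents (y-ranges) and the
#'   label of the shorter route (\code{"bottom"} under this layout).
#' @export
build_environment <- function(config = evac_config()) {
  stopifnot(inherits(config, "evac_config"))
  validate_config(config)
  wall_x <- config$room_width / 2
  off <- config$exit_offset
  env <- list(
    config = config,
    wall_x = wall_x,
    exit_centre = rbind(top = c(wall_x, off), bottom = c(wall_x, -off)),
    exit_span = rbind(
      top = c(off - config$exit_top_width / 2, off + config$exit_top_width / 2),
      bottom = c(-off - config$exit_bottom_width / 2,
                 -off + config$exit_bottom_width / 2)),
    exit_width = c(top = config$exit_top_width,
                   bottom = config$exit_bottom_width),
    shorter_route = "bottom")
  class(env) <- "evac_env"
  env
}

#' @export
print.evac_env <- function(x, ...) {
  cfg <- x$config
  cat("Two-exit evacuation environment\n")
  cat(sprintf("  room: %.1f x %.1f m; exits at y = +/-%.2f m on x = %.2f m\n",
              cfg$room_width, cfg$room_height, cfg$exit_offset, x$wall_x))
  cat(sprintf("  exit widths: top %.2f m, bottom %.2f m\n",
              cfg$exit_top_width, cfg$exit_bottom_width))
  cat(sprintf("  corridors: top %.1f m, bottom %.1f m (shorter route: %s)\n",
              cfg$corridor_top_length, cfg$corridor_bottom_length,
              x$shorter_route))
  cat(sprintf("  treatments: S=%s W=%s M=%s\n",
              cfg$treatment_S, cfg$treatment_W, cfg$treatment_M))
  invisible(x)
}

#' Crowd and simulation parameters
#'
#' @param n_peds Number of scripted pedestrians.
#' @param split_fraction Fraction assigned to the top exit.
#' @param speed Desired walking speed, m/s.
#' @param c_rate Specific exit capacity, persons per metre of exit width per
#'   second; each exit services its queue at \code{c_rate * width}.
#' @param R_capture Capture radius around an exit centre within which assigned
#'   pedestrians count towards that exit's queue, metres.
#' @param slot_spacing Spacing of ordered queue slots, metres.
#' @param dt Simulation step, seconds.
#' @param t_max Time cap, seconds.
#' @return A list of class \code{crowd_params}.
#' @export
crowd_params <- function(n_peds = 40, split_fraction = 0.5, speed = 1.3,
                         c_rate = 1.9, R_capture = 5, slot_spacing = 0.5,
                         dt = 0.1, t_max = 120) {
  stopifnot(n_peds >= 0, split_fraction >= 0, split_fraction <= 1,
            speed > 0, c_rate > 0, R_capture > 0, dt > 0, t_max > 0)
  structure(list(n_peds = as.integer(n_peds),
                 split_fraction = split_fraction, speed = speed,
                 c_rate = c_rate, R_capture = R_capture,
                 slot_spacing = slot_spacing, dt = dt, t_max = t_max),
            class = "crowd_params")
}

# status codes for scripted pedestrians
PED_MOVING <- 0L
PED_QUEUED <- 1L
PED_EXITED <- 2L

#' Initialize the scripted crowd
#'
#' Places \code{n_peds} pedestrians at non-overlapping start positions in the
#' left half of the central room and assigns \code{round(n_peds *
#' split_fraction)} of them to the top exit, the remainder to the bottom exit.
#' Assignments are fixed for a pedestrian's lifetime: the scripted crowd never
#' switches exits.
#'
#' @param env An \code{evac_env}.
#' @param pars A \code{\link{crowd_params}} list.
#' @param seed Integer seed; identical \code{(env, pars, seed)} give identical
#'   initial states.
#' @return A \code{sim_state} object (positions, assignments, queue and
#'   service bookkeeping) at time 0.
#' @export
initialize_crowd <- function(env, pars = crowd_params(), seed = 1L) {
  stopifnot(inherits(env, "evac_env"))
  n <- pars$n_peds
  cfg <- env$config
  # candidate start cells on a grid in the left part of the room
  gap <- 0.7
  xs <- seq(-cfg$room_width / 2 + gap, 0, by = gap)
  ys <- seq(-cfg$room_height / 2 + gap, cfg$room_height / 2 - gap, by = gap)
  cells <- as.matrix(expand.grid(x = xs, y = ys))
  if (n > nrow(cells))
    stop("capacity error: ", n, " pedestrians do not fit at non-overlapping ",
         "start positions (capacity ", nrow(cells), ")", call. = FALSE)
  set.seed(seed)
  if (n > 0L) {
    idx <- sample.int(nrow(cells), n)
    pos <- cells[idx, , drop = FALSE] +
      matrix(stats::runif(2L * n, -0.15, 0.15), ncol = 2L)
  } else {
    pos <- matrix(numeric(0), ncol = 2L)
  }
  n_top <- as.integer(floor(n * pars$split_fraction + 0.5))
  assigned <- rep(2L, n)            # 1 = top, 2 = bottom
  if (n_top > 0L) assigned[seq_len(n_top)] <- 1L
  state <- list(env = env, pars = pars, t = 0,
                pos = pos, assigned = assigned,
                status = rep(PED_MOVING, n),
                exit_time = rep(NA_real_, n),
                queue = list(integer(0), integer(0)),
                acc = c(0, 0), cum_exited = c(0L, 0L))
  class(state) <- "sim_state"
  state
}

# slot position for 0-based queue index i at exit e (1 top, 2 bottom)
slot_position <- function(state, e, i) {
  c(state$env$wall_x - 0.4 - state$pars$slot_spacing * i,
    state$env$exit_centre[e, 2])
}

#' Advance the simulation by one step
#'
#' Moving pedestrians advance towards their assigned exit at the desired
#' speed and adopt ordered queue slots on arrival; each exit services its
#' queue at \code{c_rate * width} persons per second through a deterministic
#' fractional accumulator (so a 1 m exit at 1.9 persons/(m s) releases one
#' pedestrian in a 1 s step and retains 0.9 in the accumulator).  The
#' accumulator saturates at empty queues.
#'
#' @param state A \code{sim_state}.
#' @param dt Step length in seconds (> 0).
#' @return The advanced \code{sim_state}.
#' @export
step_sim <- function(state, dt = state$pars$dt) {
  stopifnot(inherits(state, "sim_state"), dt > 0)
  pars <- state$pars
  env <- state$env
  # 1. service queues
  for (e in 1:2) {
    q <- state$queue[[e]]
    if (length(q) == 0L) {
      state$acc[e] <- 0
    } else {
      w <- env$exit_width[[e]]
      state$acc[e] <- state$acc[e] + pars$c_rate * w * dt
      n_out <- 0L
      while (state$acc[e] >= 1 && length(q) > 0L) {
        head_id <- q[1L]
        q <- q[-1L]
        state$status[head_id] <- PED_EXITED
        state$exit_time[head_id] <- state$t + dt
        state$pos[head_id, ] <- state$env$exit_centre[e, ] + c(0.5, 0)
        state$acc[e] <- state$acc[e] - 1
        n_out <- n_out + 1L
      }
      state$queue[[e]] <- q
      state$cum_exited[e] <- state$cum_exited[e] + n_out
    }
  }
  # 2. queued pedestrians snap to their (possibly advanced) slots
  for (e in 1:2) {
    q <- state$queue[[e]]
    if (length(q) > 0L) {
      idx <- seq_along(q) - 1L
      state$pos[q, 1L] <- env$wall_x - 0.4 - pars$slot_spacing * idx
      state$pos[q, 2L] <- env$exit_centre[e, 2L]
    }
  }
  # 3. moving pedestrians head for the tail slot of their exit's queue
  mov <- which(state$status == PED_MOVING)
  if (length(mov) > 0L) {
    for (e in 1:2) {
      grp <- mov[state$assigned[mov] == e]
      if (length(grp) == 0L) next
      target <- slot_position(state, e, length(state$queue[[e]]))
      dvec <- cbind(target[1L] - state$pos[grp, 1L],
                    target[2L] - state$pos[grp, 2L])
      dist <- sqrt(rowSums(dvec^2))
      stepl <- pars$speed * dt
      reach <- dist <= stepl + 1e-9
      if (any(reach)) {
        # nearest joins first; each joiner takes the next slot
        joiners <- grp[reach][order(dist[reach])]
        for (id in joiners) {
          i <- length(state$queue[[e]])
          state$queue[[e]] <- c(state$queue[[e]], id)
          state$status[id] <- PED_QUEUED
          state$pos[id, ] <- slot_position(state, e, i)
        }
      }
      far <- !reach
      if (any(far)) {
        g <- grp[far]
        state$pos[g, ] <- state$pos[g, , drop = FALSE] +
          dvec[far, , drop = FALSE] / dist[far] * stepl
      }
    }
  }
  state$t <- state$t + dt
  state
}

#' Queue length at an exit
#'
#' The number of not-yet-exited pedestrians assigned to the exit that lie
#' within the capture radius \code{R_capture} of its centre.  This is the
#' observable queue length the choice models' Q component is built from.
#'
#' @param state A \code{sim_state}.
#' @param exit_id \code{"top"} or \code{"bottom"}.
#' @return Integer count of persons.
#' @export
queue_length <- function(state, exit_id = c("top", "bottom")) {
  exit_id <- match.arg(exit_id)
  e <- if (exit_id == "top") 1L else 2L
  sel <- state$assigned == e & state$status != PED_EXITED
  if (!any(sel)) return(0L)
  ctr <- state$env$exit_centre[e, ]
  d <- sqrt((state$pos[sel, 1L] - ctr[1L])^2 +
            (state$pos[sel, 2L] - ctr[2L])^2)
  sum(d <= state$pars$R_capture)
}

#' Run a scripted evacuation
#'
#' Steps the crowd until every scripted pedestrian has exited or the time cap
#' is reached, recording queue lengths, cumulative exits and (optionally)
#' pedestrian positions at every simulation step.
#'
#' @param env An \code{evac_env}.
#' @param pars A \code{\link{crowd_params}} list.
#' @param seed Integer seed.
#' @param record_positions Keep per-step position snapshots (needed for jam
#'   detection downstream)?
#' @return A \code{sim_history}: \code{times}, an \code{n_times x 2} queue
#'   matrix \code{q} (columns top, bottom), cumulative-exit matrix
#'   \code{exited}, optional position array \code{pos}
#'   (\code{n_times x n_peds x 2}) and status matrix, the assignments, and a
#'   \code{complete} flag (FALSE when the cap was hit with pedestrians left).
#' @export
run_evacuation <- function(env, pars = crowd_params(), seed = 1L,
                           record_positions = TRUE) {
  state <- initialize_crowd(env, pars, seed)
  n_steps <- ceiling(pars$t_max / pars$dt)
  n <- pars$n_peds
  times <- numeric(n_steps + 1L)
  q <- matrix(0L, n_steps + 1L, 2L, dimnames = list(NULL, c("top", "bottom")))
  exited <- q
  pos <- if (record_positions && n > 0L) array(NA_real_, c(n_steps + 1L, n, 2L))
         else NULL
  status <- matrix(NA_integer_, n_steps + 1L, max(n, 1L))
  record <- function(k, state) {
    times[k] <<- state$t
    q[k, ] <<- c(queue_length(state, "top"), queue_length(state, "bottom"))
    exited[k, ] <<- state$cum_exited
    if (!is.null(pos)) pos[k, , ] <<- state$pos
    if (n > 0L) status[k, ] <<- state$status
  }
  record(1L, state)
  k <- 1L
  while (k <= n_steps && (n == 0L || any(state$status != PED_EXITED))) {
    state <- step_sim(state)
    k <- k + 1L
    record(k, state)
    if (n == 0L) break
  }
  keep <- seq_len(k)
  hist <- list(times = times[keep], q = q[keep, , drop = FALSE],
               exited = exited[keep, , drop = FALSE],
               pos = if (!is.null(pos)) pos[keep, , , drop = FALSE] else NULL,
               status = if (n > 0L) status[keep, , drop = FALSE] else NULL,
               assigned = state$assigned, env = env, pars = pars,
               dt = pars$dt, seed = seed,
               complete = n == 0L || all(state$status == PED_EXITED),
               final_state = state)
  class(hist) <- "sim_history"
  hist
}

#' @export
print.sim_history <- function(x, ...) {
  cat(sprintf(
    "Evacuation history: %d pedestrians, %.1f s simulated (%scomplete)\n",
    x$pars$n_peds, max(x$times), if (x$complete) "" else "in"))
  cat(sprintf("  exited: top %d, bottom %d; peak queues: top %d, bottom %d\n",
              x$exited[nrow(x$exited), 1L], x$exited[nrow(x$exited), 2L],
              max(x$q[, 1L]), max(x$q[, 2L])))
  invisible(x)
}

#' @export
plot.sim_history <- function(x, ...) {
  graphics::matplot(x$times, x$q, type = "l", lty = 1, col = c(2, 4),
                    xlab = "time (s)", ylab = "queue length (persons)", ...)
  graphics::legend("topright", c("top", "bottom"), lty = 1, col = c(2, 4),
                   bty = "n")
  invisible(x)
}

# index of the recorded snapshot at time t (steps are equally spaced)
history_index <- function(history, t) {
  idx <- round((t - history$times[1L]) / history$dt) + 1L
  if (idx < 1L || idx > length(history$times) ||
      abs(history$times[idx] - t) > history$dt / 2)
    return(NA_integer_)
  idx
}

#' Queue flow (drain rate) at an exit
#'
#' The finite-difference rate of change of queue length over a trailing
#' window: \code{(q(t - window) - q(t)) / window}, positive while the queue
#' shrinks.  Before one full window of history exists the flow is undefined
#' and \code{NA} is returned; feature extraction substitutes 0 for those
#' first samples.
#'
#' @param history A \code{sim_history}.
#' @param exit_id \code{"top"} or \code{"bottom"}.
#' @param t Time of evaluation, seconds.
#' @param window Trailing window, seconds.
#' @return Persons per second, or \code{NA} when insufficient history exists.
#' @export
queue_flow <- function(history, exit_id = c("top", "bottom"), t, window = 2) {
  exit_id <- match.arg(exit_id)
  e <- if (exit_id == "top") 1L else 2L
  i1 <- history_index(history, t)
  i0 <- history_index(history, t - window)
  if (is.na(i0) || is.na(i1)) return(NA_real_)
  unname((history$q[i0, e] - history$q[i1, e]) / window)
}
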