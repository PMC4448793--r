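#' Specify an exit-choice model
#'
#' A member of the 16-model family is defined by which of the four
#' information components it includes: queue length (Q), queue flow (F),
#' exit width (W) and visible shorter route (S).  Three further components
#' are present in every model and are not subject to selection: a constant
#' bias (p1), a proximity effect with its distance threshold (p8, p9) and
#' the jam effect (p10).
#'
#' @param Q,F,W,S Logical: include the component?
#' @return An object of class \code{exit_model_spec}.
#' @examples
#' model_spec(Q = TRUE, F = TRUE)          # tag "QF--"
#' @export
model_spec <- function(Q = FALSE, F = FALSE, W = FALSE, S = FALSE) {
  spec <- list(include_Q = isTRUE(Q), include_F = isTRUE(F),
               include_W = isTRUE(W), include_S = isTRUE(S))
  spec$tag <- paste0(if (spec$include_Q) "Q" else "-",
                     if (spec$include_F) "F" else "-",
                     if (spec$include_W) "W" else "-",
                     if (spec$include_S) "S" else "-")
  class(spec) <- "exit_model_spec"
  spec
}

#' @export
print.exit_model_spec <- function(x, ...) {
  cat("Exit-choice model spec:", x$tag,
      sprintf("(%d selectable components + constant/proximity/jam)\n",
              spec_size(x)))
  invisible(x)
}

spec_size <- function(spec) {
  sum(spec$include_Q, spec$include_F, spec$include_W, spec$include_S)
}

#' Enumerate the 16-member model family
#'
#' All subsets of \{Q, F, W, S\}, deterministically ordered: the full model
#' first, then by decreasing subset size, lexicographically (in component
#' order Q, F, W, S) within each size.  The subset-size counts are
#' 1, 4, 6, 4, 1.
#'
#' @return A list of 16 \code{exit_model_spec} objects, named by tag.
#' @export
enumerate_model_family <- function() {
  comps <- c("Q", "F", "W", "S")
  specs <- list()
  for (size in 4:0) {
    if (size == 0L) {
      sets <- list(character(0))
    } else {
      sets <- utils::combn(comps, size, simplify = FALSE)
    }
    for (s in sets) {
      specs[[length(specs) + 1L]] <-
        model_spec(Q = "Q" %in% s, F = "F" %in% s,
                   W = "W" %in% s, S = "S" %in% s)
    }
  }
  names(specs) <- vapply(specs, `[[`, "", "tag")
  specs
}

#' Parameter names required by a model spec
#'
#' Coefficients of excluded components are absent from the parameter space
#' (not fixed-at-zero free parameters), so the dimensionality penalty of the
#' marginal likelihood applies to exactly the listed parameters.
#'
#' @param spec An \code{exit_model_spec}.
#' @return Character vector in canonical order, always containing
#'   \code{p1}, \code{p8}, \code{p9}, \code{p10}.
#' @export
param_names <- function(spec) {
  c("p1",
    if (spec$include_S) "p2",
    if (spec$include_W) "p3",
    if (spec$include_Q) "p4",
    if (spec$include_F) "p6",
    "p8", "p9", "p10")
}

check_params <- function(params, spec) {
  need <- param_names(spec)
  if (!all(need %in% names(params)))
    stop("specification error: model ", spec$tag, " requires parameters ",
         paste(setdiff(need, names(params)), collapse = ", "), call. = FALSE)
  extra <- setdiff(names(params),
                   c("p1", "p2", "p3", "p4", "p6", "p8", "p9", "p10"))
  if (length(extra))
    stop("specification error: unknown parameters ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (params[["p9"]] < 0)
    stop("specification error: p9 (distance threshold) must be >= 0",
         call. = FALSE)
  invisible(params)
}

#' Linear predictor of the exit-choice model
#'
#' The log-odds of preferring the top exit at a sample:
#' \deqn{\eta = p_1 + p_2 s + p_3 w + p_4 q + p_6 f +
#'   p_8\, d\, 1[|d| \ge p_9] + p_{10}\, jam,}
#' where the \eqn{p_2, p_3, p_4, p_6} terms enter only when the spec includes
#' the S, W, Q, F components respectively, and \eqn{d} is the distance
#' advantage of the top exit gated by the threshold \eqn{p_9}.
#'
#' @param rows A data frame of feature rows with columns \code{q_adv},
#'   \code{f_adv}, \code{w_adv}, \code{s_vis}, \code{d_adv}, \code{jam}.
#' @param params Named numeric vector; must contain exactly the coefficients
#'   the spec requires (see \code{\link{param_names}}).
#' @param spec An \code{exit_model_spec}.
#' @return Numeric vector of log-odds, one per row.
#' @export
linear_predictor <- function(rows, params, spec) {
  check_params(params, spec)
  p <- function(nm) if (nm %in% names(params)) params[[nm]] else 0
  eta <- rep(params[["p1"]], nrow(rows))
  if (spec$include_S) eta <- eta + p("p2") * rows$s_vis
  if (spec$include_W) eta <- eta + p("p3") * rows$w_adv
  if (spec$include_Q) eta <- eta + p("p4") * rows$q_adv
  if (spec$include_F) eta <- eta + p("p6") * rows$f_adv
  eta <- eta + params[["p8"]] * rows$d_adv * (abs(rows$d_adv) >= params[["p9"]])
  eta + params[["p10"]] * rows$jam
}

#' Probability of preferring the top exit
#'
#' The logistic transform of the linear predictor; the two exit
#' probabilities always sum to one and there is no undecided state.
#'
#' @inheritParams linear_predictor
#' @return Numeric vector of probabilities P(choice = top).
#' @export
choice_probability <- function(rows, params, spec) {
  stats::plogis(linear_predictor(rows, params, spec))
}

#' Log-likelihood of a decision dataset
#'
#' Rows are treated as conditionally independent given their features; the
#' log-likelihood is the sum over rows of the log-probability of the observed
#' choice.
#'
#' @param rows A nonempty feature data frame including a \code{choice}
#'   column (\code{"top"}/\code{"bottom"}).
#' @inheritParams linear_predictor
#' @return A single number.
#' @export
log_likelihood <- function(rows, params, spec) {
  if (nrow(rows) == 0L) stop("empty dataset", call. = FALSE)
  eta <- linear_predictor(rows, params, spec)
  s <- ifelse(rows$choice == "top", eta, -eta)
  sum(log_logistic(s))
}

# numerically stable log(plogis(s))
log_logistic <- function(s) {
  ifelse(s > 0, -log1p(exp(-s)), s - log1p(exp(s)))
}

# Precompiled likelihood closure for repeated evaluation (MCMC): maps a
# parameter vector theta (ordered as param_names(spec)) to the log-likelihood.
build_loglik <- function(rows, spec) {
  nms <- param_names(spec)
  lin_cols <- cbind(
    p1 = rep(1, nrow(rows)),
    if (spec$include_S) rows$s_vis,
    if (spec$include_W) rows$w_adv,
    if (spec$include_Q) rows$q_adv,
    if (spec$include_F) rows$f_adv,
    p10 = rows$jam)
  lin_idx <- c(which(nms != "p8" & nms != "p9"))
  i_p8 <- which(nms == "p8")
  i_p9 <- which(nms == "p9")
  d <- rows$d_adv
  absd <- abs(d)
  y_top <- rows$choice == "top"
  sign_y <- ifelse(y_top, 1, -1)
  function(theta) {
    eta <- drop(lin_cols %*% theta[lin_idx]) +
      theta[i_p8] * d * (absd >= theta[i_p9])
    sum(log_logistic(sign_y * eta))
  }
}

#' Simulate a participant driven by a known choice model
#'
#' Runs the scripted crowd and a model-driven participant in one coupled
#' simulation: at every sampling tick the participant's feature row is
#' computed from the live crowd state, a preference is drawn from the choice
#' probability, and the participant walks at the crowd's desired speed
#' towards the preferred exit (waiting behind that exit's queue when one is
#' present) until it passes an exit.  This is the generative twin of the
#' fitted model and the basis of all parameter- and model-recovery studies.
#'
#' @param env An \code{evac_env}.
#' @param pars \code{\link{crowd_params}} for the scripted crowd.
#' @param spec Generating \code{exit_model_spec}.
#' @param params Generating parameter vector (see \code{\link{param_names}}).
#' @param interval Preference sampling interval, seconds.
#' @param flow_window Trailing window of the flow feature, seconds.
#' @param seed Integer seed for crowd placement and preference draws.
#' @param start Participant start position; defaults to the room's left
#'   centre.
#' @param participant_id,condition,age,gender Metadata stored on the
#'   trajectory.
#' @return A list with components \code{trajectory}
#'   (\code{participant_trajectory}) and \code{history} (\code{sim_history});
#'   the trajectory's \code{complete} flag is \code{FALSE} when the time cap
#'   was reached before the participant exited.
#' @export
simulate_participant <- function(env, pars = crowd_params(), spec, params,
                                 interval = 0.5, flow_window = 2, seed = 1L,
                                 start = NULL, participant_id = "p1",
                                 condition = "control", age = NA_real_,
                                 gender = NA_integer_) {
  check_params(params, spec)
  if (is.null(start)) start <- c(-env$config$room_width / 2 + 1, 0)
  state <- initialize_crowd(env, pars, seed)
  dt <- pars$dt
  n_steps <- ceiling(pars$t_max / dt)
  n <- pars$n_peds
  ticks_per_interval <- max(1L, round(interval / dt))

  times <- numeric(n_steps + 1L)
  qmat <- matrix(0L, n_steps + 1L, 2L,
                 dimnames = list(NULL, c("top", "bottom")))
  exited <- qmat
  pos_arr <- if (n > 0L) array(NA_real_, c(n_steps + 1L, n, 2L)) else NULL
  status_mat <- matrix(NA_integer_, n_steps + 1L, max(n, 1L))
  ppos <- matrix(NA_real_, n_steps + 1L, 2L)
  ppref <- integer(n_steps + 1L)

  w_adv <- env$exit_width[["top"]] - env$exit_width[["bottom"]]
  s_vis <- s_vis_indicator(env)
  ctr <- env$exit_centre

  q_at <- function(k) qmat[k, ]   # recorded queue lengths at step index k
  draw_pref <- function(k, p_pos) {
    # feature row from the live state at step index k
    q_adv <- qmat[k, "bottom"] - qmat[k, "top"]
    back <- k - round(flow_window / dt)
    f_adv <- if (back >= 1L) {
      ((qmat[back, "top"] - qmat[k, "top"]) -
       (qmat[back, "bottom"] - qmat[k, "bottom"])) / flow_window
    } else 0
    d_adv <- sqrt(sum((p_pos - ctr["bottom", ])^2)) -
             sqrt(sum((p_pos - ctr["top", ])^2))
    zone <- if (ppref[k] > 0L)
      queue_zone_of(env, pars$R_capture, p_pos, ppref[k]) else "none"
    jam <- if (n > 0L) {
      detect_jam(matrix(pos_arr[k, , ], ncol = 2L),
                 status_mat[k, ] != PED_EXITED, env, p_pos, zone)
    } else 0L
    row <- data.frame(q_adv = q_adv, f_adv = f_adv, w_adv = w_adv,
                      s_vis = s_vis, d_adv = d_adv, jam = jam)
    pr_top <- choice_probability(row, params, spec)
    if (stats::runif(1) < pr_top) 1L else 2L
  }

  record <- function(k, state) {
    times[k] <<- state$t
    qmat[k, ] <<- c(queue_length(state, "top"), queue_length(state, "bottom"))
    exited[k, ] <<- state$cum_exited
    if (n > 0L) {
      pos_arr[k, , ] <<- state$pos
      status_mat[k, ] <<- state$status
    }
  }

  p_pos <- start
  exit_used <- NA_character_
  exit_time <- NA_real_
  record(1L, state)
  ppos[1L, ] <- p_pos
  ppref[1L] <- draw_pref(1L, p_pos)

  k <- 1L
  while (k <= n_steps && is.na(exit_used)) {
    state <- step_sim(state)
    k <- k + 1L
    record(k, state)
    # participant target: behind the preferred exit's scripted queue, or the
    # exit centre when that queue is empty
    pref <- ppref[k - 1L]
    e <- pref
    qlen <- length(state$queue[[e]])
    target <- if (qlen > 0L) slot_position(state, e, qlen)
              else ctr[e, ]
    dvec <- target - p_pos
    dst <- sqrt(sum(dvec^2))
    stepl <- pars$speed * dt
    if (dst > 1e-12) p_pos <- p_pos + dvec * min(1, stepl / dst)
    ppos[k, ] <- p_pos
    ppref[k] <- pref
    # redraw preference on sampling ticks
    if ((k - 1L) %% ticks_per_interval == 0L)
      ppref[k] <- draw_pref(k, p_pos)
    # exit condition: reached the exit centre with no queue ahead
    if (qlen == 0L && sqrt(sum((p_pos - ctr[e, ])^2)) <= 0.3) {
      exit_used <- c("top", "bottom")[e]
      exit_time <- state$t
    }
  }
  keep <- seq_len(k)
  hist <- list(times = times[keep], q = qmat[keep, , drop = FALSE],
               exited = exited[keep, , drop = FALSE],
               pos = if (n > 0L) pos_arr[keep, , , drop = FALSE] else NULL,
               status = if (n > 0L) status_mat[keep, , drop = FALSE]
                        else NULL,
               assigned = state$assigned, env = env, pars = pars, dt = dt,
               seed = seed,
               complete = n == 0L || all(state$status == PED_EXITED),
               final_state = state)
  class(hist) <- "sim_history"
  traj <- participant_trajectory(
    participant_id = participant_id, condition = condition,
    times = times[keep], pos = ppos[keep, , drop = FALSE],
    pref = ppref[keep], exit_used = exit_used, exit_time = exit_time,
    age = age, gender = gender, complete = !is.na(exit_used))
  list(trajectory = traj, history = hist)
}
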