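test_that("change-of-mind requires one-fifth of room height of progress", {
  env <- control_env()           # room height 10 m, threshold 2 m
  top <- env$exit_centre["top", ]
  bot <- env$exit_centre["bottom", ]
  start <- c(-4, 0)

  # straight to the top exit: no change of mind
  straight <- make_traj(walk_towards(start, top, 9.3), pref = 1,
                        exit_used = "top")
  expect_false(detect_change_of_mind(straight, env))

  # 0.25 H towards the top exit, then out through the bottom: change
  leg1 <- walk_towards(start, top, 2.5)
  leg2 <- walk_towards(leg1[nrow(leg1), ], bot, 12)
  zigzag <- make_traj(rbind(leg1, leg2), pref = 2, exit_used = "bottom")
  expect_true(detect_change_of_mind(zigzag, env))

  # only 0.1 H towards the top exit first: below threshold
  leg1s <- walk_towards(start, top, 1.0)
  leg2s <- walk_towards(leg1s[nrow(leg1s), ], bot, 12)
  short <- make_traj(rbind(leg1s, leg2s), pref = 2, exit_used = "bottom")
  expect_false(detect_change_of_mind(short, env))

  # no exit reached: undefined outcome
  stuck <- make_traj(walk_towards(start, top, 1), pref = 1,
                     exit_used = NA_character_)
  expect_true(is.na(detect_change_of_mind(stuck, env)))
})

test_that("lowering the change-of-mind threshold never loses a detection", {
  env <- control_env()
  top <- env$exit_centre["top", ]
  bot <- env$exit_centre["bottom", ]
  thresholds <- c(0.5, 1, 2, 3, 4)
  for (seed in 1:10) {
    set.seed(seed)
    # random zigzag: alternating legs towards each exit, exiting at the last
    pos <- c(-4, runif(1, -2, 2))
    legs <- list()
    for (k in 1:4) {
      tgt <- if (k %% 2 == 0) top else bot
      leg <- walk_towards(pos, tgt, runif(1, 0.5, 4))
      pos <- leg[nrow(leg), ]
      legs[[k]] <- leg
    }
    legs[[5]] <- walk_towards(pos, top, sqrt(sum((pos - top)^2)))
    traj <- make_traj(do.call(rbind, legs), pref = 1, exit_used = "top")
    det <- vapply(thresholds, function(th)
      detect_change_of_mind(traj, env, threshold = th), logical(1))
    # monotone: TRUE at a high threshold implies TRUE at every lower one
    expect_true(all(diff(rev(det)) >= -1)) # sanity on shape
    expect_true(all(det == cummin(det)))   # non-increasing in threshold
  }
})

test_that("jam indicator fires only in a queue zone with a blocked path", {
  env <- control_env()
  # participant in the open room, pedestrians far away
  peds <- rbind(c(0, 4), c(0, -4))
  expect_equal(detect_jam(peds, c(TRUE, TRUE), env, c(-4, 0), "none"), 0L)

  # queued at the top exit, one disc astride the segment to the bottom exit
  participant <- c(3, 2.5)
  blocker <- c(3.8, 0.1)  # near the straight segment to the bottom exit edge
  expect_equal(detect_jam(rbind(blocker), TRUE, env, participant, "top"), 1L)
  # same geometry mirrored: queued at the bottom exit
  expect_equal(detect_jam(rbind(blocker * c(1, -1)), TRUE, env,
                          participant * c(1, -1), "bottom"), -1L)
  # exited pedestrians cannot block
  expect_equal(detect_jam(rbind(blocker), FALSE, env, participant, "top"), 0L)
  # a distant pedestrian does not block
  expect_equal(detect_jam(rbind(c(-4, -4)), TRUE, env, participant, "top"), 0L)
})

test_that("shortest-route outcome follows the corridor lengths", {
  env <- control_env()
  expect_identical(env$shorter_route, "bottom")
  via_bottom <- make_traj(walk_towards(c(-4, 0),
                                       env$exit_centre["bottom", ], 9.3),
                          pref = 2, exit_used = "bottom")
  via_top <- make_traj(walk_towards(c(-4, 0), env$exit_centre["top", ], 9.3),
                       pref = 1, exit_used = "top")
  expect_true(chose_shortest_route(via_bottom, env))
  expect_false(chose_shortest_route(via_top, env))
})

test_that("decision sampling yields floor(T/delta)+1 rows from onset", {
  env <- control_env()
  sim <- simulate_participant(env, crowd_params(), model_spec(Q = TRUE),
                              c(p1 = 0, p4 = 0.4, p8 = 2, p9 = 0, p10 = 4),
                              interval = 0.5, seed = 11)
  rows <- sample_decision_points(sim$trajectory, sim$history, interval = 0.5)
  expect_gt(nrow(rows), 0)
  # one row exactly every interval, from onset to the last tick before exit
  expect_equal(diff(rows$t_s), rep(0.5, nrow(rows) - 1))
  span <- max(rows$t_s) - min(rows$t_s)
  expect_equal(nrow(rows), floor(span / 0.5) + 1)
  expect_lte(max(rows$t_s), sim$trajectory$exit_time)
  # choices always defined, features finite
  expect_true(all(rows$choice %in% c("top", "bottom")))
  expect_true(all(is.finite(rows$q_adv) & is.finite(rows$f_adv) &
                  is.finite(rows$d_adv)))

  # an empty trajectory yields an empty table
  empty <- participant_trajectory("x", "control", numeric(0),
                                  matrix(numeric(0), ncol = 2), integer(0))
  expect_equal(nrow(sample_decision_points(empty, sim$history)), 0)
})

test_that("feature extraction commutes with the top-bottom mirror", {
  env <- control_env()
  sim <- simulate_participant(env, crowd_params(), model_spec(Q = TRUE),
                              c(p1 = 0.3, p4 = 0.4, p8 = 2, p9 = 0, p10 = 4),
                              interval = 0.5, seed = 21)
  rows <- sample_decision_points(sim$trajectory, sim$history, interval = 0.5)

  # mirror the whole world about the room's horizontal midline
  mh <- sim$history
  mh$q <- mh$q[, c(2, 1)]
  colnames(mh$q) <- c("top", "bottom")
  mh$exited <- mh$exited[, c(2, 1)]
  colnames(mh$exited) <- c("top", "bottom")
  mh$pos[, , 2] <- -mh$pos[, , 2]
  mh$assigned <- 3L - mh$assigned
  mt <- sim$trajectory
  mt$pos[, 2] <- -mt$pos[, 2]
  mt$pref <- 3L - mt$pref
  mt$exit_used <- c(top = "bottom", bottom = "top")[[mt$exit_used]]
  mrows <- sample_decision_points(mt, mh, interval = 0.5)

  expect_equal(nrow(mrows), nrow(rows))
  expect_equal(mrows$q_adv, -rows$q_adv)
  expect_equal(mrows$f_adv, -rows$f_adv)
  expect_equal(mrows$d_adv, -rows$d_adv)
  expect_equal(mrows$jam, -rows$jam)
  expect_equal(mrows$choice,
               ifelse(rows$choice == "top", "bottom", "top"))
})
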