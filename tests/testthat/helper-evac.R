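# shared fixtures: everything is built in code at test time

control_env <- function(...) build_environment(evac_config(...))

fast_settings <- function(n_rungs = 16, n_iter = 300, n_posterior = 300) {
  ss_settings(n_rungs = n_rungs, n_iter = n_iter, n_posterior = n_posterior)
}

# a fabricated straight-line trajectory from `from` towards `to` covering
# `dist` metres in steps of `step`, on a 0.1 s clock
walk_towards <- function(from, to, dist, step = 0.13) {
  u <- (to - from) / sqrt(sum((to - from)^2))
  n <- max(1L, ceiling(dist / step))
  t(vapply(seq_len(n), function(i) from + u * min(i * step, dist),
           numeric(2)))
}

# trajectory object from a position matrix with a constant preference
make_traj <- function(pos, pref, exit_used, id = "t1", cond = "control") {
  n <- nrow(pos)
  participant_trajectory(
    participant_id = id, condition = cond,
    times = seq(0, by = 0.1, length.out = n), pos = pos,
    pref = rep(pref, length.out = n), exit_used = exit_used,
    exit_time = (n - 1) * 0.1, complete = !is.na(exit_used))
}

# random feature rows for likelihood arithmetic tests
random_rows <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(q_adv = sample(-5:5, n, TRUE), f_adv = round(rnorm(n), 2),
             w_adv = sample(c(0, 0.5), n, TRUE),
             s_vis = sample(c(-1, 0, 1), n, TRUE),
             d_adv = round(rnorm(n, sd = 3), 2),
             jam = sample(c(-1L, 0L, 1L), n, TRUE),
             choice = sample(c("top", "bottom"), n, TRUE))
}

full_params <- function(p1 = 0, p2 = 0, p3 = 0, p4 = 0, p6 = 0, p8 = 0,
                        p9 = 0, p10 = 0) {
  c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p6 = p6, p8 = p8, p9 = p9, p10 = p10)
}

# evidence_estimate with prescribed summary, for ranking-layout tests
fake_estimate <- function(tag, mean, sd = 0.1, stratum = "nonM") {
  structure(list(replicates = rep(mean, 5), mean = mean, sd = sd,
                 seeds = 1:5, tag = tag, stratum = stratum),
            class = "evidence_estimate")
}
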