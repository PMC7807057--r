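ramp_traj <- function(x0, x1, f0 = 0, f1 = 0, dt = 0.01) {
  n <- length(x0)
  tibble::tibble(t = seq(0, by = dt, length.out = n), x0 = x0, x1 = x1,
                 f0 = rep_len(f0, n), f1 = rep_len(f1, n))
}

test_that("first crossing finds the earliest threshold exit", {
  # member 0 ramps to the left, member 1 stays put
  tr <- ramp_traj(seq(0, -1, length.out = 11), rep(0, 11))
  cr <- first_crossing(tr, 0.05)
  expect_equal(cr$side, "left")
  expect_equal(cr$member, 0L)
  expect_equal(cr$sample_index, 2L)  # first sample with |x| > 0.05

  # rightward exit maps to the "second" response side
  tr2 <- ramp_traj(rep(0, 11), seq(0, 1, length.out = 11))
  cr2 <- first_crossing(tr2, 0.05)
  expect_equal(cr2$side, "right")
  expect_equal(cr2$member, 1L)

  # no crossing
  expect_null(first_crossing(ramp_traj(rep(0, 5), rep(0, 5)), 0.5))

  # simultaneous exit: larger displacement wins, then lower index
  tie <- ramp_traj(c(0, 0.3), c(0, -0.6))
  expect_equal(first_crossing(tie, 0.2)$member, 1L)
  tie2 <- ramp_traj(c(0, 0.3), c(0, -0.3))
  expect_equal(first_crossing(tie2, 0.2)$member, 0L)

  expect_error(first_crossing(ramp_traj(c(2, 0), c(0, 0)), 0.1),
               "normalised")
  expect_error(first_crossing(tr, 1.5), "0, 1")
})

test_that("first crossing equals the exhaustive scan oracle", {
  set.seed(17)
  for (i in 1:200) {
    tr <- random_walk_traj()
    th <- runif(1, 0.05, 0.6)
    got <- first_crossing(tr, th)
    want <- first_crossing_oracle(tr, th)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$side, want$side)
      expect_equal(got$member, want$member)
      expect_equal(got$sample_index, want$sample_index)
    }
  }
})

test_that("mechanical work follows the per-sample-normalised sum", {
  # constant 1 N over a 0 -> 1 excursion in 10 equal steps
  tr <- ramp_traj(seq(0, 1, length.out = 11), rep(0, 11), f0 = 1)
  expect_equal(mechanical_work(tr, 0), 0.1)

  # pushing forwards while moving backwards dissipates
  tr_back <- ramp_traj(seq(1, 0, length.out = 11), rep(0, 11), f0 = 1)
  expect_lt(mechanical_work(tr_back, 0), 0)

  # sinusoidal force and position match an independent re-summation
  n <- 1000
  x <- sin(seq(0, 3 * pi, length.out = n))
  f <- cos(seq(0, 5 * pi, length.out = n))
  tr_sin <- ramp_traj(x, rep(0, n), f0 = f)
  oracle <- 0
  for (k in 2:n) oracle <- oracle + f[k] * (x[k] - x[k - 1])
  expect_equal(mechanical_work(tr_sin, 0), oracle / (n - 1),
               tolerance = 1e-12)

  expect_error(mechanical_work(tr[1, ], 0), "two samples")
})

test_that("work is stable under uniform time-resampling", {
  n <- 400
  t <- seq(0, 2, length.out = n)
  x <- pmin(pmax(cumsum(rnorm(n, 0.002, 0.01)), -1), 1)
  f <- 0.5 * sin(2 * pi * t)
  tr <- tibble::tibble(t = t, x0 = x, x1 = 0, f0 = f, f1 = 0)
  # 2x finer grid by linear interpolation
  t2 <- seq(0, 2, length.out = 2 * n - 1)
  x2 <- approx(t, x, t2)$y
  f2 <- approx(t, f, t2)$y
  tr2 <- tibble::tibble(t = t2, x0 = x2, x1 = 0, f0 = f2, f1 = 0)
  expect_equal(mechanical_work(tr2, 0), mechanical_work(tr, 0),
               tolerance = 5 / n)
})

test_that("peak force takes the absolute maximum", {
  tr <- ramp_traj(rep(0, 3), rep(0, 3), f0 = c(0.1, -0.9, 0.3))
  expect_equal(peak_force(tr, 0), 0.9)
  expect_equal(peak_force(tr, 1), 0)
})

test_that("the Leader is the member whose choice becomes the group choice", {
  expect_equal(label_leader(data.frame(choice_0 = "first",
                                       choice_1 = "second",
                                       group_choice = "second")), 1L)
  expect_equal(label_leader(data.frame(choice_0 = "second",
                                       choice_1 = "first",
                                       group_choice = "second")), 0L)
  expect_error(label_leader(data.frame(choice_0 = "first",
                                       choice_1 = "first",
                                       group_choice = NA)), "disagreement")
})

test_that("predictor accuracies match a hand count on a toy cohort", {
  # four disagreement trials with hand-chosen trajectories
  trials <- tibble::tibble(
    dyad_id = "d", block = 1, trial = 1:4,
    choice_0 = c("second", "second", "first", "first"),
    choice_1 = c("first", "first", "second", "second"),
    agreed = FALSE,
    group_choice = c("second", "first", "second", "second"),
    rt_0 = c(0.5, 0.9, 0.7, 0.4), rt_1 = c(0.8, 0.6, 0.3, 0.9)
  )
  # leaders: 0, 1, 1, 1; first mover predicts 0, 1, 1, 0 -> 3/4 correct
  mk_traj <- function(id, to) {
    x <- seq(0, to, length.out = 21)
    f_strong <- rep(0.8, 21)
    f_weak <- rep(0.2, 21)
    tibble::tibble(dyad_id = "d", block = 1, trial = id,
                   t = seq(0, 1, length.out = 21),
                   x0 = x, x1 = x,
                   f0 = if (id %% 2 == 0) f_weak else f_strong,
                   f1 = if (id %% 2 == 0) f_strong else f_weak)
  }
  # crossings to the group side for trials 1-3, to the wrong side for 4
  trajs <- dplyr::bind_rows(mk_traj(1, 1), mk_traj(2, -1),
                            mk_traj(3, 1), mk_traj(4, -1))
  rep_ <- predictor_accuracy(trials, trajs, thresholds = 0.05)

  expect_equal(
    rep_$accuracy[rep_$predictor == "first_mover_rt"], 3 / 4)
  expect_equal(
    rep_$accuracy[rep_$predictor == "first_crossing"], 3 / 4)
  # peak force: member with larger constant force predicted leader:
  # trials 1,3 -> member 0; trials 2,4 -> member 1; leaders 0,1,1,1 -> 3/4
  expect_equal(rep_$accuracy[rep_$predictor == "peak_force"], 3 / 4)
  expect_true(all(rep_$accuracy >= 0 & rep_$accuracy <= 1))

  # a cohort where the crossing side always matches the group choice
  perfect <- trials[c(1, 3), ]
  perfect_tr <- dplyr::bind_rows(mk_traj(1, 1), mk_traj(3, 1))
  rp <- predictor_accuracy(perfect, perfect_tr, "first_crossing",
                           thresholds = c(0.05, 0.2))
  expect_true(all(rp$accuracy == 1))

  # missing trajectories are skipped with a message
  expect_message(
    out <- predictor_accuracy(trials, trajs[trajs$trial != 4, ],
                              thresholds = 0.05),
    "skipped")
  expect_equal(attr(out, "n_skipped"), 1L)
  expect_equal(out$n_trials[out$predictor == "first_crossing"], 3)
})

test_that("velocity ratios match hand computation on a piecewise fixture", {
  # leader (member 0) advances at 0.2 units/s; the follower backs off at
  # 0.25 units/s and is first past the 0.05 zone at t = 0.21; afterwards
  # both handles advance at 0.22 units/s, so the combined cursor does too.
  dt <- 0.01
  t <- seq(0, 1, by = dt)
  k <- which(t >= 0.21)[1]
  x0 <- ifelse(t <= 0.21, 0.2 * t, 0.2 * 0.21 + 0.22 * (t - 0.21))
  x1 <- ifelse(t <= 0.21, -0.25 * t, -0.25 * 0.21 + 0.22 * (t - 0.21))
  trajs <- tibble::tibble(dyad_id = "d", block = 1, trial = 1, t = t,
                          x0 = x0, x1 = x1, f0 = 0, f1 = 0)
  trials <- tibble::tibble(dyad_id = "d", block = 1, trial = 1,
                           choice_0 = "second", choice_1 = "first",
                           agreed = FALSE, group_choice = "second",
                           rt_0 = 0.5, rt_1 = 0.6)
  v <- velocity_ratios(trials, trajs, reference_threshold = 0.05)
  expect_equal(v$per_trial$velo_leader, 0.2, tolerance = 1e-8)
  expect_equal(v$per_trial$velo_follower, 0.25, tolerance = 1e-8)
  expect_equal(v$per_trial$velo_dyad, 0.22, tolerance = 1e-8)
  expect_equal(unname(v$means["ratio_leader"]), 0.2 / 0.22,
               tolerance = 1e-8)
  expect_equal(unname(v$means["ratio_follower"]), 0.25 / 0.22,
               tolerance = 1e-8)

  # identical constant speeds give a unit ratio
  x <- 0.3 * t
  same <- tibble::tibble(dyad_id = "d", block = 1, trial = 1, t = t,
                         x0 = x, x1 = x, f0 = 0, f1 = 0)
  vs <- velocity_ratios(trials, same, reference_threshold = 0.05)
  expect_equal(unname(vs$means["ratio_leader"]), 1, tolerance = 1e-8)
})

test_that("simulated cohorts show the expected leadership signatures", {
  exp <- demo_experiment(seed = 99, n_blocks = 40)
  tr <- exp$trials
  tj <- exp$trajectories
  dis <- tr[!tr$agreed, ]
  expect_gt(nrow(dis), 100)

  keys <- paste(tj$dyad_id, tj$block, tj$trial)
  traj_list <- split(tj, factor(keys, levels = unique(keys)))
  dkeys <- paste(dis$dyad_id, dis$block, dis$trial)
  leaders <- vapply(seq_len(nrow(dis)),
                    function(i) label_leader(dis[i, ]), integer(1))

  peaks <- t(vapply(seq_along(dkeys), function(i) {
    tt <- traj_list[[dkeys[i]]]
    c(peak_force(tt, leaders[i]), peak_force(tt, 1L - leaders[i]))
  }, numeric(2)))
  works <- t(vapply(seq_along(dkeys), function(i) {
    tt <- traj_list[[dkeys[i]]]
    c(mechanical_work(tt, leaders[i]),
      mechanical_work(tt, 1L - leaders[i]))
  }, numeric(2)))

  # leaders push harder and drive; followers resist on average
  expect_gt(mean(peaks[, 1] > peaks[, 2]), 0.5)
  expect_gt(mean(peaks[, 1]), mean(peaks[, 2]))
  expect_gt(mean(works[, 1]), 0)
  expect_lt(mean(works[, 2]), 0)

  # the 1C accuracy is non-decreasing across the threshold sweep
  rep_ <- predictor_accuracy(tr, tj, "first_crossing")
  expect_true(all(diff(rep_$accuracy) >= 0))

  # the leader's early pace is the better match to the dyad's final pace
  v <- velocity_ratios(tr, tj)
  expect_lt(abs(v$means["ratio_leader"] - 1),
            abs(v$means["ratio_follower"] - 1))
})
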