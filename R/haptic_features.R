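traj_columns <- function(traj) {
  req <- c("t", "x0", "x1", "f0", "f1")
  if (!all(req %in% names(traj))) {
    stop("a trajectory needs columns t, x0, x1, f0, f1.", call. = FALSE)
  }
}

#' First crossing of a symmetric position threshold
#'
#' Finds the earliest sample at which either member's normalised handle
#' position leaves the zone `[-threshold, +threshold]` around the start
#' position, and on which side.  A crossing to the right (positive side)
#' corresponds to the "second" response, to the left to "first".  When
#' both members exit at the same sample the tie is broken in favour of
#' the larger absolute displacement, then of the lower member index.
#'
#' @param traj A single-trial trajectory (`t`, `x0`, `x1`, `f0`, `f1`).
#' @param threshold Fraction of the full start-to-target excursion, in
#'   (0, 1).
#' @return A list of class `crossing_event` with `side` ("left"/"right"),
#'   `member` (0 or 1), `sample_index`, `threshold`; or `NULL` if neither
#'   member ever leaves the zone.
#' @examples
#' traj <- tibble::tibble(t = seq(0, 1, 0.1), x0 = seq(0, -1, -0.1),
#'                        x1 = 0, f0 = 0, f1 = 0)
#' first_crossing(traj, 0.05)
#' @export
first_crossing <- function(traj, threshold) {
  traj_columns(traj)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1).", call. = FALSE)
  }
  if (abs(traj$x0[1]) > 1 || abs(traj$x1[1]) > 1) {
    stop("positions must be normalised to [-1, 1].", call. = FALSE)
  }
  out0 <- abs(traj$x0) > threshold
  out1 <- abs(traj$x1) > threshold
  k <- which(out0 | out1)
  if (length(k) == 0) return(NULL)
  k <- k[1]
  member <- if (out0[k] && out1[k]) {
    if (abs(traj$x0[k]) >= abs(traj$x1[k])) 0L else 1L
  } else if (out0[k]) 0L else 1L
  x <- if (member == 0L) traj$x0[k] else traj$x1[k]
  structure(list(side = if (x > 0) "right" else "left",
                 member = member, sample_index = k, threshold = threshold),
            class = "crossing_event")
}

#' Per-sample-normalised mechanical work of one member
#'
#' Computes `W = (1/N) * sum_k f[k] * (x[k] - x[k-1])`, the sum of force
#' times handle displacement over all `N` sample increments, divided by
#' `N`.  Positive work means the member drives the motion; negative work
#' means it resists the ongoing displacement.
#'
#' @param traj A single-trial trajectory.
#' @param member Member index, 0 or 1.
#' @return Work in joules (per-sample normalised).
#' @examples
#' traj <- tibble::tibble(t = seq(0, 1, 0.1), x0 = seq(0, 1, 0.1),
#'                        x1 = 0, f0 = 1, f1 = 0)
#' mechanical_work(traj, 0)  # 0.1
#' @export
mechanical_work <- function(traj, member) {
  traj_columns(traj)
  stopifnot(member %in% c(0, 1))
  x <- traj[[paste0("x", member)]]
  f <- traj[[paste0("f", member)]]
  if (length(x) < 2L) stop("need at least two samples.", call. = FALSE)
  if (length(x) != length(f)) {
    stop("position and force series must have equal length.", call. = FALSE)
  }
  sum(f[-1] * diff(x)) / (length(x) - 1)
}

#' Peak force applied by one member
#'
#' The highest absolute force a member applied to the interface over the
#' group-decision phase (magnitude, ignoring direction).
#'
#' @param traj A single-trial trajectory.
#' @param member Member index, 0 or 1.
#' @return Peak |force| in newtons.
#' @export
peak_force <- function(traj, member) {
  traj_columns(traj)
  stopifnot(member %in% c(0, 1))
  max(abs(traj[[paste0("f", member)]]))
}

#' Label the Leader of a disagreement trial
#'
#' On a disagreement trial the Leader is the member whose individual
#' choice equals the final group choice; the other member is the
#' Follower.
#'
#' @param trial A one-row trial record with `choice_0`, `choice_1`,
#'   `group_choice`.
#' @return Member index 0 or 1.
#' @examples
#' label_leader(data.frame(choice_0 = "first", choice_1 = "second",
#'                         group_choice = "second"))  # 1
#' @export
label_leader <- function(trial) {
  if (nrow(trial) != 1L) stop("`trial` must be a single row.", call. = FALSE)
  if (trial$choice_0 == trial$choice_1 || is.na(trial$group_choice)) {
    stop("the Leader is only defined on disagreement trials with a ",
         "group choice.", call. = FALSE)
  }
  if (trial$choice_0 == trial$group_choice) 0L else 1L
}

split_trajectories <- function(trajectories) {
  key <- paste(trajectories$dyad_id, trajectories$block, trajectories$trial)
  split(trajectories, factor(key, levels = unique(key)))
}

#' Score kinematic and kinetic predictors of the group choice
#'
#' Evaluates, over the disagreement trials of a cohort, how often each
#' movement-derived predictor identifies the group outcome:
#'
#' * `first_mover_rt` — the member with the shorter individual response
#'   time is predicted to be the Leader;
#' * `first_crossing` — the side on which a handle first exits the
#'   `[-threshold, +threshold]` zone is the predicted group choice (the
#'   "1C" predictor), evaluated over a sweep of thresholds;
#' * `peak_force` — the member applying the larger peak |force| is
#'   predicted to be the Leader;
#' * `work` — the member providing the larger mechanical work is
#'   predicted to be the Leader.
#'
#' Disagreement trials without a matching trajectory are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param trials A trials tibble (with `dyad_id`, `block`, `trial`).
#' @param trajectories A long trajectory tibble as produced by
#'   [run_experiment()].
#' @param predictors Which predictors to score.
#' @param thresholds Threshold sweep for the first-crossing predictor.
#' @return A tibble with columns `predictor`, `threshold` (`NA` except
#'   for the 1C rows), `n_trials`, `accuracy`, with attribute
#'   `n_skipped`.
#' @export
predictor_accuracy <- function(trials, trajectories,
                               predictors = c("first_mover_rt",
                                              "first_crossing",
                                              "peak_force", "work"),
                               thresholds = c(0.05, 0.08, 0.10, 0.15,
                                              0.20, 0.25, 0.30)) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  dis <- trials[!trials$agreed, , drop = FALSE]
  if (nrow(dis) == 0) stop("no disagreement trials to score.", call. = FALSE)
  traj_list <- split_trajectories(trajectories)
  keys <- paste(dis$dyad_id, dis$block, dis$trial)
  have <- keys %in% names(traj_list)
  n_skipped <- sum(!have)
  if (n_skipped > 0) {
    message(n_skipped, " disagreement trial(s) without a trajectory were ",
            "skipped.")
  }
  dis <- dis[have, , drop = FALSE]
  keys <- keys[have]
  n <- nrow(dis)

  leader <- vapply(seq_len(n), function(i) label_leader(dis[i, ]),
                   integer(1))
  rows <- list()

  if ("first_mover_rt" %in% predictors) {
    pred <- ifelse(dis$rt_0 <= dis$rt_1, 0L, 1L)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      predictor = "first_mover_rt", threshold = NA_real_, n_trials = n,
      accuracy = mean(pred == leader))
  }
  if ("first_crossing" %in% predictors) {
    for (th in thresholds) {
      pred_choice <- vapply(keys, function(k) {
        cr <- first_crossing(traj_list[[k]], th)
        if (is.null(cr)) NA_character_
        else if (cr$side == "right") "second" else "first"
      }, character(1), USE.NAMES = FALSE)
      ok <- !is.na(pred_choice)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        predictor = "first_crossing", threshold = th, n_trials = sum(ok),
        accuracy = mean(pred_choice[ok] == dis$group_choice[ok]))
    }
  }
  if ("peak_force" %in% predictors) {
    pf0 <- vapply(keys, function(k) peak_force(traj_list[[k]], 0),
                  numeric(1), USE.NAMES = FALSE)
    pf1 <- vapply(keys, function(k) peak_force(traj_list[[k]], 1),
                  numeric(1), USE.NAMES = FALSE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      predictor = "peak_force", threshold = NA_real_, n_trials = n,
      accuracy = mean(ifelse(pf0 >= pf1, 0L, 1L) == leader))
  }
  if ("work" %in% predictors) {
    w0 <- vapply(keys, function(k) mechanical_work(traj_list[[k]], 0),
                 numeric(1), USE.NAMES = FALSE)
    w1 <- vapply(keys, function(k) mechanical_work(traj_list[[k]], 1),
                 numeric(1), USE.NAMES = FALSE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      predictor = "work", threshold = NA_real_, n_trials = n,
      accuracy = mean(ifelse(w0 >= w1, 0L, 1L) == leader))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Leader, Follower and dyad velocities around the first crossing
#'
#' Splits each disagreement trajectory at the first crossing of
#' `reference_threshold` and computes mean absolute velocities: the
#' Leader's and the Follower's own handle over segment 1 (up to the
#' crossing) and the combined cursor (mean of the two handles) over
#' segment 2 (after it).  The ratios `VeloL/VeloD` and `VeloF/VeloD`
#' index how strongly each member's early pace matches the pace at which
#' the dyad then completes the decision; a ratio closer to 1 for the
#' Leader indicates that the Leader imposes its pace.
#'
#' Trials whose trajectory never crosses the reference threshold, or
#' whose segments are degenerate, are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param trials,trajectories Cohort tables as in [predictor_accuracy()].
#' @param reference_threshold Threshold used to split the movement
#'   (default 0.05).
#' @param member_series `"individual"` uses each member's own handle for
#'   the segment-1 velocities; `"common"` uses the combined cursor for
#'   both, grouped by leader identity.
#' @return A list with `per_trial` (tibble: `velo_leader`,
#'   `velo_follower`, `velo_dyad`, `ratio_leader`, `ratio_follower`) and
#'   `means` (named numeric vector of the cohort-mean ratios), with
#'   attribute `n_excluded`.
#' @export
velocity_ratios <- function(trials, trajectories, reference_threshold = 0.05,
                            member_series = c("individual", "common")) {
  member_series <- match.arg(member_series)
  dis <- trials[!trials$agreed, , drop = FALSE]
  traj_list <- split_trajectories(trajectories)
  keys <- paste(dis$dyad_id, dis$block, dis$trial)
  have <- keys %in% names(traj_list)
  dis <- dis[have, , drop = FALSE]
  keys <- keys[have]

  n_excluded <- 0L
  rows <- list()
  for (i in seq_along(keys)) {
    tr <- traj_list[[keys[i]]]
    cr <- first_crossing(tr, reference_threshold)
    k <- if (is.null(cr)) NA_integer_ else cr$sample_index
    nn <- nrow(tr)
    if (is.na(k) || k < 2L || k > nn - 1L) {
      n_excluded <- n_excluded + 1L
      next
    }
    dt <- diff(tr$t[1:2])
    leader <- label_leader(dis[i, ])
    if (member_series == "individual") {
      xl <- tr[[paste0("x", leader)]]
      xf <- tr[[paste0("x", 1L - leader)]]
    } else {
      xl <- xf <- (tr$x0 + tr$x1) / 2
    }
    xd <- (tr$x0 + tr$x1) / 2
    velo_l <- mean(abs(diff(xl[1:k]))) / dt
    velo_f <- mean(abs(diff(xf[1:k]))) / dt
    velo_d <- mean(abs(diff(xd[k:nn]))) / dt
    if (!is.finite(velo_d) || velo_d == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      dyad_id = dis$dyad_id[i], block = dis$block[i], trial = dis$trial[i],
      velo_leader = velo_l, velo_follower = velo_f, velo_dyad = velo_d,
      ratio_leader = velo_l / velo_d, ratio_follower = velo_f / velo_d)
  }
  if (length(rows) == 0) {
    stop("no trajectory crossed the reference threshold.", call. = FALSE)
  }
  per_trial <- dplyr::bind_rows(rows)
  out <- list(
    per_trial = per_trial,
    means = c(ratio_leader = mean(per_trial$ratio_leader),
              ratio_follower = mean(per_trial$ratio_follower))
  )
  attr(out, "n_excluded") <- n_excluded
  out
}
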