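# Minimum-jerk primitives: position and (max-normalised) velocity profile
# of a unit reach, clamped outside [0, 1] of normalised time.
minjerk_pos <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

minjerk_vel <- function(tau) {
  out <- numeric(length(tau))
  inside <- tau > 0 & tau < 1
  # peak of 30 t^2 (1 - t)^2 is 1.875 at t = 0.5
  out[inside] <- 30 * tau[inside]^2 * (1 - tau[inside])^2 / 1.875
  out
}

# Low-pass filtered gaussian noise so simulated handles wobble smoothly.
smooth_noise <- function(n, sd) {
  if (sd <= 0 || n < 2) return(numeric(n))
  w <- stats::filter(stats::rnorm(n, 0, sd), rep(1, 8) / 8, sides = 1)
  w[is.na(w)] <- 0
  as.numeric(w)
}

#' Simulate a coupled-handle trajectory for one disagreement trial
#'
#' Generates the group-decision phase of a disagreement trial: the member
#' whose individual choice equals the group choice (the Leader) starts a
#' smooth minimum-jerk reach towards the winning side, with an onset time
#' that shrinks and a force amplitude that grows with its absolute
#' confidence.  The other member (the Follower) first moves towards and
#' pushes for its own choice, keeps resisting through the coupling for
#' `follower_yield_delay` seconds after its own onset, then yields,
#' relaxes its force and is carried to the winning side by the coupling.
#' The two handles are tied by a virtual spring
#' (`coupling_stiffness`), so each actual handle position is a compliant
#' mix of the member's own intention and the common mean; the displayed
#' dyad cursor is the mean of the two handles.
#'
#' Positions are normalised so the start is 0 and the "first"/"second"
#' response sides are -1/+1; the trial ends with the combined cursor held
#' inside the validated response zone (|x| >= 0.9) of the group-choice
#' side for one second.
#'
#' @param trial A one-row data frame with columns `choice_0`, `choice_1`,
#'   `group_choice`, `confidence_0`, `confidence_1` (as produced by
#'   [run_experiment()]); the two choices must differ.
#' @param cfg A [sim_config()] object supplying the sample rate, coupling
#'   stiffness, yield delay and the per-member response-time and motor
#'   noise parameters.
#'
#' @return A tibble with columns `t` (seconds, uniform step), `x0`, `x1`
#'   (normalised handle positions in \[-1, 1\]) and `f0`, `f1` (applied
#'   forces, newtons).
#' @examples
#' cfg <- sim_config(seed = 1)
#' trial <- data.frame(choice_0 = "second", choice_1 = "first",
#'                     group_choice = "second",
#'                     confidence_0 = 2, confidence_1 = -0.5)
#' traj <- simulate_trajectory(trial, cfg)
#' range(traj$x0)
#' @export
simulate_trajectory <- function(trial, cfg) {
  if (!inherits(cfg, "sim_config")) {
    stop("`cfg` must be a `sim_config` object.", call. = FALSE)
  }
  if (nrow(trial) != 1L) stop("`trial` must be a single row.", call. = FALSE)
  if (trial$choice_0 == trial$choice_1) {
    stop("trajectories are only generated for disagreement trials.",
         call. = FALSE)
  }
  if (is.na(trial$group_choice)) {
    stop("`trial` must carry a group choice.", call. = FALSE)
  }

  dir_g <- if (trial$group_choice == "second") 1 else -1
  leader <- if (trial$choice_0 == trial$group_choice) 0L else 1L
  conf <- c(trial$confidence_0, trial$confidence_1)
  c_l <- abs(conf[leader + 1L])
  c_f <- abs(conf[2L - leader])
  obs_l <- cfg$observers[[leader + 1L]]
  obs_f <- cfg$observers[[2L - leader]]

  onset <- function(obs, conf_abs) {
    obs$rt_offset +
      (obs$rt_gain / max(conf_abs, 0.05)) * exp(stats::rnorm(1, 0, 0.15))
  }
  t_on_l <- onset(obs_l, c_l)
  t_on_f <- onset(obs_f, c_f)

  dur_l <- max(0.6, min(1.4, 1.3 / (1 + 0.15 * c_l)))  # reach duration, s
  exc_f <- min(0.5, 0.15 + 0.12 * c_f)   # follower own-side excursion
  dur_own <- 0.5                          # follower own reach, s
  dur_yield <- 0.8                        # follower yielding reach, s
  t_yield <- t_on_f + cfg$follower_yield_delay

  dt <- 1 / cfg$sample_rate
  t_end <- max(t_on_l + dur_l, t_yield + dur_yield) + 1.0
  t <- seq(0, t_end, by = dt)
  n <- length(t)

  # intended positions
  u_l <- dir_g * minjerk_pos((t - t_on_l) / dur_l)
  u_own <- -dir_g * exc_f * minjerk_pos((t - t_on_f) / dur_own)
  x_y0 <- -dir_g * exc_f * minjerk_pos((t_yield - t_on_f) / dur_own)
  u_f <- ifelse(t < t_yield, u_own,
                x_y0 + (dir_g - x_y0) * minjerk_pos((t - t_yield) / dur_yield))

  # compliant spring coupling: each handle is mixed towards the other
  # member's intention; the symmetric mixing keeps the combined cursor at
  # the exact mean of the two intentions.  lambda < 0.5 preserves the
  # ordering of the handles (rigid coupling is the lambda -> 0.5 limit).
  lambda <- 0.5 * cfg$coupling_stiffness / (cfg$coupling_stiffness + 10)
  x_l <- u_l + lambda * (u_f - u_l) + smooth_noise(n, obs_l$motor_noise_sd)
  x_f <- u_f + lambda * (u_l - u_f) + smooth_noise(n, obs_f$motor_noise_sd)
  x_l <- pmin(pmax(x_l, -1), 1)
  x_f <- pmin(pmax(x_f, -1), 1)

  # applied forces: amplitude scales with confidence.  The follower pushes
  # towards its own side for the whole conflict window (smooth ramp-in,
  # sustained until it yields) and then relaxes, letting the coupling
  # carry its handle.
  amp_l <- 0.35 * (1 + 0.35 * c_l)
  amp_f <- 0.35 * (1 + 0.35 * c_f)
  f_l <- dir_g * amp_l * minjerk_vel((t - t_on_l) / dur_l)
  conflict <- as.numeric(t < t_yield) * minjerk_pos((t - t_on_f) / 0.5)
  f_f <- -dir_g * amp_f * conflict
  f_l <- f_l + stats::rnorm(n, 0, 0.02)
  f_f <- f_f + stats::rnorm(n, 0, 0.02)

  if (leader == 0L) {
    tibble::tibble(t = t, x0 = x_l, x1 = x_f, f0 = f_l, f1 = f_f)
  } else {
    tibble::tibble(t = t, x0 = x_f, x1 = x_l, f0 = f_f, f1 = f_l)
  }
}
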