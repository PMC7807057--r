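#' Signal-detection observer parameters
#'
#' Describes one member of a dyad as a biased, noisy observer of the signed
#' contrast difference.  On every trial the observer draws an internal
#' decision variable `z ~ Normal(delta_c + bias_b, sigma)` and reports
#' "second" when `z > 0`, so that the probability of reporting "second" is
#' the cumulative Gaussian `pnorm((delta_c + bias_b) / sigma)`.  The
#' confidence attached to the choice is the normalised decision variable
#' `z / sigma`.
#'
#' `rt_offset`, `rt_gain` and `motor_noise_sd` parameterise the response
#' generator rather than the decision model: individual response times
#' follow `rt_offset + rt_gain / |confidence|` (times a lognormal jitter),
#' so that confident decisions are fast, and `motor_noise_sd` sets the
#' amplitude of smooth positional noise added to the simulated handle.
#'
#' @param bias_b Response bias, in contrast-percent units.  Positive values
#'   shift responses towards "second".
#' @param sigma Standard deviation of the internal noise, in
#'   contrast-percent units.  Must be strictly positive; smaller values
#'   mean a more sensitive observer.
#' @param rt_offset Non-decision response-time floor, seconds.
#' @param rt_gain Gain of the inverse confidence/response-time law,
#'   seconds per unit confidence.
#' @param motor_noise_sd Standard deviation of the smooth motor noise added
#'   to simulated handle positions (normalised position units).
#'
#' @return An object of class `observer_params`.
#' @seealso [sim_config()], [simulate_individual()]
#' @examples
#' obs <- observer_params(bias_b = 1, sigma = 6)
#' obs$sigma
#' @export
observer_params <- function(bias_b = 0, sigma = 7, rt_offset = 0.35,
                            rt_gain = 0.45, motor_noise_sd = 0.01) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single strictly positive number.", call. = FALSE)
  }
  if (rt_offset < 0 || rt_gain < 0 || motor_noise_sd < 0) {
    stop("`rt_offset`, `rt_gain` and `motor_noise_sd` must be >= 0.",
         call. = FALSE)
  }
  structure(
    list(bias_b = bias_b, sigma = sigma, rt_offset = rt_offset,
         rt_gain = rt_gain, motor_noise_sd = motor_noise_sd),
    class = "observer_params"
  )
}

#' Configuration of a synthetic dyad experiment
#'
#' Bundles everything [run_experiment()] needs: the balanced block design,
#' the two observers, the group-decision rule used to resolve
#' disagreements, and the parameters of the coupled-handle trajectory
#' generator.  The defaults reproduce the standard design: 8 blocks of 16
#' trials, baseline contrast 10% and oddball contrast levels 11.5%, 13.5%,
#' 17% and 25%, giving signed contrast differences of +/-1.5, +/-3.5, +/-7
#' and +/-15 contrast-percent.
#'
#' @param n_blocks Number of blocks; each block presents every
#'   (oddball timing x contrast level) combination exactly twice.
#' @param observers List of two [observer_params()] objects (members 0
#'   and 1).
#' @param group_model Rule used to resolve disagreement trials: `"WCS"`
#'   (weighted confidence sharing — sign of the summed confidences),
#'   `"CF"` (coin flip), `"BF"` (defer to the member with smaller sigma)
#'   or `"DSS"` (direct signal sharing — precision-weighted evidence).
#' @param baseline_contrast Baseline Gabor contrast, as a fraction.
#' @param oddball_contrast_levels Oddball contrast levels, fractions; all
#'   must exceed `baseline_contrast`.
#' @param sample_rate Trajectory sampling rate, Hz.
#' @param coupling_stiffness Stiffness of the virtual spring coupling the
#'   two handles, in newtons per unit of normalised position.  Large
#'   values make the two handles track their common mean almost rigidly;
#'   small values let each member's handle express its own intention.
#' @param follower_yield_delay Seconds the losing member keeps pushing
#'   towards its own choice before yielding to the group choice.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$oddball_contrast_levels
#' @export
sim_config <- function(n_blocks = 8,
                       observers = list(observer_params(sigma = 6),
                                        observer_params(sigma = 9)),
                       group_model = c("WCS", "CF", "BF", "DSS"),
                       baseline_contrast = 0.10,
                       oddball_contrast_levels = c(0.115, 0.135, 0.17, 0.25),
                       sample_rate = 100,
                       coupling_stiffness = 40,
                       follower_yield_delay = 0.9,
                       seed = NULL) {
  group_model <- match.arg(group_model)
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 1 ||
      n_blocks != round(n_blocks)) {
    stop("`n_blocks` must be a positive integer.", call. = FALSE)
  }
  if (!is.list(observers) || length(observers) != 2L ||
      !all(vapply(observers, inherits, logical(1), "observer_params"))) {
    stop("`observers` must be a list of two `observer_params` objects.",
         call. = FALSE)
  }
  if (length(oddball_contrast_levels) < 1L ||
      any(oddball_contrast_levels <= baseline_contrast)) {
    stop("every oddball contrast level must exceed the baseline contrast.",
         call. = FALSE)
  }
  if (sample_rate <= 0 || coupling_stiffness < 0 || follower_yield_delay < 0) {
    stop("`sample_rate` must be > 0; stiffness and yield delay must be >= 0.",
         call. = FALSE)
  }
  structure(
    list(n_blocks = as.integer(n_blocks), observers = observers,
         group_model = group_model, baseline_contrast = baseline_contrast,
         oddball_contrast_levels = oddball_contrast_levels,
         sample_rate = sample_rate, coupling_stiffness = coupling_stiffness,
         follower_yield_delay = follower_yield_delay, seed = seed),
    class = "sim_config"
  )
}
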