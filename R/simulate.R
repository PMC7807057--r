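#' Simulate individual 2AFC decisions
#'
#' Draws, for each trial, the internal decision variable
#' `z ~ Normal(delta_c + bias_b, sigma)` of a signal-detection observer and
#' converts it to a choice ("second" when `z > 0`, "first" otherwise), a
#' signed confidence `z / sigma`, and a response time following the inverse
#' confidence law `rt_offset + rt_gain / |confidence|` with multiplicative
#' lognormal jitter.  Across many trials at a fixed `delta_c`, the fraction
#' of "second" choices converges to `pnorm((delta_c + bias_b) / sigma)`,
#' the generative inverse of the cumulative-Gaussian psychometric model.
#'
#' @param delta_c Numeric vector of signed contrast differences
#'   (contrast-percent), one per trial.
#' @param obs An [observer_params()] object.
#'
#' @return A tibble with one row per trial: `choice` ("first"/"second"),
#'   `confidence` (signed, unitless) and `rt` (seconds).
#' @examples
#' set.seed(1)
#' out <- simulate_individual(rep(15, 1000), observer_params(sigma = 5))
#' mean(out$choice == "second")   # close to pnorm(3)
#' @export
simulate_individual <- function(delta_c, obs) {
  if (!inherits(obs, "observer_params")) {
    stop("`obs` must be an `observer_params` object.", call. = FALSE)
  }
  n <- length(delta_c)
  z <- stats::rnorm(n, mean = delta_c + obs$bias_b, sd = obs$sigma)
  confidence <- z / obs$sigma
  choice <- ifelse(z > 0, "second", "first")
  # floor |confidence| so near-zero evidence gives long but finite RTs
  rt <- obs$rt_offset +
    (obs$rt_gain / pmax(abs(confidence), 0.05)) * stats::rlnorm(n, 0, 0.2)
  tibble::tibble(choice = choice, confidence = confidence, rt = rt)
}

#' Resolve disagreement trials under a group-decision model
#'
#' Given the two members' signed confidences (normalised decision
#' variables `z / sigma`) on trials where their individual choices differ,
#' returns the group choice under one of four rules:
#'
#' * `"WCS"` — weighted confidence sharing: the sign of
#'   `confidence_0 + confidence_1` decides (positive means "second"), so
#'   the member with the larger absolute confidence always prevails;
#' * `"DSS"` — direct signal sharing: the sign of the precision-weighted
#'   evidence `z_0 / sigma_0^2 + z_1 / sigma_1^2`
#'   (equivalently `confidence_0 / sigma_0 + confidence_1 / sigma_1`);
#' * `"CF"` — coin flip: each disagreement resolved at random;
#' * `"BF"` — behaviour and feedback: defer to the member with the
#'   smaller `sigma` (ties go to member 0).
#'
#' @param confidence_0,confidence_1 Signed confidences of members 0 and 1;
#'   equal-length numeric vectors.  The two members must disagree on every
#'   trial (opposite choice signs).
#' @param sigma_0,sigma_1 The members' internal noise levels
#'   (contrast-percent); used by the DSS and BF rules.
#' @param model One of `"WCS"`, `"CF"`, `"BF"`, `"DSS"`.
#'
#' @return Character vector of group choices, "first" or "second".
#' @examples
#' simulate_group_choice(2, -0.5, 6, 9, model = "WCS")  # "second"
#' @export
simulate_group_choice <- function(confidence_0, confidence_1,
                                  sigma_0, sigma_1,
                                  model = c("WCS", "CF", "BF", "DSS")) {
  model <- match.arg(model)
  if (length(confidence_0) != length(confidence_1)) {
    stop("confidence vectors must have equal length.", call. = FALSE)
  }
  choice_0 <- confidence_0 > 0
  choice_1 <- confidence_1 > 0
  if (any(choice_0 == choice_1)) {
    stop("group decisions are only defined for disagreement trials ",
         "(individual choices must differ).", call. = FALSE)
  }
  score <- switch(
    model,
    WCS = confidence_0 + confidence_1,
    DSS = confidence_0 / sigma_0 + confidence_1 / sigma_1,
    CF  = stats::runif(length(confidence_0)) - 0.5,
    BF  = if (sigma_0 <= sigma_1) confidence_0 else confidence_1
  )
  ifelse(score > 0, "second", "first")
}
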