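fit_params <- function(fit, arg) {
  # accept a psychometric_fit or any list carrying bias_b and sigma
  if (!is.list(fit) || is.null(fit$sigma)) {
    stop("`", arg, "` must be a psychometric fit (with $bias_b, $sigma).",
         call. = FALSE)
  }
  if (!is.finite(fit$sigma) || fit$sigma <= 0) {
    stop("`", arg, "` has a non-positive sigma.", call. = FALSE)
  }
  list(b = if (is.null(fit$bias_b)) 0 else fit$bias_b, sigma = fit$sigma,
       s = slope_from_sigma(fit$sigma))
}

new_dyad_prediction <- function(model, b_dyad, sigma_dyad, s_dyad,
                                provenance = NULL) {
  structure(list(model = model, b_dyad = b_dyad, sigma_dyad = sigma_dyad,
                 s_dyad = s_dyad, provenance = provenance),
            class = "dyad_prediction")
}

#' @export
print.dyad_prediction <- function(x, ...) {
  cat("<dyad_prediction> ", x$model,
      sprintf(": b = %.4f, sigma = %.4f, s = %.5f", x$b_dyad, x$sigma_dyad,
              x$s_dyad),
      if (!is.null(x$provenance)) paste0("  [", x$provenance, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Weighted Confidence Sharing prediction for a dyad
#'
#' Under the Weighted Confidence Sharing (WCS) model the members pool
#' their normalised decision variables `z / sigma`, so the dyad's
#' psychometric function is again a cumulative Gaussian with
#' \deqn{b_{dyad} = \frac{\sigma_2 b_1 + \sigma_1 b_2}{\sigma_1 + \sigma_2},
#'   \qquad
#'   \sigma_{dyad} = \sqrt{2}\,\frac{\sigma_1 \sigma_2}{\sigma_1 + \sigma_2},}
#' which is equivalent to a dyad slope
#' \eqn{s_{dyad} = (s_1 + s_2)/\sqrt{2}}.  The prediction is symmetric in
#' the two members.
#'
#' @param fit_1,fit_2 Individual [fit_psychometric()] results (or any
#'   lists carrying `bias_b` and `sigma`).
#' @return A `dyad_prediction` with fields `model = "WCS"`, `b_dyad`,
#'   `sigma_dyad`, `s_dyad`.
#' @examples
#' wcs_predict(list(bias_b = 0, sigma = 2), list(bias_b = 0, sigma = 3))
#' @export
wcs_predict <- function(fit_1, fit_2) {
  p1 <- fit_params(fit_1, "fit_1")
  p2 <- fit_params(fit_2, "fit_2")
  b_dyad <- (p2$sigma * p1$b + p1$sigma * p2$b) / (p1$sigma + p2$sigma)
  sigma_dyad <- sqrt(2) * p1$sigma * p2$sigma / (p1$sigma + p2$sigma)
  new_dyad_prediction("WCS", b_dyad, sigma_dyad, slope_from_sigma(sigma_dyad))
}

#' Critical sensitivity ratio of the WCS model
#'
#' The ratio `s_min / s_max` of member sensitivities at which the
#' WCS-predicted dyad slope equals the best member's slope.  Solving
#' `(s_min + s_max) / sqrt(2) = s_max` gives `2 / sqrt(2) - 1 =
#' sqrt(2) - 1`, approximately 0.41, which rounds to 0.4: dyads whose
#' members are more similar than this are predicted to beat their best
#' member, and to do worse otherwise.
#'
#' @return `sqrt(2) - 1`, exactly.
#' @examples
#' round(critical_ratio(), 1)  # 0.4
#' @export
critical_ratio <- function() {
  sqrt(2) - 1
}

#' Weights of an over-weighted confidence sharing variant
#'
#' In the weighted variant of the WCS model the dyad over-weights the
#' decisions of its more sensitive member: the less sensitive member's
#' contribution is scaled by `alpha` and the more sensitive member's by
#' `beta`, with `beta > alpha > 0`.  Only the ratio
#' `gamma = alpha / beta < 1` enters the improvement line.
#'
#' @param alpha Weight on the less sensitive member, > 0.
#' @param beta Weight on the more sensitive member, > `alpha`.
#' @return A list of class `wcs_weights` with `alpha`, `beta`, `gamma`.
#' @seealso [improvement_line()]
#' @export
wcs_weights <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      !(beta > alpha && alpha > 0)) {
    stop("weights must satisfy beta > alpha > 0.", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = alpha / beta),
            class = "wcs_weights")
}

#' Predicted dyad improvement as a function of the sensitivity ratio
#'
#' Under WCS the dyad's relative sensitivity is an affine function of the
#' member ratio:
#' \deqn{\frac{s_{dyad}}{s_{max}} = \frac{\sqrt{2}}{2} +
#'   \frac{\sqrt{2}}{2}\,\frac{s_{min}}{s_{max}},}
#' i.e. slope and intercept both `sqrt(2)/2`, about 0.71.  The weighted
#' variant multiplies the ratio by `gamma = alpha / beta < 1`, flattening
#' the slope while leaving the intercept unchanged.
#'
#' @param ratio Member sensitivity ratio `s_min / s_max`, in (0, 1];
#'   vectorised.
#' @param weights Optional [wcs_weights()] for the over-weighted variant.
#' @return Predicted `s_dyad / s_max`.
#' @examples
#' improvement_line(1)                  # sqrt(2): two equal members
#' improvement_line(critical_ratio())   # exactly 1
#' @export
improvement_line <- function(ratio, weights = NULL) {
  if (any(!is.finite(ratio)) || any(ratio <= 0) || any(ratio > 1)) {
    stop("`ratio` must lie in (0, 1].", call. = FALSE)
  }
  gamma <- 1
  if (!is.null(weights)) {
    if (!inherits(weights, "wcs_weights")) {
      stop("`weights` must be created with wcs_weights().", call. = FALSE)
    }
    gamma <- weights$gamma
  }
  sqrt(2) / 2 + sqrt(2) / 2 * gamma * ratio
}

#' Dyad predictions under the alternative group-decision models
#'
#' Closed-form dyad slopes for the three competitor models (formulas taken
#' from the source that introduced them, flagged in the returned object):
#'
#' * `"CF"` (coin flip): disagreements resolved at random, so the dyad
#'   slope is the members' average, `s_dyad = (s_1 + s_2) / 2`;
#' * `"BF"` (behaviour and feedback): the dyad learns to defer to its
#'   better member, `s_dyad = max(s_1, s_2)`;
#' * `"DSS"` (direct signal sharing): members share the full mean and
#'   variance of their sensory evidence and combine it optimally,
#'   `s_dyad = sqrt(s_1^2 + s_2^2)`.
#'
#' The dyad bias is the corresponding combination of member biases (mean
#' for CF, the better member's for BF, precision-weighted for DSS).
#'
#' @param fit_1,fit_2 Individual psychometric fits.
#' @param model `"CF"`, `"BF"` or `"DSS"`.
#' @return A `dyad_prediction`.
#' @examples
#' alternative_predict(list(bias_b = 0, sigma = 5),
#'                     list(bias_b = 0, sigma = 5), "DSS")
#' @export
alternative_predict <- function(fit_1, fit_2, model = c("CF", "BF", "DSS")) {
  model <- match.arg(model)
  p1 <- fit_params(fit_1, "fit_1")
  p2 <- fit_params(fit_2, "fit_2")
  s_dyad <- switch(model,
    CF  = (p1$s + p2$s) / 2,
    BF  = max(p1$s, p2$s),
    DSS = sqrt(p1$s^2 + p2$s^2)
  )
  b_dyad <- switch(model,
    CF  = (p1$b + p2$b) / 2,
    BF  = if (p1$s >= p2$s) p1$b else p2$b,
    DSS = (p1$b / p1$sigma^2 + p2$b / p2$sigma^2) /
          (1 / p1$sigma^2 + 1 / p2$sigma^2)
  )
  new_dyad_prediction(model, b_dyad, sigma_from_slope(s_dyad), s_dyad,
                      provenance = "cited-source formula")
}

#' Summarise one dyad's observed performance against its members
#'
#' Collects the quantities the group-level analyses work with: the
#' members' slopes ordered as `s_min <= s_max`, their ratio, the dyad's
#' observed slope, the improvement `s_dyad / s_max`, and the similarity
#' class (`"similar"` when `ratio >= 0.4`, `"different"` otherwise; the
#' boundary value 0.4 is classified as similar).
#'
#' @param fit_1,fit_2 Individual psychometric fits.
#' @param dyad_fit The dyad's own psychometric fit.
#' @return A one-row tibble: `s_min`, `s_max`, `ratio`,
#'   `s_dyad_observed`, `improvement`, `similarity_class`.
#' @export
dyad_summary <- function(fit_1, fit_2, dyad_fit) {
  p1 <- fit_params(fit_1, "fit_1")
  p2 <- fit_params(fit_2, "fit_2")
  pd <- fit_params(dyad_fit, "dyad_fit")
  s_min <- min(p1$s, p2$s)
  s_max <- max(p1$s, p2$s)
  ratio <- s_min / s_max
  tibble::tibble(
    s_min = s_min, s_max = s_max, ratio = ratio,
    s_dyad_observed = pd$s, improvement = pd$s / s_max,
    similarity_class = ifelse(ratio >= 0.4, "similar", "different")
  )
}

#' Partition dyads into similar- and different-sensitivity classes
#'
#' Splits a table of [dyad_summary()] rows at the sensitivity-ratio
#' threshold 0.4 (ratios of exactly 0.4 count as similar).  The two
#' classes are exhaustive and disjoint.
#'
#' @param summaries A tibble with a `ratio` column in (0, 1].
#' @return A list with tibbles `similar` and `different`.
#' @export
classify_dyads <- function(summaries) {
  if (any(summaries$ratio <= 0) || any(summaries$ratio > 1)) {
    stop("sensitivity ratios must lie in (0, 1].", call. = FALSE)
  }
  cls <- ifelse(summaries$ratio >= 0.4, "similar", "different")
  list(similar = summaries[cls == "similar", , drop = FALSE],
       different = summaries[cls == "different", , drop = FALSE])
}
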