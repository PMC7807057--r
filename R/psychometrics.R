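#' Sensitivity slope of a cumulative-Gaussian psychometric function
#'
#' The psychometric model `P(delta_c) = pnorm((delta_c + b) / sigma)` has
#' its maximum slope at its midpoint, `s = 1 / sqrt(2 * pi * sigma^2)`.
#' `slope_from_sigma()` applies that formula; `sigma_from_slope()` inverts
#' it.  Steeper slope means smaller internal noise, i.e. a more sensitive
#' observer.
#'
#' @param sigma Internal noise (contrast-percent), strictly positive.
#' @param slope Sensitivity slope (1/contrast-percent), strictly positive.
#' @return A numeric vector.
#' @examples
#' slope_from_sigma(5)                    # 1 / sqrt(50 * pi)
#' sigma_from_slope(slope_from_sigma(5))  # 5
#' @export
slope_from_sigma <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be strictly positive.", call. = FALSE)
  }
  1 / sqrt(2 * pi * sigma^2)
}

#' @rdname slope_from_sigma
#' @export
sigma_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope <= 0)) {
    stop("`slope` must be strictly positive.", call. = FALSE)
  }
  1 / (slope * sqrt(2 * pi))
}

#' Bin 2AFC responses by contrast difference
#'
#' Tallies, for one response unit, the number of "second" reports at each
#' distinct signed contrast difference, producing the proportions that the
#' psychometric function is fitted to.  For `unit = "dyad"` the response
#' on an agreement trial is the common individual choice and on a
#' disagreement trial the group choice.
#'
#' @param trials A trials tibble as produced by [run_experiment()] (or
#'   read with [read_trials()]).
#' @param unit Which responses to bin: `"member_0"`, `"member_1"` or
#'   `"dyad"`.
#' @param disagreement_only For `unit = "dyad"`, restrict to disagreement
#'   trials (default keeps all trials).
#'
#' @return A tibble with one row per distinct `delta_c`: `delta_c`,
#'   `n_second`, `n_total`.
#' @examples
#' exp <- run_experiment(sim_config(n_blocks = 2, seed = 1))
#' bin_choices(exp$trials, "dyad")
#' @export
bin_choices <- function(trials, unit = c("member_0", "member_1", "dyad"),
                        disagreement_only = FALSE) {
  unit <- match.arg(unit)
  if (is.null(trials) || nrow(trials) == 0) {
    stop("`trials` must contain at least one trial.", call. = FALSE)
  }
  resp <- switch(unit,
    member_0 = trials$choice_0,
    member_1 = trials$choice_1,
    dyad = {
      final <- ifelse(trials$agreed, trials$choice_0, trials$group_choice)
      if (anyNA(final)) {
        stop("dyad binning needs a group choice on every disagreement trial.",
             call. = FALSE)
      }
      final
    }
  )
  keep <- rep(TRUE, nrow(trials))
  if (unit == "dyad" && disagreement_only) keep <- !trials$agreed
  tibble::tibble(delta_c = trials$delta_c[keep], .resp = resp[keep]) %>%
    dplyr::group_by(.data$delta_c) %>%
    dplyr::summarise(n_second = sum(.data$.resp == "second"),
                     n_total = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$delta_c)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Estimates the bias `b` and internal noise `sigma` of the model
#' `P(delta_c) = pnorm((delta_c + b) / sigma)` from binned choice
#' proportions.  The default criterion is unweighted least squares on the
#' per-level proportions; `"binomial_mle"` maximises the binomial
#' likelihood instead and additionally reports asymptotic standard errors
#' from the observed information.  The sensitivity slope is derived as
#' `s = 1 / sqrt(2 * pi * sigma^2)`.
#'
#' The optimiser is initialised from a probit-transformed linear
#' regression and `sigma` is constrained to \[0.1, 100\]
#' contrast-percent.  Proportions of exactly 0 or 1 are used as-is by the
#' least-squares criterion; the likelihood handles them natively.
#'
#' @param binned A tibble from [bin_choices()] (`delta_c`, `n_second`,
#'   `n_total`).
#' @param method `"least_squares"` (default) or `"binomial_mle"`.
#'
#' @return An object of class `psychometric_fit`: a list with `bias_b`,
#'   `sigma`, `slope_s`, `n_trials`, `fit_method`, `converged`, and (for
#'   the MLE) `se_b`, `se_sigma`, `se_slope`.
#' @examples
#' levels <- c(-15, -7, -3.5, -1.5, 1.5, 3.5, 7, 15)
#' binned <- tibble::tibble(delta_c = levels,
#'                          n_second = round(100 * pnorm(levels / 5)),
#'                          n_total = 100)
#' fit_psychometric(binned)
#' @export
fit_psychometric <- function(binned,
                             method = c("least_squares", "binomial_mle")) {
  method <- match.arg(method)
  req <- c("delta_c", "n_second", "n_total")
  if (!all(req %in% names(binned))) {
    stop("`binned` must have columns delta_c, n_second, n_total.",
         call. = FALSE)
  }
  if (any(binned$n_second < 0) || any(binned$n_second > binned$n_total)) {
    stop("counts must satisfy 0 <= n_second <= n_total.", call. = FALSE)
  }
  dc <- binned$delta_c
  p <- binned$n_second / binned$n_total
  if (length(unique(dc)) < 2L || length(unique(p)) < 2L) {
    stop("non-identifiable: need at least two levels with varying ",
         "response proportions.", call. = FALSE)
  }

  # probit-linear initialisation with a mild continuity correction
  p_adj <- (binned$n_second + 0.5) / (binned$n_total + 1)
  ini <- stats::coef(stats::lm(stats::qnorm(p_adj) ~ dc))
  sigma0 <- if (is.finite(ini[2]) && ini[2] > 1e-6) 1 / ini[2] else 10
  sigma0 <- min(max(sigma0, 0.1), 100)
  b0 <- min(max(ini[1] * sigma0, -50), 50)

  objective <- if (method == "least_squares") {
    function(par) {
      sum((p - stats::pnorm((dc + par[1]) / par[2]))^2)
    }
  } else {
    function(par) {
      pr <- stats::pnorm((dc + par[1]) / par[2])
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      -sum(stats::dbinom(binned$n_second, binned$n_total, pr, log = TRUE))
    }
  }

  ctrl <- list(factr = 1e4, maxit = 500)
  o1 <- stats::optim(c(b0, sigma0), objective, method = "L-BFGS-B",
                     lower = c(-50, 0.1), upper = c(50, 100), control = ctrl)
  # polish from the first optimum; at a tight optimum the line search can
  # report a spurious non-zero code, so convergence is taken from either run
  o <- stats::optim(o1$par, objective, method = "L-BFGS-B",
                    lower = c(-50, 0.1), upper = c(50, 100), control = ctrl,
                    hessian = (method == "binomial_mle"))
  converged <- (o$convergence == 0) || (o1$convergence == 0)
  if (o$value > o1$value) o$par <- o1$par

  b <- o$par[1]
  sigma <- o$par[2]
  s <- slope_from_sigma(sigma)
  se_b <- se_sigma <- se_slope <- NA_real_
  if (method == "binomial_mle" && !is.null(o$hessian)) {
    vc <- tryCatch(solve(o$hessian), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      se_b <- sqrt(vc[1, 1])
      se_sigma <- sqrt(vc[2, 2])
      se_slope <- (s / sigma) * se_sigma   # delta method on s = c / sigma
    }
  }
  structure(
    list(bias_b = unname(b), sigma = unname(sigma), slope_s = unname(s),
         n_trials = sum(binned$n_total), fit_method = method,
         converged = converged,
         se_b = se_b, se_sigma = se_sigma, se_slope = se_slope),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit> (", x$fit_method, ", n = ", x$n_trials, ")\n",
      sprintf("  bias b  = %8.4f\n", x$bias_b),
      sprintf("  sigma   = %8.4f\n", x$sigma),
      sprintf("  slope s = %8.5f\n", x$slope_s),
      if (!x$converged) "  [did not converge]\n" else "",
      sep = "")
  invisible(x)
}

#' Plot a fitted psychometric function over its binned data
#'
#' @param x A `psychometric_fit`.
#' @param binned Optionally the binned data used for the fit, drawn as
#'   points.
#' @param ... Passed to [graphics::curve()].
#' @return `x`, invisibly.
#' @export
plot.psychometric_fit <- function(x, binned = NULL, ...) {
  rng <- if (is.null(binned)) c(-20, 20) else range(binned$delta_c)
  f <- function(dc) stats::pnorm((dc + x$bias_b) / x$sigma)
  graphics::curve(f, from = rng[1], to = rng[2],
                  xlab = "contrast difference (%)",
                  ylab = "P(choose second)", ylim = c(0, 1), ...)
  if (!is.null(binned)) {
    graphics::points(binned$delta_c, binned$n_second / binned$n_total,
                     pch = 19)
  }
  invisible(x)
}
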