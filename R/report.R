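# One-sample t-test robust to degenerate (constant) differences: a vector
# of exact zeros is a null result (t = 0, p = 1) rather than an error.
one_sample_t <- function(d) {
  if (stats::sd(d) == 0) {
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(statistic = stat, df = length(d) - 1,
                p_value = if (stat == 0) 1 else 0))
  }
  tt <- stats::t.test(d, mu = 0)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Test whether dyads outperform their best members
#'
#' Paired comparison of dyad versus best-member sensitivity within one
#' similarity class: a one-sample t-test of the per-dyad differences
#' `s_dyad_observed - s_max` against zero, with `n - 1` degrees of
#' freedom.  A positive statistic means the dyads beat their best
#' members.
#'
#' @param summaries A tibble of [dyad_summary()] rows (with
#'   `similarity_class`).
#' @param class `"similar"`, `"different"`, or `"all"` to pool.
#' @return A one-row tibble: `class`, `n`, `mean_diff`, `statistic`,
#'   `df`, `p_value`.
#' @export
compare_dyad_vs_best <- function(summaries,
                                 class = c("similar", "different", "all")) {
  class <- match.arg(class)
  sub <- if (class == "all") summaries
         else summaries[summaries$similarity_class == class, , drop = FALSE]
  if (nrow(sub) < 2L) {
    stop("need at least 2 dyads in class '", class, "' (have ", nrow(sub),
         ").", call. = FALSE)
  }
  d <- sub$s_dyad_observed - sub$s_max
  tt <- one_sample_t(d)
  tibble::tibble(class = class, n = nrow(sub), mean_diff = mean(d),
                 statistic = tt$statistic, df = tt$df, p_value = tt$p_value)
}

#' Test observed against WCS-predicted dyad slopes
#'
#' Paired t-test of each dyad's fitted slope against its WCS-predicted
#' slope `(s_1 + s_2) / sqrt(2)`.  A non-significant result means the
#' confidence-sharing prediction is consistent with the cohort.
#'
#' @param s_observed,s_predicted Equal-length numeric vectors of observed
#'   and predicted dyad slopes.
#' @return A one-row tibble: `n`, `mean_diff`, `statistic`, `df`,
#'   `p_value`.
#' @export
compare_observed_vs_wcs <- function(s_observed, s_predicted) {
  if (length(s_observed) != length(s_predicted) || length(s_observed) < 2) {
    stop("need two equal-length vectors with at least 2 dyads.",
         call. = FALSE)
  }
  tt <- one_sample_t(s_observed - s_predicted)
  tibble::tibble(n = length(s_observed),
                 mean_diff = mean(s_observed - s_predicted),
                 statistic = tt$statistic, df = tt$df, p_value = tt$p_value)
}

#' Regress dyad improvement on the member sensitivity ratio
#'
#' Ordinary least squares of `improvement = s_dyad / s_max` on
#' `ratio = s_min / s_max` across dyads.  Under unweighted confidence
#' sharing both slope and intercept equal `sqrt(2)/2`; a flatter fitted
#' slope with the same intercept is the signature of over-weighting the
#' better member.  The over-weighting factor `gamma` is therefore also
#' estimated by least squares with the intercept fixed at `sqrt(2)/2`:
#' `gamma_hat = sum(r * (y - sqrt(2)/2)) / (sqrt(2)/2 * sum(r^2))`.
#'
#' @param summaries A tibble of [dyad_summary()] rows; needs at least 3
#'   dyads and a non-constant ratio.
#' @return A list of class `improvement_regression`: `n`, `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `r_squared`, `f_statistic`,
#'   `df`, `p_value`, `gamma`, and the underlying `lm` fit.
#' @export
improvement_regression <- function(summaries) {
  if (nrow(summaries) < 3L) {
    stop("need at least 3 dyads for the regression.", call. = FALSE)
  }
  r <- summaries$ratio
  y <- summaries$improvement
  if (stats::sd(r) == 0) {
    stop("degenerate design: all sensitivity ratios identical.",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ r)
  sm <- summary(fit)
  co <- sm$coefficients
  fstat <- sm$fstatistic
  gamma <- sum(r * (y - sqrt(2) / 2)) / (sqrt(2) / 2 * sum(r^2))
  structure(
    list(n = length(r),
         slope = unname(co["r", "Estimate"]),
         slope_se = unname(co["r", "Std. Error"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         intercept_se = unname(co["(Intercept)", "Std. Error"]),
         r_squared = sm$r.squared,
         f_statistic = unname(fstat[1]),
         df = unname(c(fstat[2], fstat[3])),
         p_value = stats::pf(fstat[1], fstat[2], fstat[3],
                             lower.tail = FALSE),
         gamma = gamma,
         lm_fit = fit),
    class = "improvement_regression"
  )
}

#' @export
print.improvement_regression <- function(x, ...) {
  cat("<improvement_regression> n =", x$n, "\n",
      sprintf("  slope     = %.4f +/- %.4f\n", x$slope, x$slope_se),
      sprintf("  intercept = %.4f +/- %.4f\n", x$intercept, x$intercept_se),
      sprintf("  R^2 = %.3f, F(%d,%d) = %.2f, p = %.4g\n", x$r_squared,
              x$df[1], x$df[2], x$f_statistic, x$p_value),
      sprintf("  over-weighting gamma = %.4f\n", x$gamma), sep = "")
  invisible(x)
}

#' Simulate and analyse a whole cohort of dyads
#'
#' Runs the complete analysis chain on a synthetic cohort: for each dyad
#' it simulates an experiment ([run_experiment()]), fits individual and
#' dyad psychometric functions, forms the WCS prediction and the dyad
#' summary; it then computes the cohort statistics (similar- and
#' different-class dyad-vs-best t-tests, observed-vs-WCS slope test,
#' improvement-vs-ratio regression with the over-weighting estimate) and
#' the haptic leadership analyses (predictor accuracies over the 1C
#' threshold sweep, velocity ratios).  Fully reproducible from `seed`.
#'
#' Member noise levels are drawn per dyad from a lognormal distribution
#' truncated to `sigma_range`, which yields a realistic spread of member
#' sensitivity ratios; a matrix of fixed noise levels can be supplied
#' instead via `sigmas`.
#'
#' @param n_dyads Number of dyads in the cohort.
#' @param n_blocks Blocks per dyad experiment.
#' @param group_model Group-decision rule used by the simulator.
#' @param seed Integer seed for the whole pipeline.
#' @param sigma_meanlog,sigma_sdlog,sigma_range Lognormal parameters and
#'   truncation bounds (contrast-percent) for the per-member noise draw.
#' @param bias_sd Standard deviation of the per-member bias draw.
#' @param fit_method Psychometric fitting criterion, see
#'   [fit_psychometric()].
#' @param sigmas Optional `n_dyads x 2` matrix of member noise levels,
#'   overriding the random draw.
#' @param thresholds First-crossing threshold sweep.
#' @return A list of class `cohort_result`: `summaries` (per-dyad
#'   tibble), `tests` (tibble of t-test rows), `regression`,
#'   `predictor_report`, `velocity` and `settings`.
#' @examples
#' \donttest{
#' res <- run_pipeline(n_dyads = 4, n_blocks = 4, seed = 1)
#' res$tests
#' }
#' @export
run_pipeline <- function(n_dyads = 19, n_blocks = 8, group_model = "WCS",
                         seed = 1, sigma_meanlog = log(7),
                         sigma_sdlog = 0.5, sigma_range = c(3, 20),
                         bias_sd = 1, fit_method = "least_squares",
                         sigmas = NULL,
                         thresholds = c(0.05, 0.08, 0.10, 0.15, 0.20,
                                        0.25, 0.30)) {
  if (n_dyads < 1) stop("`n_dyads` must be >= 1.", call. = FALSE)
  set.seed(seed)

  if (is.null(sigmas)) {
    draw <- function() {
      s <- stats::rlnorm(1, sigma_meanlog, sigma_sdlog)
      while (s < sigma_range[1] || s > sigma_range[2]) {
        s <- stats::rlnorm(1, sigma_meanlog, sigma_sdlog)
      }
      s
    }
    sigmas <- matrix(replicate(2 * n_dyads, draw()), ncol = 2)
  } else {
    sigmas <- as.matrix(sigmas)
    if (nrow(sigmas) != n_dyads || ncol(sigmas) != 2) {
      stop("`sigmas` must be an n_dyads x 2 matrix.", call. = FALSE)
    }
  }

  summaries <- list()
  all_trials <- list()
  all_traj <- list()
  s_obs <- s_wcs <- numeric(n_dyads)

  for (d in seq_len(n_dyads)) {
    id <- sprintf("dyad%02d", d)
    cfg <- sim_config(
      n_blocks = n_blocks,
      observers = list(
        observer_params(bias_b = stats::rnorm(1, 0, bias_sd),
                        sigma = sigmas[d, 1]),
        observer_params(bias_b = stats::rnorm(1, 0, bias_sd),
                        sigma = sigmas[d, 2])
      ),
      group_model = group_model, seed = NULL
    )
    exp <- run_experiment(cfg, dyad_id = id)
    fit0 <- fit_psychometric(bin_choices(exp$trials, "member_0"), fit_method)
    fit1 <- fit_psychometric(bin_choices(exp$trials, "member_1"), fit_method)
    fitd <- fit_psychometric(bin_choices(exp$trials, "dyad"), fit_method)
    pred <- wcs_predict(fit0, fit1)
    row <- dyad_summary(fit0, fit1, fitd)
    row$dyad_id <- id
    row$sigma_0 <- fit0$sigma
    row$sigma_1 <- fit1$sigma
    row$b_0 <- fit0$bias_b
    row$b_1 <- fit1$bias_b
    row$s_wcs <- pred$s_dyad
    summaries[[d]] <- row
    s_obs[d] <- fitd$slope_s
    s_wcs[d] <- pred$s_dyad
    all_trials[[d]] <- exp$trials
    all_traj[[d]] <- exp$trajectories
  }
  summaries <- dplyr::bind_rows(summaries)
  trials <- dplyr::bind_rows(all_trials)
  trajectories <- dplyr::bind_rows(all_traj)

  safe_test <- function(expr) {
    tryCatch(expr, error = function(e) {
      tibble::tibble(class = NA_character_, n = NA_integer_,
                     mean_diff = NA_real_, statistic = NA_real_,
                     df = NA_real_, p_value = NA_real_,
                     note = conditionMessage(e))
    })
  }
  t_sim <- safe_test(compare_dyad_vs_best(summaries, "similar"))
  t_dif <- safe_test(compare_dyad_vs_best(summaries, "different"))
  t_wcs <- compare_observed_vs_wcs(s_obs, s_wcs)
  t_wcs$class <- "observed_vs_wcs"
  tests <- dplyr::bind_rows(
    dplyr::mutate(t_sim, test = "dyad_vs_best"),
    dplyr::mutate(t_dif, test = "dyad_vs_best"),
    dplyr::mutate(t_wcs, test = "observed_vs_wcs")
  )

  regression <- if (n_dyads >= 3 && stats::sd(summaries$ratio) > 0) {
    improvement_regression(summaries)
  } else NULL

  predictor_report <- predictor_accuracy(trials, trajectories,
                                         thresholds = thresholds)
  velocity <- velocity_ratios(trials, trajectories,
                              reference_threshold = min(thresholds))

  structure(
    list(summaries = summaries, tests = tests, regression = regression,
         predictor_report = predictor_report, velocity = velocity,
         settings = list(n_dyads = n_dyads, n_blocks = n_blocks,
                         group_model = group_model, seed = seed,
                         fit_method = fit_method,
                         classification_threshold = 0.4,
                         thresholds = thresholds)),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", x$settings$n_dyads, " dyads, ",
      x$settings$n_blocks, " blocks, model ", x$settings$group_model,
      ", seed ", x$settings$seed, "\n", sep = "")
  ns <- sum(x$summaries$similarity_class == "similar")
  cat("  similar/different:", ns, "/",
      nrow(x$summaries) - ns, "\n")
  print(x$tests)
  if (!is.null(x$regression)) print(x$regression)
  cat("  velocity ratios (L, F vs dyad):",
      sprintf("%.4f / %.4f", x$velocity$means["ratio_leader"],
              x$velocity$means["ratio_follower"]), "\n")
  invisible(x)
}
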