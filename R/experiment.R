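#' Run a full synthetic dyad experiment
#'
#' Generates a balanced stimulus schedule, simulates both members'
#' individual decisions, resolves disagreements with the configured
#' group-decision model and synthesises one coupled-handle trajectory per
#' disagreement trial.  The whole run is reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()] object.
#' @param dyad_id Identifier stored in the output tables.
#'
#' @return A list of class `dyad_experiment` with elements
#' * `trials` — tibble, one row per trial: the schedule columns plus
#'   `choice_0`, `choice_1`, `confidence_0`, `confidence_1`, `rt_0`,
#'   `rt_1`, `agreed`, `group_choice` (`NA` on agreement trials) and
#'   `group_correct`;
#' * `trajectories` — long tibble (`dyad_id`, `block`, `trial`, `t`,
#'   `x0`, `x1`, `f0`, `f1`) holding the group-phase trajectories of the
#'   disagreement trials.
#' @examples
#' exp <- run_experiment(sim_config(n_blocks = 2, seed = 1))
#' mean(exp$trials$agreed)
#' @export
run_experiment <- function(cfg, dyad_id = "dyad01") {
  if (!inherits(cfg, "sim_config")) {
    stop("`cfg` must be a `sim_config` object.", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  sched <- make_schedule(cfg$n_blocks, cfg$oddball_contrast_levels,
                         cfg$baseline_contrast, seed = NULL)
  m0 <- simulate_individual(sched$delta_c, cfg$observers[[1]])
  m1 <- simulate_individual(sched$delta_c, cfg$observers[[2]])

  trials <- sched
  trials$dyad_id <- dyad_id
  trials$choice_0 <- m0$choice
  trials$choice_1 <- m1$choice
  trials$confidence_0 <- m0$confidence
  trials$confidence_1 <- m1$confidence
  trials$rt_0 <- m0$rt
  trials$rt_1 <- m1$rt
  trials$agreed <- m0$choice == m1$choice
  trials$group_choice <- NA_character_

  dis <- which(!trials$agreed)
  if (length(dis) > 0) {
    trials$group_choice[dis] <- simulate_group_choice(
      m0$confidence[dis], m1$confidence[dis],
      cfg$observers[[1]]$sigma, cfg$observers[[2]]$sigma,
      model = cfg$group_model
    )
  }
  final <- ifelse(trials$agreed, trials$choice_0, trials$group_choice)
  trials$group_correct <- final == trials$oddball_interval
  trials <- trials[, c("dyad_id", "block", "trial", "oddball_interval",
                       "oddball_contrast", "baseline_contrast", "delta_c",
                       "choice_0", "choice_1", "confidence_0", "confidence_1",
                       "rt_0", "rt_1", "agreed", "group_choice",
                       "group_correct")]

  trajs <- lapply(dis, function(i) {
    tr <- simulate_trajectory(trials[i, ], cfg)
    tr$dyad_id <- dyad_id
    tr$block <- trials$block[i]
    tr$trial <- trials$trial[i]
    tr[, c("dyad_id", "block", "trial", "t", "x0", "x1", "f0", "f1")]
  })
  trajectories <- if (length(trajs) > 0) {
    dplyr::bind_rows(trajs)
  } else {
    tibble::tibble(dyad_id = character(), block = integer(),
                   trial = integer(), t = numeric(), x0 = numeric(),
                   x1 = numeric(), f0 = numeric(), f1 = numeric())
  }

  structure(list(trials = tibble::as_tibble(trials),
                 trajectories = trajectories, config = cfg),
            class = "dyad_experiment")
}

#' @export
print.dyad_experiment <- function(x, ...) {
  n <- nrow(x$trials)
  nd <- sum(!x$trials$agreed)
  cat("<dyad_experiment> ", unique(x$trials$dyad_id), ": ", n, " trials, ",
      nd, " disagreements (", sprintf("%.1f%%", 100 * nd / n), "), model ",
      x$config$group_model, "\n", sep = "")
  invisible(x)
}

#' Read and write experiment tables
#'
#' Plain-CSV round trip for the per-trial decision log and the long-format
#' trajectory log (UTF-8, `.` decimal separator, fixed headers), so
#' simulated cohorts can be exchanged with, or replaced by, externally
#' recorded data in the same layout.
#'
#' @param trials,trajectories Tibbles in the layout produced by
#'   [run_experiment()].
#' @param path File path.
#' @return The readers return tibbles; the writers return `path`
#'   invisibly.
#' @name experiment_io
NULL

#' @rdname experiment_io
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname experiment_io
#' @export
read_trials <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' @rdname experiment_io
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname experiment_io
#' @export
read_trajectories <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}
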