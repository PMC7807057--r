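#' Balanced stimulus schedule for a two-interval oddball experiment
#'
#' Builds the trial list for a blocked 2AFC contrast-oddball experiment.
#' Within every block, each combination of oddball timing (first or second
#' interval) and oddball contrast level appears exactly twice, in an order
#' shuffled independently per block, so a block holds
#' `2 x 2 x length(levels)` trials.
#'
#' The signed contrast difference `delta_c` is the contrast of the second
#' interval minus that of the first at the oddball location, expressed in
#' contrast-percent: `+(level - baseline) * 100` when the oddball is in the
#' second interval and the negative of that when it is in the first, so a
#' positive `delta_c` means the correct answer is "second".
#'
#' @param n_blocks Number of blocks (positive integer).
#' @param levels Oddball contrast levels as fractions; defaults to the
#'   standard 11.5%, 13.5%, 17% and 25%.
#' @param baseline Baseline contrast fraction; must be below every level.
#' @param seed Optional integer seed for the shuffle; `NULL` uses the
#'   current RNG state.
#'
#' @return A tibble with one row per trial: `block`, `trial` (within
#'   block), `oddball_interval` ("first"/"second"), `oddball_contrast`,
#'   `baseline_contrast` and `delta_c`.
#' @examples
#' sched <- make_schedule(n_blocks = 1, seed = 1)
#' nrow(sched)        # 16 trials per block for the 4-level design
#' table(sched$delta_c)
#' @export
make_schedule <- function(n_blocks = 8,
                          levels = c(0.115, 0.135, 0.17, 0.25),
                          baseline = 0.10,
                          seed = NULL) {
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 1 ||
      n_blocks != round(n_blocks)) {
    stop("`n_blocks` must be a positive integer.", call. = FALSE)
  }
  if (length(levels) < 1L) stop("`levels` must be non-empty.", call. = FALSE)
  if (any(levels <= baseline)) {
    stop("`baseline` must be strictly below every oddball level ",
         "(otherwise delta_c degenerates to 0).", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  base <- expand.grid(oddball_interval = c("first", "second"),
                      oddball_contrast = levels,
                      rep = 1:2,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  per_block <- nrow(base)

  blocks <- lapply(seq_len(n_blocks), function(b) {
    idx <- sample.int(per_block)
    blk <- base[idx, c("oddball_interval", "oddball_contrast")]
    tibble::tibble(
      block = b,
      trial = seq_len(per_block),
      oddball_interval = blk$oddball_interval,
      oddball_contrast = blk$oddball_contrast,
      baseline_contrast = baseline,
      delta_c = ifelse(blk$oddball_interval == "second", 1, -1) *
        (blk$oddball_contrast - baseline) * 100
    )
  })
  dplyr::bind_rows(blocks)
}
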