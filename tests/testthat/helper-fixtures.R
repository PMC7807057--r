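# Shared fixture builders for the test suite.

paper_levels <- c(-15, -7, -3.5, -1.5, 1.5, 3.5, 7, 15)

# Binned choices generated exactly from the cumulative-Gaussian model.
exact_binned <- function(b, sigma, levels = paper_levels, n_total = 1000) {
  tibble::tibble(
    delta_c = levels,
    n_second = pnorm((levels + b) / sigma) * n_total,
    n_total = n_total
  )
}

# Binomial choices sampled from the model (counts, not proportions).
sampled_binned <- function(b, sigma, levels = paper_levels, n_per_level = 200) {
  tibble::tibble(
    delta_c = levels,
    n_second = rbinom(length(levels), n_per_level,
                      pnorm((levels + b) / sigma)),
    n_total = n_per_level
  )
}

# A bounded random-walk trajectory starting at the origin, for the
# first-crossing oracle checks.
random_walk_traj <- function(n = 120, step_sd = 0.08) {
  walk <- function() {
    x <- cumsum(rnorm(n, 0, step_sd))
    pmin(pmax(x, -1), 1)
  }
  tibble::tibble(t = seq(0, by = 0.01, length.out = n),
                 x0 = c(0, walk()[-n]), x1 = c(0, walk()[-n]),
                 f0 = rnorm(n, 0, 0.1), f1 = rnorm(n, 0, 0.1))
}

# Brute-force first-crossing oracle: scan every sample in order and apply
# the tie rules literally.
first_crossing_oracle <- function(traj, threshold) {
  for (k in seq_len(nrow(traj))) {
    o0 <- abs(traj$x0[k]) > threshold
    o1 <- abs(traj$x1[k]) > threshold
    if (o0 || o1) {
      member <- if (o0 && o1) {
        if (abs(traj$x0[k]) >= abs(traj$x1[k])) 0L else 1L
      } else if (o0) 0L else 1L
      x <- if (member == 0L) traj$x0[k] else traj$x1[k]
      return(list(side = if (x > 0) "right" else "left",
                  member = member, sample_index = k))
    }
  }
  NULL
}

# Small default experiment used by several feature tests.
demo_experiment <- function(seed = 99, n_blocks = 40,
                            sigma = c(5, 7), bias = c(0, 0)) {
  cfg <- sim_config(
    n_blocks = n_blocks,
    observers = list(observer_params(bias_b = bias[1], sigma = sigma[1]),
                     observer_params(bias_b = bias[2], sigma = sigma[2])),
    seed = seed
  )
  run_experiment(cfg)
}
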