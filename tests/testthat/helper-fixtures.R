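# deterministic hand-built inventory: n_samples x reps spectra on a small grid
tiny_inventory <- function(n_samples = 2, n_channels = 16, reps = 3) {
  grid <- seq(1000, 1000 + 10 * (n_channels - 1), by = 10)
  meta <- data.frame(sample_id = sprintf("T%02d", seq_len(n_samples)),
                     day = rep(c(7L, 28L), length.out = n_samples),
                     is_control = FALSE,
                     mper = rep(c(FALSE, TRUE), length.out = n_samples),
                     hav = FALSE, bmp9 = FALSE, tgfb1 = FALSE)
  key <- expand.grid(replicate = seq_len(reps), sample_id = meta$sample_id,
                     stringsAsFactors = FALSE)[c("sample_id", "replicate")]
  key <- key[order(key$sample_id, key$replicate), ]
  X <- outer(seq_len(nrow(key)), seq_len(n_channels),
             function(i, j) sin(i + j / 3) + 0.1 * i)
  nir_inventory(grid, meta, X, key)
}

# a small feasible study-like design for fast workflow tests
small_cfg <- function(seed = 1L, n_missing = 0L, n_controls = 2L) {
  generator_config(
    day7_counts = joint_counts_from_marginals(16, mper = 5, hav = 8, bmp9 = 6, tgfb1 = 4),
    day28_counts = joint_counts_from_marginals(12, mper = 4, hav = 6, bmp9 = 5, tgfb1 = 3),
    n_controls_per_day = n_controls, replicates = 3L,
    n_missing_replicates = n_missing, seed = seed)
}

small_grid <- function(n = 64) seq(1000, 2400, length.out = n)

# independent Savitzky-Golay oracle: least-squares quadratic in each
# 13-point window, analytic first derivative evaluated at the centre
# (edges: first/last full window evaluated at the edge positions)
sg_oracle <- function(y, window = 13L) {
  half <- (window - 1L) %/% 2L
  n <- length(y)
  deriv_at <- function(win, pos) {
    i <- seq_along(win)
    co <- stats::coef(stats::lm(win ~ i + I(i^2)))
    unname(co[2] + 2 * co[3] * pos)
  }
  out <- numeric(n)
  for (j in seq_len(n)) {
    if (j <= half) {
      out[j] <- deriv_at(y[1:window], j)
    } else if (j > n - half) {
      out[j] <- deriv_at(y[(n - window + 1):n], j - (n - window))
    } else {
      out[j] <- deriv_at(y[(j - half):(j + half)], half + 1L)
    }
  }
  out
}
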