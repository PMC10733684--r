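#' Default synthetic wavelength grid
#'
#' 256 channels spanning 943.8-2491 nm, the range of the diffuse-reflectance
#' probe the study design assumes.
#'
#' @return numeric vector of length 256.
#' @export
default_grid <- function() seq(943.8, 2491, length.out = 256)

# nonneg integer matrix with given row/column sums: proportional seed,
# residual filled north-west corner (always feasible)
allocate_two_way <- function(row_m, col_m) {
  if (sum(row_m) != sum(col_m)) abort("margin totals differ: %d vs %d", sum(row_m), sum(col_m))
  n <- sum(row_m)
  M <- if (n > 0) floor(outer(row_m, col_m) / n) else outer(row_m, col_m) * 0
  r <- row_m - rowSums(M)
  s <- col_m - colSums(M)
  for (i in seq_along(r)) {
    for (j in seq_along(s)) {
      add <- min(r[i], s[j])
      M[i, j] <- M[i, j] + add
      r[i] <- r[i] - add
      s[j] <- s[j] - add
    }
  }
  M
}

#' Build joint design cell counts from per-day marginals
#'
#' The study design table reports only per-constituent marginals by
#' incubation day. This helper fits a feasible joint allocation over
#' (HAV x growth factor x M-PER) cells by sequential proportional fitting:
#' proportional seeding of each two-way table followed by a deterministic
#' residual fill, so every marginal is met exactly.
#'
#' @param n total samples for the day.
#' @param mper,hav,bmp9,tgfb1 counts of samples carrying each constituent.
#' @return a 2 x 3 x 2 integer array with dimensions `hav` (no/yes),
#'   `gf` (none/bmp9/tgfb1) and `mper` (no/yes).
#' @export
joint_counts_from_marginals <- function(n, mper, hav, bmp9, tgfb1) {
  for (nm in c("mper", "hav", "bmp9", "tgfb1")) {
    v <- get(nm)
    if (v < 0 || v > n) abort("infeasible marginal: %s = %d with n = %d", nm, v, n)
  }
  if (bmp9 + tgfb1 > n) {
    abort("infeasible marginal: bmp9 + tgfb1 = %d exceeds n = %d (growth factors are exclusive)",
          bmp9 + tgfb1, n)
  }
  hav_gf <- allocate_two_way(c(n - hav, hav), c(n - bmp9 - tgfb1, bmp9, tgfb1))
  cells <- allocate_two_way(as.vector(hav_gf), c(n - mper, mper))
  array(cells, dim = c(2, 3, 2),
        dimnames = list(hav = c("no", "yes"), gf = c("none", "bmp9", "tgfb1"),
                        mper = c("no", "yes")))
}

# the published per-day marginals of the study design
study_marginals <- function() {
  list(day7  = list(n = 41L, mper = 11L, hav = 24L, bmp9 = 22L, tgfb1 = 14L),
       day28 = list(n = 28L, mper = 10L, hav = 16L, bmp9 = 12L, tgfb1 = 7L))
}

#' Synthetic roster configuration
#'
#' Joint design cell counts for the two incubation days plus control and
#' replicate settings. The defaults reproduce the study design exactly:
#' 69 test constructs (41 at Day 7, 28 at Day 28) whose per-constituent
#' marginals match the published distribution, 6 control samples per day,
#' 3 technical replicates per sample, and 2 samples with one missing
#' replicate.
#'
#' @param day7_counts,day28_counts 2 x 3 x 2 arrays as produced by
#'   [joint_counts_from_marginals()]; defaults reproduce the study design.
#' @param n_controls_per_day controls per incubation day (default 6).
#' @param replicates technical replicates per sample (default 3).
#' @param n_missing_replicates samples rendered with one replicate fewer
#'   (default 2).
#' @param seed root seed for spectra rendering.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(day7_counts = NULL, day28_counts = NULL,
                             n_controls_per_day = 6L, replicates = 3L,
                             n_missing_replicates = 2L, seed = 1L) {
  m <- study_marginals()
  day7_counts <- day7_counts %||% do.call(joint_counts_from_marginals, m$day7)
  day28_counts <- day28_counts %||% do.call(joint_counts_from_marginals, m$day28)
  for (a in list(day7_counts, day28_counts)) {
    if (!is.array(a) || !identical(dim(a), c(2L, 3L, 2L))) {
      abort("day counts must be 2 x 3 x 2 arrays (hav x gf x mper)")
    }
    if (any(a < 0)) abort("negative design cell count")
  }
  if (replicates < 1L) abort("replicates must be >= 1")
  n_test <- sum(day7_counts) + sum(day28_counts)
  if (n_missing_replicates > n_test) {
    abort("n_missing_replicates = %d exceeds the %d non-control samples",
          n_missing_replicates, n_test)
  }
  structure(list(day7_counts = day7_counts, day28_counts = day28_counts,
                 n_controls_per_day = as.integer(n_controls_per_day),
                 replicates = as.integer(replicates),
                 n_missing_replicates = as.integer(n_missing_replicates),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Spectral effect model for the synthetic generator
#'
#' Phenomenological model of the NIR spectra: a scaffold baseline built from
#' Gaussian bands, a broadband maturity component added to mature
#' (Day-28, cell-containing) constructs, one signature per non-neotissue
#' constituent, and three noise terms (smooth per-replicate baseline drift,
#' a per-replicate offset, and iid channel noise). The default M-PER
#' signature is a single strong band centred at 1050 nm; the HAV, BMP-9 and
#' TGF-beta1 signatures are low-amplitude sums of three broad bands spanning
#' the grid, at least five times weaker than M-PER. Amplitudes are in the
#' same arbitrary reflectance units as the baseline.
#'
#' @param base_offset,base_bands scaffold baseline: constant offset plus
#'   Gaussian bands (data.frame with columns center, width, weight, in nm
#'   for center/width).
#' @param maturity_amplitude,maturity_bands the Day-28 spectral shift.
#' @param maturity_sample_cv coefficient of variation of the per-sample
#'   maturity amplitude (construct development is heterogeneous; some
#'   mature constructs barely differ from immature ones). Draws are
#'   truncated at zero.
#' @param signatures named list (`mper`, `hav`, `bmp9`, `tgfb1`) of
#'   `list(amplitude =, bands =)` components.
#' @param replicate_noise_sd sd of the per-replicate intensity offset.
#' @param channel_noise_sd sd of iid per-channel noise.
#' @param baseline_drift_sd sd of the smooth per-replicate drift
#'   coefficients.
#' @return a list of class `effect_model`.
#' @export
effect_model <- function(
    base_offset = 0.2,
    base_bands = data.frame(center = c(1150, 1450, 1930),
                            width = c(200, 80, 90),
                            weight = c(0.15, 0.30, 0.40)),
    maturity_amplitude = 0.05,
    maturity_sample_cv = 0.4,
    maturity_bands = data.frame(center = c(1510, 2280),
                                width = c(120, 100),
                                weight = c(1, 0.8)),
    signatures = list(
      mper = list(amplitude = 0.05,
                  bands = data.frame(center = 1050, width = 25, weight = 1)),
      bmp9 = list(amplitude = 0.010,
                  bands = data.frame(center = c(1100, 1750, 2350),
                                     width = c(260, 320, 300),
                                     weight = c(1, 0.6, -0.8))),
      tgfb1 = list(amplitude = 0.005,
                   bands = data.frame(center = c(980, 1500, 2100),
                                      width = c(240, 310, 290),
                                      weight = c(-0.6, 1, 0.7))),
      hav = list(amplitude = 0.004,
                 bands = data.frame(center = c(1000, 1600, 2200),
                                    width = c(250, 300, 280),
                                    weight = c(1, -0.7, 0.5)))),
    replicate_noise_sd = 0.002,
    channel_noise_sd = 0.01,
    baseline_drift_sd = 0.005) {
  if (maturity_amplitude < 0) abort("maturity_amplitude must be >= 0")
  if (maturity_sample_cv < 0) abort("maturity_sample_cv must be >= 0")
  missing_sig <- setdiff(CONSTITUENTS, names(signatures))
  if (length(missing_sig) > 0) {
    abort("signatures missing for: %s", paste(missing_sig, collapse = ", "))
  }
  for (nm in CONSTITUENTS) {
    if (signatures[[nm]]$amplitude < 0) abort("%s amplitude must be >= 0", nm)
  }
  for (sd_ in c(replicate_noise_sd, channel_noise_sd, baseline_drift_sd)) {
    if (sd_ < 0) abort("noise standard deviations must be >= 0")
  }
  structure(list(base_offset = base_offset, base_bands = base_bands,
                 maturity_amplitude = maturity_amplitude,
                 maturity_sample_cv = maturity_sample_cv,
                 maturity_bands = maturity_bands,
                 signatures = signatures,
                 replicate_noise_sd = replicate_noise_sd,
                 channel_noise_sd = channel_noise_sd,
                 baseline_drift_sd = baseline_drift_sd),
            class = "effect_model")
}

gaussian_mixture <- function(grid, bands) {
  shape <- numeric(length(grid))
  for (i in seq_len(nrow(bands))) {
    shape <- shape + bands$weight[i] *
      exp(-((grid - bands$center[i]) / bands$width[i])^2 / 2)
  }
  shape
}

#' Generate a sample roster matching the study design
#'
#' Expands the joint design cell counts into per-sample metadata
#' (deterministic, no randomness is needed at the roster stage) and appends
#' the control samples: cell-free, growth-factor-free, unconjugated
#' constructs stored in PBS, half incubated 7 days and half 28 days.
#'
#' @param cfg a [generator_config()].
#' @param grid wavelength grid for the (still empty) inventory.
#' @return a metadata-only [nir_inventory()] with the configuration attached
#'   as attribute `"config"`.
#' @export
generate_roster <- function(cfg = generator_config(), grid = default_grid()) {
  stopifnot(inherits(cfg, "generator_config"))
  one_day <- function(counts, day) {
    rows <- list()
    k <- 0L
    for (h in 1:2) for (g in 1:3) for (mp in 1:2) {
      n_cell <- counts[h, g, mp]
      if (n_cell == 0) next
      for (r in seq_len(n_cell)) {
        k <- k + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("S%02d_%03d", day, k), day = day,
          is_control = FALSE, mper = mp == 2L, hav = h == 2L,
          bmp9 = g == 2L, tgfb1 = g == 3L)
      }
    }
    do.call(rbind, rows)
  }
  meta <- rbind(one_day(cfg$day7_counts, 7L), one_day(cfg$day28_counts, 28L))
  if (cfg$n_controls_per_day > 0) {
    ctrl <- do.call(rbind, lapply(c(7L, 28L), function(day) {
      data.frame(sample_id = sprintf("C%02d_%03d", day, seq_len(cfg$n_controls_per_day)),
                 day = day, is_control = TRUE, mper = FALSE, hav = FALSE,
                 bmp9 = FALSE, tgfb1 = FALSE)
    }))
    meta <- rbind(meta, ctrl)
  }
  if (is.null(meta)) abort("empty design: all cell counts are zero and no controls requested")
  roster <- nir_inventory(grid, meta)
  attr(roster, "config") <- cfg
  roster
}

#' Render synthetic spectra for a roster
#'
#' Each sample receives `replicates` spectra equal to the scaffold baseline,
#' plus the maturity component for Day-28 cell-containing samples (controls
#' keep the immature baseline), plus the signature of every constituent the
#' sample carries, plus per-replicate smooth baseline drift, a per-replicate
#' offset, and iid channel noise. A seeded draw marks
#' `n_missing_replicates` non-control samples, which are rendered with one
#' replicate fewer. Deterministic given the seed.
#'
#' @param roster a metadata-only inventory from [generate_roster()].
#' @param eff an [effect_model()].
#' @param seed integer seed; sub-streams are derived per stage.
#' @return an [nir_inventory()] with spectra.
#' @export
render_spectra <- function(roster, eff = effect_model(), seed = 1L) {
  stopifnot(inherits(roster, "nir_inventory"), inherits(eff, "effect_model"))
  cfg <- attr(roster, "config") %||% generator_config(n_missing_replicates = 0L)
  grid <- roster$grid
  meta <- roster$meta
  base <- eff$base_offset + gaussian_mixture(grid, eff$base_bands)
  maturity_shape <- gaussian_mixture(grid, eff$maturity_bands)
  sig <- lapply(eff$signatures[CONSTITUENTS], function(s) {
    s$amplitude * gaussian_mixture(grid, s$bands)
  })

  missing_ids <- character(0)
  if (cfg$n_missing_replicates > 0) {
    candidates <- meta$sample_id[!meta$is_control]
    set.seed(derive_seed(seed, "missing-replicates"))
    missing_ids <- sort(sample(candidates, cfg$n_missing_replicates))
  }

  t_grid <- seq(-1, 1, length.out = length(grid))
  set.seed(derive_seed(seed, "render"))
  keys <- list()
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    mu <- base
    # maturity scale drawn for every sample so the stream is stable; it
    # only acts on mature, cell-containing constructs
    mat_scale <- max(stats::rnorm(1, 1, eff$maturity_sample_cv), 0)
    if (meta$day[i] == 28L && !meta$is_control[i]) {
      mu <- mu + eff$maturity_amplitude * mat_scale * maturity_shape
    }
    for (nm in CONSTITUENTS) if (meta[[nm]][i]) mu <- mu + sig[[nm]]
    n_rep <- cfg$replicates - (meta$sample_id[i] %in% missing_ids)
    for (r in seq_len(cfg$replicates)) {
      drift_coef <- stats::rnorm(3, 0, eff$baseline_drift_sd)
      drift <- drift_coef[1] + drift_coef[2] * t_grid +
        drift_coef[3] * (2 * t_grid^2 - 1)
      offset <- stats::rnorm(1, 0, eff$replicate_noise_sd)
      noise <- stats::rnorm(length(grid), 0, eff$channel_noise_sd)
      if (r > n_rep) next  # draws still consumed: missingness never shifts others
      rows[[length(rows) + 1L]] <- mu + drift + offset + noise
      keys[[length(keys) + 1L]] <- data.frame(sample_id = meta$sample_id[i],
                                              replicate = r)
    }
  }
  inv <- nir_inventory(grid, meta, do.call(rbind, rows), do.call(rbind, keys))
  attr(inv, "config") <- cfg
  inv
}

#' Generate a complete synthetic dataset
#'
#' Composes [generate_roster()] and [render_spectra()]; deterministic given
#' `cfg$seed`.
#'
#' @inheritParams generate_roster
#' @inheritParams render_spectra
#' @return an [nir_inventory()] with spectra.
#' @export
generate_dataset <- function(cfg = generator_config(), eff = effect_model()) {
  render_spectra(generate_roster(cfg), eff, cfg$seed)
}
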