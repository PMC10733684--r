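test_that("the default roster reproduces every cell of the study design", {
  r <- generate_roster()
  m <- r$meta[!r$meta$is_control, ]
  expect_equal(nrow(m), 69L)
  expect_equal(sum(m$day == 7), 41L)
  expect_equal(sum(m$day == 28), 28L)
  published <- list(
    mper = c(`7` = 11, `28` = 10), hav = c(`7` = 24, `28` = 16),
    bmp9 = c(`7` = 22, `28` = 12), tgfb1 = c(`7` = 14, `28` = 7))
  for (f in names(published)) {
    for (d in c(7, 28)) {
      expect_equal(sum(m[[f]][m$day == d]), unname(published[[f]][as.character(d)]),
                   info = paste(f, d))
    }
  }
  expect_false(any(m$bmp9 & m$tgfb1))
  ctrl <- r$meta[r$meta$is_control, ]
  expect_equal(nrow(ctrl), 12L)
  expect_equal(sum(ctrl$day == 7), 6L)
  expect_false(any(ctrl$mper | ctrl$hav | ctrl$bmp9 | ctrl$tgfb1))
})

test_that("roster marginals equal any configured cell counts", {
  set.seed(31)
  for (i in 1:5) {
    n7 <- sample(8:20, 1); n28 <- sample(6:15, 1)
    mk <- function(n) {
      b <- sample(0:(n %/% 2), 1); t <- sample(0:(n - b), 1)
      joint_counts_from_marginals(n, sample(0:n, 1), sample(0:n, 1), b, t)
    }
    c7 <- mk(n7); c28 <- mk(n28)
    ros <- generate_roster(generator_config(day7_counts = c7, day28_counts = c28,
                                            n_missing_replicates = 0, seed = i))
    m <- ros$meta[!ros$meta$is_control, ]
    count_cells <- function(mm) {
      out <- array(0L, dim = c(2, 3, 2))
      gf <- ifelse(mm$bmp9, 2L, ifelse(mm$tgfb1, 3L, 1L))
      for (k in seq_len(nrow(mm))) {
        idx <- cbind(mm$hav[k] + 1L, gf[k], mm$mper[k] + 1L)
        out[idx] <- out[idx] + 1L
      }
      out
    }
    expect_equal(count_cells(m[m$day == 7, ]), array(as.integer(c7), dim(c7)))
    expect_equal(count_cells(m[m$day == 28, ]), array(as.integer(c28), dim(c28)))
  }
})

test_that("infeasible marginals are rejected with the violated margin named", {
  expect_error(joint_counts_from_marginals(10, mper = 11, hav = 2, bmp9 = 2, tgfb1 = 2),
               "mper")
  expect_error(joint_counts_from_marginals(10, mper = 2, hav = 2, bmp9 = 6, tgfb1 = 6),
               "bmp9 \\+ tgfb1")
})

test_that("a minimal design yields one test sample plus controls", {
  counts <- array(0L, dim = c(2, 3, 2))
  counts0 <- counts; counts0[1, 1, 1] <- 1L
  ros <- generate_roster(generator_config(day7_counts = counts0, day28_counts = counts,
                                          n_missing_replicates = 0, seed = 1))
  expect_equal(nrow(ros$meta), 1L + 12L)
  expect_equal(sum(!ros$meta$is_control), 1L)
})

test_that("null effects give identical spectra equal to the base curve", {
  eff <- effect_model(maturity_amplitude = 0, maturity_sample_cv = 0,
                      replicate_noise_sd = 0, channel_noise_sd = 0,
                      baseline_drift_sd = 0)
  for (f in c("mper", "hav", "bmp9", "tgfb1")) eff$signatures[[f]]$amplitude <- 0
  inv0 <- render_spectra(generate_roster(small_cfg(seed = 4)), eff, seed = 4)
  expect_equal(max(apply(inv0$spectra, 2, function(col) diff(range(col)))), 0)
})

test_that("rendering is deterministic in the seed and respects replicate settings", {
  cfg <- small_cfg(seed = 9, n_missing = 2L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$spectra, b$spectra)
  expect_false(identical(generate_dataset(small_cfg(seed = 10, n_missing = 2L))$spectra,
                         a$spectra))
  # exactly two non-control samples short one replicate
  reps <- table(factor(a$key$sample_id, levels = a$meta$sample_id))
  short <- names(reps)[reps == 2]
  expect_length(short, 2L)
  expect_false(any(a$meta$is_control[a$meta$sample_id %in% short]))
  expect_true(all(reps %in% c(2L, 3L)))
  # single-replicate configuration
  one <- generate_dataset(generator_config(
    day7_counts = small_cfg()$day7_counts, day28_counts = small_cfg()$day28_counts,
    replicates = 1L, n_missing_replicates = 0L, seed = 2))
  expect_true(all(table(one$key$sample_id) == 1L))
})

test_that("the M-PER signature is localized to 1000-1100 nm after preprocessing", {
  inv <- generate_dataset(generator_config(seed = 3))
  avg <- average_replicates(preprocess_inventory(inv))
  d <- colMeans(avg$spectra[avg$meta$mper, , drop = FALSE]) -
    colMeans(avg$spectra[!avg$meta$mper, , drop = FALSE])
  peak_nm <- avg$grid[which.max(abs(d))]
  expect_gte(peak_nm, 1000)
  expect_lte(peak_nm, 1100)
  # and it dominates the subtle signatures by construction
  eff <- effect_model()
  others <- sapply(c("hav", "bmp9", "tgfb1"), function(f) eff$signatures[[f]]$amplitude)
  expect_gte(eff$signatures$mper$amplitude, 5 * max(others))
})
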