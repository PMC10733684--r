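test_that("inventory round-trips exactly through CSV", {
  inv <- tiny_inventory()
  sp <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  write_inventory(inv, sp, md)
  back <- read_inventory(sp, md)
  expect_identical(back$grid, inv$grid)
  expect_identical(back$meta, inv$meta)
  expect_identical(back$key, inv$key)
  expect_equal(back$spectra, inv$spectra, tolerance = 0)
})

test_that("wide-format spectra are accepted and equal the long form", {
  inv <- tiny_inventory(n_samples = 2, n_channels = 5)
  sp <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  write_inventory(inv, sp, md)
  wide <- cbind(inv$key, as.data.frame(inv$spectra))
  names(wide)[-(1:2)] <- format(inv$grid)
  wide_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wide, wide_path, row.names = FALSE)
  expect_equal(read_inventory(wide_path, md)$spectra, inv$spectra,
               tolerance = 1e-12)
})

test_that("reader validates metadata and keys with informative errors", {
  inv <- tiny_inventory()
  sp <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  write_inventory(inv, sp, md)

  # a sample with a missing replicate is accepted
  partial <- inv
  drop <- which(partial$key$sample_id == "T01" & partial$key$replicate == 3L)
  partial$spectra <- partial$spectra[-drop, , drop = FALSE]
  partial$key <- partial$key[-drop, , drop = FALSE]
  write_inventory(partial, sp, md)
  got <- read_inventory(sp, md)
  expect_equal(sum(got$key$sample_id == "T01"), 2L)

  # invalid incubation day names the sample
  bad_meta <- utils::read.csv(md)
  bad_meta$day[1] <- 14L
  utils::write.csv(bad_meta, md, row.names = FALSE)
  expect_error(read_inventory(sp, md), "day must be 7 or 28.*T01")

  # duplicated (sample, replicate, wavelength) key is rejected by name
  write_inventory(inv, sp, md)
  tab <- utils::read.csv(sp)
  utils::write.csv(rbind(tab, tab[1, ]), sp, row.names = FALSE)
  expect_error(read_inventory(sp, md), "duplicated.*T01")

  # unknown sample ids are dropped with a warning
  write_inventory(inv, sp, md)
  tab <- utils::read.csv(sp)
  tab$sample_id[tab$sample_id == "T02"] <- "GHOST"
  utils::write.csv(tab, sp, row.names = FALSE)
  expect_warning(got <- read_inventory(sp, md), "GHOST")
  expect_false("GHOST" %in% got$key$sample_id)

  # non-numeric intensity is named
  write_inventory(inv, sp, md)
  tab <- utils::read.csv(sp, colClasses = "character")
  tab$intensity[5] <- "oops"
  utils::write.csv(tab, sp, row.names = FALSE, quote = FALSE)
  expect_error(read_inventory(sp, md), "non-numeric intensity.*oops")
})

test_that("metadata invariants are enforced", {
  inv <- tiny_inventory()
  m <- inv$meta
  m$bmp9[1] <- TRUE; m$tgfb1[1] <- TRUE
  expect_error(nir_inventory(inv$grid, m, inv$spectra, inv$key), "bmp9 and tgfb1")
  m <- inv$meta
  m$is_control[2] <- TRUE; m$hav[2] <- TRUE
  expect_error(nir_inventory(inv$grid, m, inv$spectra, inv$key), "control samples")
  expect_error(nir_inventory(rev(inv$grid), inv$meta, inv$spectra, inv$key),
               "strictly increasing")
})

test_that("replicate averaging is the channel-wise arithmetic mean", {
  inv <- tiny_inventory(n_samples = 1, n_channels = 8, reps = 1)
  expect_equal(average_replicates(inv)$spectra, inv$spectra)

  inv2 <- tiny_inventory(n_samples = 1, n_channels = 8, reps = 2)
  inv2$spectra[1, ] <- 0
  inv2$spectra[2, ] <- 2
  expect_equal(as.vector(average_replicates(inv2)$spectra), rep(1, 8))

  set.seed(11)
  inv3 <- tiny_inventory(n_samples = 3, n_channels = 12, reps = 3)
  inv3$spectra <- matrix(rnorm(length(inv3$spectra)), nrow(inv3$spectra))
  avg <- average_replicates(inv3)
  for (s in inv3$meta$sample_id) {
    rows <- inv3$key$sample_id == s
    expect_equal(avg$spectra[avg$meta$sample_id == s, ],
                 colSums(inv3$spectra[rows, , drop = FALSE]) / 3,
                 tolerance = 1e-12)
  }
})

test_that("zero-variance channels are found exactly and the drop is idempotent", {
  set.seed(5)
  inv <- tiny_inventory(n_samples = 4, n_channels = 256, reps = 2)
  inv$spectra <- matrix(rnorm(length(inv$spectra)), nrow(inv$spectra))
  const_at <- c(5L, 100L, 200L)
  inv$spectra[, const_at] <- rep(c(0.7, -1, 3), each = nrow(inv$spectra))
  res <- drop_zero_variance_channels(inv)
  brute <- which(apply(inv$spectra, 2, function(col) length(unique(col)) > 1))
  expect_identical(res$kept, brute)
  expect_equal(length(res$kept), 253L)
  # idempotent
  res2 <- drop_zero_variance_channels(res$inventory)
  expect_identical(res2$kept, seq_len(253L))
  expect_equal(res2$inventory$spectra, res$inventory$spectra)
  # no-op case keeps everything
  clean <- tiny_inventory(n_samples = 2, n_channels = 16)
  expect_identical(drop_zero_variance_channels(clean)$kept, 1:16)
  # degenerate dataset
  flat <- clean
  flat$spectra[] <- 1
  expect_error(drop_zero_variance_channels(flat), "every channel is constant")
})

test_that("missing replicates are filled by duplicating the first replicate", {
  inv <- tiny_inventory(n_samples = 2, n_channels = 8, reps = 3)
  drop <- which(inv$key$sample_id == "T01" & inv$key$replicate == 3L)
  inv$spectra <- inv$spectra[-drop, , drop = FALSE]
  inv$key <- inv$key[-drop, , drop = FALSE]
  out <- impute_missing_replicates(inv, target_count = 3L)
  rows <- which(out$key$sample_id == "T01")
  expect_length(rows, 3L)
  first <- out$spectra[out$key$sample_id == "T01" & out$key$replicate == 1L, ]
  added <- out$spectra[out$key$sample_id == "T01" & out$key$replicate == 3L, ]
  expect_equal(added, first)
  # complete samples untouched
  expect_equal(out$spectra[out$key$sample_id == "T02", ],
               inv$spectra[inv$key$sample_id == "T02", ])
  # count audit on the full synthetic design: 2 incomplete of 81 -> 81 * 3
  ds <- generate_dataset(generator_config(seed = 21))
  expect_equal(nrow(ds$spectra), 81L * 3L - 2L)
  filled <- impute_missing_replicates(ds, 3L)
  expect_equal(nrow(filled$spectra), 81L * 3L)
  before <- table(factor(ds$key$sample_id, levels = ds$meta$sample_id))
  after <- table(factor(filled$key$sample_id, levels = filled$meta$sample_id))
  expect_equal(sum(before != after), 2L)
})
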