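test_that("uncontrolled arms follow the aliasing rule and reject empty arms", {
  ros <- generate_roster(small_cfg())
  arms <- build_uncontrolled_training(ros, "mper")
  m <- ros$meta[!ros$meta$is_control, ]
  expect_setequal(arms$day28_ids, m$sample_id[m$day == 28 & m$mper])
  expect_setequal(arms$day7_ids, m$sample_id[m$day == 7 & !m$mper])
  expect_false(any(ros$meta$sample_id[ros$meta$is_control] %in%
                     c(arms$day28_ids, arms$day7_ids)))
  # no Day-28 sample with the constituent -> error naming it
  ros2 <- ros
  ros2$meta$tgfb1[ros2$meta$day == 28] <- FALSE
  expect_error(build_uncontrolled_training(ros2, "tgfb1"), "tgfb1")
})

test_that("propensity scores reduce to cell proportions in saturated toys", {
  mk_meta <- function(day, mper) {
    data.frame(sample_id = sprintf("P%02d", seq_along(day)), day = day,
               is_control = FALSE, mper = mper, hav = FALSE, bmp9 = FALSE,
               tgfb1 = FALSE)
  }
  # flags identical for everyone -> every score equals the Day-28 prevalence
  meta <- mk_meta(rep(c(7L, 28L), c(6, 4)), rep(TRUE, 10))
  inv <- nir_inventory(small_grid(16), meta)
  expect_equal(unname(estimate_propensity(inv)), rep(0.4, 10), tolerance = 1e-9)

  # one varying covariate: fitted scores are the cell-wise Day-28 proportions
  meta2 <- mk_meta(rep(c(28L, 7L), each = 4),
                   c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  inv2 <- nir_inventory(small_grid(16), meta2)
  sc <- estimate_propensity(inv2)
  expect_equal(unname(sc[meta2$mper]), rep(0.75, 4), tolerance = 1e-6)
  expect_equal(unname(sc[!meta2$mper]), rep(0.25, 4), tolerance = 1e-6)

  # a constant flag column is non-informative
  meta3 <- meta2
  meta3$hav <- TRUE
  inv3 <- nir_inventory(small_grid(16), meta3)
  expect_equal(unname(estimate_propensity(inv3)), unname(sc), tolerance = 1e-8)
})

test_that("greedy nearest-neighbour matching is correct on worked examples", {
  sc <- c(t1 = 0.8, t2 = 0.6, c1 = 0.75, c2 = 0.5, c3 = 0.2)
  m <- match_nearest_neighbor(sc, c("t1", "t2"), c("c1", "c2", "c3"))
  expect_equal(m$pairs$day28_id, c("t1", "t2"))
  expect_equal(m$pairs$day7_id, c("c1", "c2"))
  expect_setequal(m$unmatched, "c3")

  # identical scores: all matched at distance zero
  sc2 <- stats::setNames(rep(0.5, 7), paste0("s", 1:7))
  m2 <- match_nearest_neighbor(sc2, paste0("s", 1:3), paste0("s", 4:7))
  expect_equal(nrow(m2$pairs), 3L)
  expect_equal(m2$pairs$distance, rep(0, 3))

  # more treated than controls: the excess goes unmatched
  sc3 <- stats::setNames(seq(0.1, 0.8, length.out = 8), paste0("u", 1:8))
  m3 <- match_nearest_neighbor(sc3, paste0("u", 1:5), paste0("u", 6:8))
  expect_equal(nrow(m3$pairs), 3L)
  expect_equal(sum(m3$unmatched %in% paste0("u", 1:5)), 2L)

  # a tight caliper refuses distant pairs
  sc4 <- c(a = 0.9, b = 0.1)
  m4 <- match_nearest_neighbor(sc4, "a", "b", max_distance = 0.5)
  expect_equal(nrow(m4$pairs), 0L)
  expect_setequal(m4$unmatched, c("a", "b"))
})

test_that("the controlled training set is day-balanced and duplicate-free", {
  ros <- generate_roster(small_cfg())
  meta <- ros$meta[!ros$meta$is_control, ]
  sc <- estimate_propensity(ros)
  m <- match_nearest_neighbor(sc, meta$sample_id[meta$day == 28],
                              meta$sample_id[meta$day == 7])
  ids <- build_controlled_training(m)
  expect_equal(length(ids), 2L * nrow(m$pairs))
  expect_false(anyDuplicated(ids) > 0)
  days <- meta$day[match(ids, meta$sample_id)]
  expect_equal(sum(days == 28), sum(days == 7))
  empty <- m
  empty$pairs <- empty$pairs[0, ]
  expect_error(build_controlled_training(empty), "no matched pairs")
})

test_that("test sets are the complement of the training union, controls excluded", {
  ros <- generate_roster(small_cfg())
  meta <- ros$meta[!ros$meta$is_control, ]
  sc <- estimate_propensity(ros)
  m <- match_nearest_neighbor(sc, meta$sample_id[meta$day == 28],
                              meta$sample_id[meta$day == 7])
  keep <- order(m$pairs$distance, m$pairs$day28_id)[1:5]
  m$pairs <- m$pairs[keep, ]
  controlled <- build_controlled_training(m)
  for (con in c("mper", "hav", "bmp9", "tgfb1")) {
    part <- build_partition(ros, con, controlled)
    expect_length(intersect(part$test_ids, part$uncontrolled_train_ids), 0)
    expect_length(intersect(part$test_ids, part$controlled_train_ids), 0)
    expect_setequal(c(part$test_ids, union(part$uncontrolled_train_ids,
                                           part$controlled_train_ids)),
                    meta$sample_id)
    expect_false(any(ros$meta$sample_id[ros$meta$is_control] %in%
                       unlist(part[-1])))
  }
})
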