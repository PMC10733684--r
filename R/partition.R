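non_control_meta <- function(inv) inv$meta[!inv$meta$is_control, , drop = FALSE]

#' Build the deliberately confounded (uncontrolled) training arms
#'
#' The Day-28 arm takes every Day-28 sample carrying the constituent; the
#' Day-7 arm takes every Day-7 sample lacking it. Training on such a set
#' perfectly aliases the constituent with maturity, which is the confounded
#' design under study. Controls are excluded throughout.
#'
#' @param inv an [nir_inventory()].
#' @param constituent one of `"mper"`, `"hav"`, `"bmp9"`, `"tgfb1"`.
#' @return a list with `day28_ids` and `day7_ids`.
#' @export
build_uncontrolled_training <- function(inv, constituent) {
  if (!(constituent %in% CONSTITUENTS)) {
    abort("unknown constituent '%s'", constituent)
  }
  meta <- non_control_meta(inv)
  day28 <- meta$sample_id[meta$day == 28L & meta[[constituent]]]
  day7 <- meta$sample_id[meta$day == 7L & !meta[[constituent]]]
  if (length(day28) == 0) {
    abort("empty Day-28 arm: no Day-28 sample carries '%s'", constituent)
  }
  if (length(day7) == 0) {
    abort("empty Day-7 arm: every Day-7 sample carries '%s'", constituent)
  }
  list(day28_ids = day28, day7_ids = day7)
}

#' Estimate propensity scores
#'
#' Logistic regression of Day-28 membership on the four constituent flags,
#' fitted to the non-control samples. Under complete separation the fit
#' falls back to a ridge-penalized logistic model (with a message).
#'
#' @param inv an [nir_inventory()] whose non-control samples cover both
#'   incubation days.
#' @return named numeric vector of scores in (0, 1), one per non-control
#'   sample.
#' @export
estimate_propensity <- function(inv) {
  meta <- non_control_meta(inv)
  if (length(unique(meta$day)) < 2) {
    abort("propensity model needs non-control samples from both days")
  }
  meta$day28 <- meta$day == 28L
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(day28 ~ mper + hav + bmp9 + tgfb1, family = stats::binomial(),
               data = meta),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated) {
    message("complete separation in the propensity model; using a ridge-penalized fit")
    x <- as.matrix(meta[CONSTITUENTS]) * 1
    rf <- glmnet::glmnet(x, factor(meta$day28), family = "binomial",
                         alpha = 0, lambda = 0.01, standardize = FALSE)
    scores <- as.vector(predict(rf, x, type = "response"))
  } else {
    scores <- unname(stats::predict(fit, type = "response"))
  }
  stats::setNames(scores, meta$sample_id)
}

#' Nearest-neighbour propensity matching without replacement
#'
#' Greedy one-to-one matching of Day-28 (treated) to Day-7 (control)
#' samples on the logit of the propensity score: treated samples are
#' visited in descending propensity (ties by smallest id) and each takes
#' the unused control with the smallest absolute logit difference (ties by
#' smallest control id). With `max_distance` set, pairs farther apart than
#' the caliper are not formed.
#'
#' @param scores named propensity scores from [estimate_propensity()].
#' @param treated_ids,control_ids sample ids of the two groups.
#' @param max_distance optional caliper on the logit distance (default
#'   `NULL`: no caliper).
#' @return a list of class `match_result` with `pairs` (data.frame
#'   `day28_id`, `day7_id`, `distance`) and `unmatched` (ids of treated
#'   without an admissible partner plus unused controls).
#' @export
match_nearest_neighbor <- function(scores, treated_ids, control_ids,
                                   max_distance = NULL) {
  if (length(treated_ids) == 0 || length(control_ids) == 0) {
    abort("both treated and control groups must be non-empty")
  }
  missing_scores <- setdiff(c(treated_ids, control_ids), names(scores))
  if (length(missing_scores) > 0) {
    abort("no propensity score for: %s", paste(missing_scores, collapse = ", "))
  }
  lt <- stats::qlogis(scores[treated_ids])
  lc <- stats::qlogis(scores[control_ids])
  ord <- order(-lt, treated_ids)
  available <- rep(TRUE, length(control_ids))
  pairs <- list()
  unmatched_treated <- character(0)
  for (i in ord) {
    d <- abs(lt[i] - lc)
    d[!available] <- Inf
    j <- order(d, control_ids)[1]
    if (!is.finite(d[j]) || (!is.null(max_distance) && d[j] > max_distance)) {
      unmatched_treated <- c(unmatched_treated, treated_ids[i])
      next
    }
    available[j] <- FALSE
    pairs[[length(pairs) + 1L]] <- data.frame(
      day28_id = treated_ids[i], day7_id = control_ids[j], distance = unname(d[j]))
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(day28_id = character(0), day7_id = character(0),
               distance = numeric(0))
  structure(list(pairs = pairs,
                 unmatched = c(unmatched_treated, control_ids[available])),
            class = "match_result")
}

#' Controlled training set from matched pairs
#'
#' Union of both members of every retained pair: day-balanced by
#' construction.
#'
#' @param match a `match_result`.
#' @return character vector of sample ids.
#' @export
build_controlled_training <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (nrow(match$pairs) == 0) abort("no matched pairs: controlled training set is empty")
  c(match$pairs$day28_id, match$pairs$day7_id)
}

#' Shared test set for one constituent
#'
#' All non-control samples in neither the constituent's uncontrolled
#' training set nor the controlled training set. Replicates of the test
#' samples are averaged at evaluation time.
#'
#' @param inv an [nir_inventory()].
#' @param constituent the constituent being compared (bookkeeping).
#' @param uncontrolled_ids,controlled_ids training sample ids.
#' @return character vector of test sample ids.
#' @export
build_test_set <- function(inv, constituent, uncontrolled_ids, controlled_ids) {
  meta <- non_control_meta(inv)
  test_ids <- setdiff(meta$sample_id, union(uncontrolled_ids, controlled_ids))
  if (length(test_ids) == 0) {
    abort("empty test set for constituent '%s'", constituent)
  }
  test_ids
}

#' Full partition for one constituent
#'
#' Convenience wrapper assembling the uncontrolled arms, the controlled
#' (matched) training set and the shared test set into one specification.
#'
#' @inheritParams build_uncontrolled_training
#' @param controlled_ids controlled training ids (from
#'   [build_controlled_training()]).
#' @return a list of class `partition_spec` with `constituent`,
#'   `uncontrolled_train_ids`, `controlled_train_ids`, `test_ids`.
#' @export
build_partition <- function(inv, constituent, controlled_ids) {
  arms <- build_uncontrolled_training(inv, constituent)
  uncontrolled <- c(arms$day28_ids, arms$day7_ids)
  test_ids <- build_test_set(inv, constituent, uncontrolled, controlled_ids)
  structure(list(constituent = constituent,
                 uncontrolled_train_ids = uncontrolled,
                 controlled_train_ids = controlled_ids,
                 test_ids = test_ids),
            class = "partition_spec")
}
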