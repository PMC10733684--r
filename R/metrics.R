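#' Confusion matrix for a binary classifier
#'
#' @param truth logical vector (TRUE = positive class).
#' @param predicted logical vector of predicted labels.
#' @param positive_label name of the positive class (bookkeeping only).
#' @return a list of class `confusion_matrix` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(truth, predicted, positive_label = "positive") {
  truth <- as.logical(truth)
  predicted <- as.logical(predicted)
  if (length(truth) != length(predicted)) abort("truth and predicted lengths differ")
  structure(list(tp = sum(truth & predicted), fp = sum(!truth & predicted),
                 fn = sum(truth & !predicted), tn = sum(!truth & !predicted),
                 positive_label = positive_label),
            class = "confusion_matrix")
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2*tp / (2*tp + fp + fn)`. By
#' convention the score is 0 when there are no true positives but some
#' false calls; it is undefined (error) when tp, fp and fn are all zero.
#'
#' @param cm a [confusion_matrix()], or NULL if counts are given directly.
#' @param tp,fp,fn confusion counts (ignored when `cm` is supplied).
#' @return the F1 score in `[0, 1]`.
#' @export
f1_score <- function(cm = NULL, tp = NULL, fp = NULL, fn = NULL) {
  if (!is.null(cm)) {
    stopifnot(inherits(cm, "confusion_matrix"))
    tp <- cm$tp; fp <- cm$fp; fn <- cm$fn
  }
  if (tp < 0 || fp < 0 || fn < 0) abort("confusion counts must be non-negative")
  if (tp + fp + fn == 0) {
    abort("F1 undefined: no positives observed or predicted (tp = fp = fn = 0)")
  }
  2 * tp / (2 * tp + fp + fn)
}

#' AUC from positive and negative class scores
#'
#' Computed as the Mann-Whitney pair statistic: the proportion of
#' (positive, negative) score pairs ranked correctly, ties counted half.
#' Equivalent to trapezoidal integration of the ROC curve and exact under
#' ties.
#'
#' @param scores_pos scores of the positive-class samples.
#' @param scores_neg scores of the negative-class samples.
#' @return the AUC in `[0, 1]`.
#' @export
auc_score <- function(scores_pos, scores_neg) {
  n_pos <- length(scores_pos)
  n_neg <- length(scores_neg)
  if (n_pos == 0 || n_neg == 0) abort("both score groups must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# exact two-sided rank-sum p-value by enumeration of all subsets
# (midranks, so ties are handled exactly)
rank_sum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  sets <- utils::combn(length(pooled), length(x))
  w_all <- apply(sets, 2, function(ix) sum(r[ix]))
  mu <- mean(w_all)
  eps <- 1e-9
  mean(abs(w_all - mu) >= abs(w_obs - mu) - eps)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test of location difference between two score
#' sets. For combined sample sizes up to `exact_max_n` the p-value is
#' computed by exhaustive enumeration of rank assignments (with midranks,
#' so ties are exact); above that a normal approximation with tie and
#' continuity correction is used. When every value in both groups is
#' identical the p-value is 1 by convention. A Wilcoxon signed-rank variant
#' for paired scores is available behind `signed_rank = TRUE` as a
#' sensitivity analysis; the rank-sum form is the default used throughout
#' the pipeline.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param exact_max_n largest combined n for exact enumeration (default 12).
#' @param signed_rank use the paired signed-rank variant instead.
#' @return a list of class `nir_test` with `statistic` (rank sum of `x`),
#'   `p_value` and `mean_difference` (`mean(x) - mean(y)`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 12L, signed_rank = FALSE) {
  if (length(x) < 2 || length(y) < 2) abort("each group needs at least 2 values")
  if (signed_rank) {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                              correct = TRUE))
    return(structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                          mean_difference = mean(x) - mean(y),
                          ci95_low = NA_real_, ci95_high = NA_real_),
                     class = "nir_test"))
  }
  w <- sum(rank(c(x, y))[seq_along(x)])
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
  } else if (length(x) + length(y) <= exact_max_n) {
    p <- rank_sum_exact_p(x, y)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- ht$p.value
  }
  structure(list(statistic = w, p_value = p,
                 mean_difference = mean(x) - mean(y),
                 ci95_low = NA_real_, ci95_high = NA_real_),
            class = "nir_test")
}

#' Paired t-test on a vector of differences
#'
#' Two-sided one-sample t-test of the mean difference against zero, with a
#' 95% confidence interval; used to test the per-iteration F1 improvements
#' of the Monte Carlo comparison.
#'
#' @param differences numeric vector of paired differences (n >= 2, with
#'   positive variance).
#' @return a list of class `nir_test` with `statistic`, `p_value`,
#'   `mean_difference`, `ci95_low`, `ci95_high`.
#' @export
paired_t <- function(differences) {
  if (length(differences) < 2) abort("need at least 2 differences")
  if (stats::sd(differences) == 0) {
    abort("degenerate paired t-test: differences have zero variance")
  }
  ht <- stats::t.test(differences, conf.level = 0.95)
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 mean_difference = unname(ht$estimate),
                 ci95_low = ht$conf.int[1], ci95_high = ht$conf.int[2]),
            class = "nir_test")
}

#' @export
print.nir_test <- function(x, ...) {
  cat(sprintf("statistic = %.4g, p = %.4g, mean difference = %.4g",
              x$statistic, x$p_value, x$mean_difference))
  if (!is.na(x$ci95_low)) cat(sprintf(" (CI95: %.4g to %.4g)", x$ci95_low, x$ci95_high))
  cat("\n")
  invisible(x)
}
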