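#' Stratified k-fold test indices
#'
#' Partitions sample indices into `k` disjoint test folds whose class
#' proportions stay within one sample of the global proportion: each class
#' is shuffled and dealt into near-equal chunks, with remainder chunks
#' assigned from opposite ends for the two classes so fold sizes stay
#' balanced.
#'
#' @param labels logical (or two-level) vector of class labels.
#' @param k number of folds (default 10).
#' @param seed integer seed for the within-class shuffles.
#' @return a list of `k` integer vectors covering `seq_along(labels)`.
#' @export
stratified_kfold_indices <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) abort("k must be at least 2")
  if (k > n) abort("k = %d exceeds the %d samples", k, n)
  labels <- as.factor(labels)
  set.seed(seed)
  folds <- vector("list", k)
  for (ci in seq_along(levels(labels))) {
    idx <- which(labels == levels(labels)[ci])
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    sizes <- rep(base, k)
    if (extra > 0) {
      # alternate which folds take the remainder per class
      take <- if (ci %% 2 == 1) seq_len(extra) else k + 1L - seq_len(extra)
      sizes[take] <- sizes[take] + 1L
    }
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (f in seq_len(k)) {
      if (sizes[f] > 0) folds[[f]] <- c(folds[[f]], idx[starts[f]:stops[f]])
    }
  }
  lapply(folds, sort)
}

#' Constituent detectability screen (Workflow A)
#'
#' Asks whether each non-neotissue constituent leaves a detectable imprint
#' on the spectra: for every (constituent, algorithm) pair, runs stratified
#' k-fold cross-validation on the replicate-averaged spectra (controls
#' included with their true flags), pools the out-of-fold predictions, and
#' reports one confusion matrix, F1 and AUC per pair. A constituent that is
#' constant across the inventory is skipped with a warning.
#'
#' @param inv a preprocessed [nir_inventory()] (derivative applied).
#' @param constituents constituent flags to screen.
#' @param algorithms algorithm names (default all nine).
#' @param k folds (default 10).
#' @param seed root seed; fold assignment and each fit get derived streams.
#' @return a list of class `nir_eval` with element `table`: a data.frame of
#'   (constituent, algorithm, AUC, F1, tp, fp, fn, tn).
#' @export
run_workflow_a <- function(inv, constituents = CONSTITUENTS,
                           algorithms = algorithm_names(), k = 10L, seed = 1L) {
  avg <- average_replicates(inv)
  X <- avg$spectra
  rows <- list()
  for (con in constituents) {
    y <- avg$meta[[con]]
    if (length(unique(y)) < 2) {
      warning(sprintf("constituent '%s' is constant across the inventory; skipped", con),
              call. = FALSE)
      next
    }
    folds <- stratified_kfold_indices(y, k = k, seed = derive_seed(seed, con, "folds"))
    for (alg in algorithms) {
      scores <- numeric(length(y))
      classes <- logical(length(y))
      for (f in seq_along(folds)) {
        test_idx <- folds[[f]]
        spec <- make_algorithm(alg, derive_seed(seed, con, alg, f))
        model <- fit_classifier(spec, X[-test_idx, , drop = FALSE], y[-test_idx])
        scores[test_idx] <- predict_scores(model, X[test_idx, , drop = FALSE])
        classes[test_idx] <- predict_classes(model, X[test_idx, , drop = FALSE])
      }
      cm <- confusion_matrix(y, classes, positive_label = con)
      rows[[length(rows) + 1L]] <- data.frame(
        constituent = con, algorithm = alg,
        AUC = auc_score(scores[y], scores[!y]),
        F1 = f1_score(cm), tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
    }
  }
  structure(list(table = do.call(rbind, rows)), class = "nir_eval")
}

#' @export
print.nir_eval <- function(x, ...) {
  cat("<nir_eval> pooled out-of-fold metrics\n")
  print(x$table[c("constituent", "algorithm", "AUC", "F1")], digits = 3)
  invisible(x)
}
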