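# replicate-level training matrix and per-sample averaged test matrix
training_matrix <- function(inv, ids) {
  keep <- inv$key$sample_id %in% ids
  list(X = inv$spectra[keep, , drop = FALSE],
       y = inv$meta$day[match(inv$key$sample_id[keep], inv$meta$sample_id)] == 28L)
}

test_matrix <- function(inv, ids) {
  sub <- subset_inventory(inv, ids)
  avg <- average_replicates(sub)
  list(X = avg$spectra, y = avg$meta$day == 28L)
}

#' Controlled vs uncontrolled maturity models (Workflow B, step 1)
#'
#' For each constituent, trains one uncontrolled and one controlled model
#' per algorithm on replicate-level spectra and evaluates both on the same
#' test set (replicates averaged per sample), with Day-28 (mature) as the
#' positive class. The single controlled training set - both members of the
#' retained propensity-matched pairs - is shared across all four
#' comparisons; only the uncontrolled sets and hence the test sets vary.
#' Controls are excluded throughout. The performance differences per
#' metric are summarised as mean (controlled - uncontrolled) with a
#' Wilcoxon rank-sum p-value over the per-algorithm scores.
#'
#' Matching without an admissibility rule would pair every Day-28 sample
#' (Day-7 candidates outnumber them), leaving no mature samples for the
#' shared test sets, so the `n_pairs` closest pairs are retained; the
#' default of 10 reproduces the size of the study's controlled set.
#'
#' @param inv a preprocessed [nir_inventory()].
#' @param algorithms algorithm names (default all nine).
#' @param seed root seed.
#' @param n_pairs matched pairs retained for the controlled training set.
#' @param constituents constituents to compare.
#' @return a list of class `comparison_result` with elements `table`
#'   (per constituent x algorithm metrics), `summary` (mean differences and
#'   rank-sum p-values), `partitions`, and `match`.
#' @export
run_step1 <- function(inv, algorithms = algorithm_names(), seed = 1L,
                      n_pairs = 10L, constituents = CONSTITUENTS) {
  meta <- non_control_meta(inv)
  scores <- estimate_propensity(inv)
  match <- match_nearest_neighbor(scores,
                                  treated_ids = meta$sample_id[meta$day == 28L],
                                  control_ids = meta$sample_id[meta$day == 7L])
  keep <- order(match$pairs$distance, match$pairs$day28_id)
  keep <- keep[seq_len(min(n_pairs, nrow(match$pairs)))]
  match$pairs <- match$pairs[keep, , drop = FALSE]
  controlled_ids <- build_controlled_training(match)

  rows <- list()
  summaries <- list()
  partitions <- list()
  for (con in constituents) {
    part <- build_partition(inv, con, controlled_ids)
    partitions[[con]] <- part
    test <- test_matrix(inv, part$test_ids)
    tr_unc <- training_matrix(inv, part$uncontrolled_train_ids)
    tr_con <- training_matrix(inv, controlled_ids)
    for (alg in algorithms) {
      res <- lapply(list(controlled = tr_con, uncontrolled = tr_unc), function(tr) {
        spec <- make_algorithm(alg, derive_seed(seed, con, alg))
        model <- fit_classifier(spec, tr$X, tr$y)
        cm <- confusion_matrix(test$y, predict_classes(model, test$X), "day28")
        sc <- predict_scores(model, test$X)
        list(F1 = f1_score(cm), AUC = auc_score(sc[test$y], sc[!test$y]))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        constituent = con, algorithm = alg,
        F1_controlled = res$controlled$F1, F1_uncontrolled = res$uncontrolled$F1,
        AUC_controlled = res$controlled$AUC,
        AUC_uncontrolled = res$uncontrolled$AUC)
    }
    tab <- do.call(rbind, rows[(length(rows) - length(algorithms) + 1L):length(rows)])
    summaries[[con]] <- data.frame(
      constituent = con,
      F1_mean_difference = mean(tab$F1_controlled - tab$F1_uncontrolled),
      F1_p = wilcoxon_rank_sum(tab$F1_controlled, tab$F1_uncontrolled)$p_value,
      AUC_mean_difference = mean(tab$AUC_controlled - tab$AUC_uncontrolled),
      AUC_p = wilcoxon_rank_sum(tab$AUC_controlled, tab$AUC_uncontrolled)$p_value)
  }
  structure(list(table = do.call(rbind, rows),
                 summary = do.call(rbind, summaries),
                 partitions = partitions, match = match),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> controlled vs uncontrolled maturity models\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
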