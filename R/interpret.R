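#' Leave-one-out zero-fill feature importance
#'
#' For every feature of every view, the feature's scaled value is replaced
#' by zero for all test subjects, latents are re-extracted, predictions are
#' re-made and the test mean absolute error is recomputed. The importance
#' delta is `MAE(zero-filled) - MAE(baseline)`: features whose removal hurts
#' prediction most rank first. Zero-filling happens in the scaled \[0, 1\]
#' space (0 is the training minimum) because the model only ever sees scaled
#' inputs.
#'
#' @param params trained `mvae_params`.
#' @param head fitted `mv_head` regression head.
#' @param test_views named list of scaled test-view matrices.
#' @param y_test observed phenotype for the test subjects.
#' @param top_k rows to keep in the `top` summary (default 15).
#' @return list of class `importance_ranking` with `ranking` (data frame:
#'   `view`, `feature`, `baseline_mae`, `zeroed_mae`, `delta`, sorted by
#'   decreasing delta over all features of all views), `top` (head of the
#'   ranking) and `baseline_mae`.
#' @export
loo_importance <- function(params, head, test_views, y_test, top_k = 15) {
  stopifnot(inherits(params, "mvae_params"), inherits(head, "mv_head"))
  n <- nrow(test_views[[1]])
  assert_that(n >= 1, "empty test set")
  assert_that(length(y_test) == n, "y_test must match the test views")
  baseline_mae <- evaluate_predictions(
    y_test, predict_head(head, extract_latents(params, test_views)))$mae
  rows <- vector("list", length(test_views))
  for (vi in seq_along(test_views)) {
    vname <- names(test_views)[vi]
    x <- test_views[[vname]]
    p <- ncol(x)
    feats <- colnames(x) %||% paste0(vname, "_f", seq_len(p))
    deltas <- numeric(p)
    for (j in seq_len(p)) {
      zv <- test_views
      xz <- x
      xz[, j] <- 0
      zv[[vname]] <- xz
      mae_j <- evaluate_predictions(
        y_test, predict_head(head, extract_latents(params, zv)))$mae
      deltas[j] <- mae_j - baseline_mae
    }
    rows[[vi]] <- data.frame(view = vname, feature = feats,
                             baseline_mae = baseline_mae,
                             zeroed_mae = baseline_mae + deltas,
                             delta = deltas, stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$delta), ]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking,
                 top = utils::head(ranking, top_k),
                 baseline_mae = baseline_mae),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("importance_ranking: %d features, baseline MAE %.4g\n",
              nrow(x$ranking), x$baseline_mae))
  print(x$top)
  invisible(x)
}
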