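#' Misprediction diagnostics report
#'
#' Two complementary views of why nonredundant pairs get predicted as
#' redundant. (1) Every feature receives a separation score
#' ([separation_score()]) locating the mispredicted nonredundant pairs
#' between the correctly predicted nonredundant and redundant groups;
#' features whose score is close to 1 and whose ensemble importance rank
#' is high are flagged as likely drivers of mispredictions. (2) A PCA
#' (per-feature z-scored) over the correctly and incorrectly predicted
#' nonredundant pairs summarizes which features differ between them; the
#' top contributors to Dimension 1 are listed by absolute loading.
#'
#' When no nonredundant pair is mispredicted the report is returned empty
#' with an explanation (too few instances to characterize). Redundant
#' pairs predicted nonredundant are not analyzed here for the same
#' small-sample reason.
#'
#' @param x feature matrix (engineered columns; rows = pairs).
#' @param actual logical actual labels (`TRUE` = redundant).
#' @param predicted logical predicted labels.
#' @param importance importance table from [feature_importance()].
#' @param score_threshold separation-score flag cutoff (default 0.9).
#' @param rank_threshold importance-rank flag cutoff (default 10).
#' @param top_k number of Dimension-1 contributors to list (default 24).
#' @return object of class `misprediction_report`: list with `empty`,
#'   `separation` (feature, score, undefined, importance_rank, flagged),
#'   `prop_score_one` (fraction of defined scores equal to 1), `pca`
#'   (explained-variance fractions, loadings, `top_dim1` contributors), and
#'   group sizes.
#' @export
misprediction_report <- function(x, actual, predicted, importance,
                                 score_threshold = 0.9, rank_threshold = 10,
                                 top_k = 24) {
  x <- as.matrix(x)
  actual <- as.logical_label(actual)
  predicted <- as.logical_label(predicted)
  n_mis <- sum(!actual & predicted)
  if (n_mis == 0) {
    return(structure(
      list(empty = TRUE,
           reason = "no mispredicted nonredundant pairs to characterize",
           n_groups = c(correct_nr = sum(!actual & !predicted),
                        mispredicted_nr = 0L,
                        correct_rd = sum(actual & predicted))),
      class = "misprediction_report"
    ))
  }

  sep <- separation_score(x, actual, predicted)
  sep$importance_rank <- importance$rank[match(sep$feature, importance$feature)]
  sep$flagged <- !sep$undefined &
    !is.na(sep$importance_rank) &
    sep$score >= score_threshold &
    sep$importance_rank <= rank_threshold
  defined <- sep$score[!sep$undefined]
  prop_one <- mean(defined == 1)

  # PCA over all nonredundant pairs (correct + mispredicted), z-scored
  nr_idx <- which(!actual)
  xnr <- x[nr_idx, , drop = FALSE]
  keep <- apply(xnr, 2, stats::var) > 0
  z <- scale(xnr[, keep, drop = FALSE])
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  load1 <- p$rotation[, 1]
  top <- order(-abs(load1))[seq_len(min(top_k, length(load1)))]
  pca <- list(
    explained = expl,
    loadings = p$rotation[, seq_len(min(5, ncol(p$rotation))), drop = FALSE],
    scores = p$x[, seq_len(min(5, ncol(p$x))), drop = FALSE],
    mispredicted = predicted[nr_idx],
    top_dim1 = data.frame(feature = names(load1)[top],
                          loading = unname(load1[top]), row.names = NULL)
  )

  structure(
    list(empty = FALSE, separation = sep, prop_score_one = prop_one,
         pca = pca,
         n_groups = c(correct_nr = sum(!actual & !predicted),
                      mispredicted_nr = n_mis,
                      correct_rd = sum(actual & predicted))),
    class = "misprediction_report"
  )
}

#' @export
print.misprediction_report <- function(x, ...) {
  if (x$empty) {
    cat("misprediction_report: empty -", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("misprediction_report: %d mispredicted NR pairs; %d/%d features flagged\n",
              x$n_groups[["mispredicted_nr"]], sum(x$separation$flagged),
              nrow(x$separation)))
  cat(sprintf("separation score == 1 for %.1f%% of defined features\n",
              100 * x$prop_score_one))
  cat(sprintf("PCA of NR pairs: Dim1 %.1f%%, Dim2 %.1f%% of variance\n",
              100 * x$pca$explained[1], 100 * x$pca$explained[2]))
  invisible(x)
}

#' Write misprediction report tables to TSV
#'
#' @param report a `misprediction_report`.
#' @param sep_path path for the per-feature separation table.
#' @param pca_path path for the Dimension-1 contribution table.
#' @export
write_misprediction_report <- function(report, sep_path, pca_path) {
  if (report$empty) stop("report is empty: ", report$reason)
  utils::write.table(report$separation, sep_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- data.frame(dimension = 1, report$pca$top_dim1)
  utils::write.table(out, pca_path, sep = "\t", quote = FALSE, row.names = FALSE)
}
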