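#' Fisher's exact test for a binary pair feature
#'
#' Binary pair features (counts in 0/1/2) are dichotomized as presence
#' (at least one gene has the property) versus absence, and tested against
#' the redundancy label with a two-sided Fisher's exact test. The effect
#' size is the cross-product odds ratio of the 2x2 enrichment table, with
#' a 0.5 continuity correction applied (and flagged) when any cell is
#' empty.
#'
#' @param values numeric vector of pair counts (0/1/2) or 0/1 indicators.
#' @param labels logical or two-level factor; `TRUE` (or the second level)
#'   is the redundant class.
#' @return list with `odds_ratio`, `p`, `table` (the 2x2 counts, and the
#'   full presence-level table as `"table_full"`), `corrected` (continuity
#'   correction used), `degenerate` (a margin was empty; `p = 1` and the
#'   odds ratio is undefined).
#' @export
fisher_binary <- function(values, labels) {
  labels <- as.logical_label(labels)
  present <- values >= 1
  tab <- table(factor(present, levels = c(TRUE, FALSE)),
               factor(labels, levels = c(TRUE, FALSE)),
               dnn = c("present", "redundant"))
  full <- table(factor(values), factor(labels, levels = c(TRUE, FALSE)))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(list(odds_ratio = NA_real_, p = 1, table = tab, table_full = full,
                corrected = FALSE, degenerate = TRUE))
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = unname(or), p = p, table = tab, table_full = full,
       corrected = corrected, degenerate = FALSE)
}

#' Wilcoxon rank-sum test for a continuous pair feature
#'
#' Tests whether feature values differ between redundant and nonredundant
#' pairs. The standardized effect size is `z / sqrt(n)`, where the z
#' statistic is recovered from the two-sided p-value via the standard
#' normal quantile and signed by the direction of the location shift
#' (positive when the redundant class has the higher values), and `n` is
#' the total sample size.
#'
#' @param values numeric vector.
#' @param labels logical or two-level factor; `TRUE`/second level =
#'   redundant.
#' @param exact use the exact null distribution? Default (`NULL`): exact
#'   for `n <= 25` without ties, normal approximation with tie correction
#'   otherwise.
#' @return list with `p`, `z`, `effect`, `direction` (`"redundant"` or
#'   `"nonredundant"`: which class has higher values; `"none"` for no
#'   shift), `n`.
#' @export
wilcoxon_continuous <- function(values, labels, exact = NULL) {
  labels <- as.logical_label(labels)
  x <- values[labels]
  y <- values[!labels]
  if (length(x) < 2 || length(y) < 2) {
    stop("wilcoxon_continuous needs at least 2 observations per class")
  }
  n <- length(values)
  if (length(unique(values)) == 1) {
    return(list(p = 1, z = 0, effect = 0, direction = "none", n = n))
  }
  if (is.null(exact)) exact <- n <= 25 && !anyDuplicated(values)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)
  )
  shift <- stats::median(x) - stats::median(y)
  if (shift == 0) shift <- mean(rank(values)[labels]) - mean(rank(values)[!labels])
  s <- sign(shift)
  p <- wt$p.value
  z <- s * stats::qnorm(pmax(p / 2, .Machine$double.xmin), lower.tail = FALSE)
  list(
    p = p, z = unname(z), effect = unname(z / sqrt(n)),
    direction = if (s > 0) "redundant" else if (s < 0) "nonredundant" else "none",
    n = n
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return q-values on the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# internal: coerce labels to logical with TRUE = redundant class
as.logical_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two levels")
  f == levels(f)[2]
}

#' Feature-class association table
#'
#' Runs the appropriate association test on every engineered column of a
#' pair feature matrix — Fisher's exact test for binary-count features,
#' Wilcoxon rank-sum for everything else — and applies Benjamini-Hochberg
#' correction across each test family.
#'
#' @param pf a `pair_features` object (or a numeric data.frame/matrix, in
#'   which case all columns are treated as continuous).
#' @param labels logical redundancy labels, one per pair.
#' @param alpha significance threshold on q (default 0.05).
#' @return data.frame with columns `feature`, `test`, `p`, `q`, `effect`
#'   (odds ratio or z/sqrt(n)), `direction`, `n`, `significant`.
#' @export
associate_features <- function(pf, labels, alpha = 0.05) {
  if (inherits(pf, "pair_features")) {
    x <- pf$features
    is_binary <- pf$metadata$data_type == "binary" &
      pf$metadata$transform == "identity"
  } else {
    x <- as.data.frame(pf)
    is_binary <- rep(FALSE, ncol(x))
  }
  labels <- as.logical_label(labels)
  stopifnot(length(labels) == nrow(x))
  rows <- lapply(seq_len(ncol(x)), function(j) {
    if (is_binary[j]) {
      f <- fisher_binary(x[[j]], labels)
      dirn <- if (f$degenerate || is.na(f$odds_ratio)) "none"
        else if (f$odds_ratio > 1) "redundant" else if (f$odds_ratio < 1) "nonredundant" else "none"
      data.frame(feature = colnames(x)[j], test = "fisher", p = f$p,
                 effect = f$odds_ratio, direction = dirn, n = length(labels))
    } else {
      w <- wilcoxon_continuous(x[[j]], labels)
      data.frame(feature = colnames(x)[j], test = "wilcoxon", p = w$p,
                 effect = w$effect, direction = w$direction, n = w$n)
    }
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (tst in unique(res$test)) {
    sel <- res$test == tst
    res$q[sel] <- bh_adjust(res$p[sel])
  }
  res$significant <- res$q < alpha
  res[, c("feature", "test", "p", "q", "effect", "direction", "n", "significant")]
}

#' Feature separation score for misprediction diagnostics
#'
#' Locates mispredicted nonredundant pairs between the two correctly
#' predicted groups on each feature's scale:
#' `(Med_mispredictedNR - Med_correctNR) / (Med_correctRD - Med_correctNR)`.
#' A score of 0 means mispredicted nonredundant pairs look like correctly
#' predicted nonredundant pairs; 1 means they look like redundant pairs.
#'
#' @param values numeric vector (one feature) or matrix/data.frame
#'   (features in columns).
#' @param actual logical actual labels (`TRUE` = redundant).
#' @param predicted logical predicted labels.
#' @return data.frame with `feature`, `score`, `undefined` (denominator
#'   zero: the feature does not separate the correctly predicted classes).
#' @export
separation_score <- function(values, actual, predicted) {
  x <- as.matrix(values)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  actual <- as.logical_label(actual)
  predicted <- as.logical_label(predicted)
  g_nr <- !actual & !predicted   # correct NR
  g_mis <- !actual & predicted   # NR predicted redundant
  g_rd <- actual & predicted     # correct redundant
  groups <- c(
    "correctly predicted nonredundant" = sum(g_nr),
    "mispredicted nonredundant" = sum(g_mis),
    "correctly predicted redundant" = sum(g_rd)
  )
  if (any(groups == 0)) {
    stop("empty group(s): ", paste(names(groups)[groups == 0], collapse = ", "))
  }
  med <- function(sel) apply(x[sel, , drop = FALSE], 2, stats::median)
  m_nr <- med(g_nr); m_mis <- med(g_mis); m_rd <- med(g_rd)
  denom <- m_rd - m_nr
  score <- ifelse(denom == 0, NA_real_, (m_mis - m_nr) / denom)
  data.frame(feature = colnames(x), score = unname(score),
             undefined = unname(denom == 0), row.names = NULL)
}

#' Compare association results and importances across two definitions
#'
#' @param assoc_a,assoc_b association tables from [associate_features()]
#'   for two redundancy definitions.
#' @param importance_a,importance_b optional importance tables from
#'   [feature_importance()].
#' @param top_k size of the top sets for the shared-feature counts
#'   (default 20).
#' @return list with `spearman_logq` (Spearman rank correlation of
#'   `-log10(q)` over shared features), `pearson_importance_rank`,
#'   `shared_top_assoc`, `shared_top_importance`, `n_shared`.
#' @export
compare_definitions <- function(assoc_a, assoc_b,
                                importance_a = NULL, importance_b = NULL,
                                top_k = 20) {
  shared <- intersect(assoc_a$feature, assoc_b$feature)
  if (length(shared) == 0) stop("no shared features between the two association tables")
  qa <- -log10(pmax(assoc_a$q[match(shared, assoc_a$feature)], 1e-300))
  qb <- -log10(pmax(assoc_b$q[match(shared, assoc_b$feature)], 1e-300))
  rho <- stats::cor(qa, qb, method = "spearman")
  top <- function(tab, k) tab$feature[order(tab$q)][seq_len(min(k, nrow(tab)))]
  out <- list(
    spearman_logq = rho,
    n_shared = length(shared),
    shared_top_assoc = length(intersect(top(assoc_a, top_k), top(assoc_b, top_k)))
  )
  if (!is.null(importance_a) && !is.null(importance_b)) {
    sh <- intersect(importance_a$feature, importance_b$feature)
    if (length(sh) > 1) {
      ra <- importance_a$rank[match(sh, importance_a$feature)]
      rb <- importance_b$rank[match(sh, importance_b$feature)]
      out$pearson_importance_rank <- stats::cor(ra, rb, method = "pearson")
      ta <- importance_a$feature[order(importance_a$rank)][seq_len(min(top_k, nrow(importance_a)))]
      tb <- importance_b$feature[order(importance_b$rank)][seq_len(min(top_k, nrow(importance_b)))]
      out$shared_top_importance <- length(intersect(ta, tb))
    }
  }
  out
}

#' Write an association table to TSV
#'
#' @param assoc table from [associate_features()].
#' @param path output path.
#' @export
write_assoc_results <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
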