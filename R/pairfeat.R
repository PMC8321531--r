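#' Pair feature from a binary gene attribute
#'
#' The pair value is the number of genes in the pair (0, 1 or 2) carrying
#' the annotation/property.
#'
#' @param a,b 0/1 values for the two genes (vectorized).
#' @return integer count in `{0, 1, 2}`, symmetric in `(a, b)`.
#' @export
#' @examples
#' binary_pair_feature(1, 0) # 1
binary_pair_feature <- function(a, b) {
  ok <- function(v) all(is.na(v) | v %in% c(0, 1))
  if (!ok(a) || !ok(b)) {
    stop("binary pair feature requires 0/1 gene values")
  }
  as.integer(a + b)
}

#' Pair features from categorical annotation sets
#'
#' Summarizes the similarity of two annotation token sets: the number of
#' overlapping annotations, the total number of unique annotations in the
#' pair, and the percent overlap (100 * overlap / union; 0 when both sets
#' are empty).
#'
#' @param set_a,set_b character vectors of annotation tokens (possibly
#'   empty).
#' @return list with `n_overlap`, `n_union`, `pct_overlap`.
#' @export
#' @examples
#' categorical_overlap(c("DNA binding", "signal transduction"),
#'                     c("signal transduction", "protein binding"))
categorical_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a[!is.na(set_a) & nzchar(set_a)])
  set_b <- unique(set_b[!is.na(set_b) & nzchar(set_b)])
  n_overlap <- length(intersect(set_a, set_b))
  n_union <- length(union(set_a, set_b))
  list(
    n_overlap = n_overlap,
    n_union = n_union,
    pct_overlap = if (n_union == 0) 0 else 100 * n_overlap / n_union
  )
}

#' Pair features from a continuous gene attribute
#'
#' @param x,y numeric values for the two genes (vectorized); if either is
#'   missing all five outputs are missing.
#' @return data.frame with columns `diff` (absolute difference — pairs are
#'   unordered), `avg`, `max`, `min`, `total`; all symmetric in `(x, y)`.
#' @export
#' @examples
#' continuous_pair_features(10, 9) # isoelectric-point style example
continuous_pair_features <- function(x, y) {
  data.frame(
    diff = abs(x - y),
    avg = (x + y) / 2,
    max = pmax(x, y),
    min = pmin(x, y),
    total = x + y
  )
}

#' Assign values to four quartile bins
#'
#' Bin boundaries are the empirical 25/50/75% quantiles of `values` (or of
#' the training data, when frozen `breaks` are supplied). Values equal to a
#' boundary take the lower bin; missing values stay missing.
#'
#' @param values numeric vector (at least 4 non-missing values when breaks
#'   are computed from it).
#' @param breaks optional numeric length-3 vector of frozen boundaries.
#' @return integer bins in 1..4 with the boundaries attached as attribute
#'   `"breaks"`.
#' @export
quartile_bin <- function(values, breaks = NULL) {
  if (is.null(breaks)) {
    nm <- sum(!is.na(values))
    if (nm < 4) {
      stop("quartile binning needs at least 4 non-missing values")
    }
    if (length(unique(values[!is.na(values)])) < 4) {
      warning("fewer than 4 distinct values; some quartile bins will be empty")
    }
    breaks <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), na.rm = TRUE))
  }
  stopifnot(length(breaks) == 3)
  bins <- 1L + (values > breaks[1]) + (values > breaks[2]) + (values > breaks[3])
  structure(as.integer(bins), breaks = breaks)
}

#' Transform a numeric feature column
#'
#' Implements the square, log10, reciprocal and quartile-bin variants used
#' to expand each aggregated pair feature. Zero handling: a column
#' containing zeros uses `log10(x + delta)` with `delta` the smallest
#' positive value in the column; for the reciprocal, zeros are replaced by
#' the smallest positive value before inversion. Columns with negative
#' values (or no positive value at all, for log10/reciprocal) are not
#' transformable: the function warns and returns `NULL` so the column is
#' not emitted.
#'
#' @param values numeric vector.
#' @param kind one of `"square"`, `"log10"`, `"reciprocal"`,
#'   `"quartile_bin"`.
#' @param delta frozen zero-handling constant from a training run
#'   (log10/reciprocal), or `NULL` to compute it from `values`.
#' @param breaks frozen bin boundaries (quartile_bin), or `NULL`.
#' @return transformed vector with attribute `"delta"` or `"breaks"`, or
#'   `NULL` if the transform does not apply.
#' @export
transform_column <- function(values, kind = c("square", "log10", "reciprocal", "quartile_bin"),
                             delta = NULL, breaks = NULL) {
  kind <- match.arg(kind)
  if (kind == "square") {
    return(structure(values^2, delta = 0))
  }
  if (kind == "quartile_bin") {
    return(quartile_bin(values, breaks = breaks))
  }
  if (any(values < 0, na.rm = TRUE)) {
    warning(sprintf("%s transform skipped: column contains negative values", kind))
    return(NULL)
  }
  pos <- values[!is.na(values) & values > 0]
  if (is.null(delta)) {
    if (any(values == 0, na.rm = TRUE)) {
      if (length(pos) == 0) {
        warning(sprintf("%s transform skipped: column has no positive values", kind))
        return(NULL)
      }
      delta <- min(pos)
    } else {
      delta <- 0
    }
  }
  if (kind == "log10") {
    out <- log10(values + delta)
  } else {
    v <- values
    v[!is.na(v) & v == 0] <- if (delta > 0) delta else 1
    out <- 1 / v
  }
  structure(out, delta = delta)
}

#' Principal-component score features
#'
#' Appends the scores of the top principal components of a complete
#' numeric matrix (covariance PCA by default; set `scale. = TRUE` for
#' correlation PCA). Zero-variance columns are excluded from the
#' decomposition.
#'
#' @param x complete numeric matrix (impute missing values first).
#' @param n_components number of leading components (default 5).
#' @param scale. standardize columns to unit variance first?
#' @return list with `scores` (n x n_components matrix), `rotation`,
#'   `center`, `scale`, `explained` (variance fractions), `cols` (columns
#'   used).
#' @export
pca_features <- function(x, n_components = 5, scale. = FALSE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("PCA requires a complete matrix; impute missing values first")
  keep <- apply(x, 2, stats::var) > 0
  p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  if (n_components > ncol(p$rotation)) {
    stop(sprintf("n_components (%d) exceeds the rank of the matrix (%d)",
                 n_components, ncol(p$rotation)))
  }
  idx <- seq_len(n_components)
  list(
    scores = p$x[, idx, drop = FALSE],
    rotation = p$rotation[, idx, drop = FALSE],
    center = p$center,
    scale = if (isTRUE(scale.)) p$scale else NULL,
    explained = p$sdev^2 / sum(p$sdev^2),
    cols = colnames(x)[keep]
  )
}

# internal: split ";"-separated categorical cells into token lists
split_tokens <- function(cells) {
  lapply(strsplit(ifelse(is.na(cells), "", cells), ";", fixed = TRUE),
         function(t) unique(t[nzchar(trimws(t))]))
}

# internal: identity (untransformed) aggregate columns for one base feature
aggregate_feature <- function(feat, type, va, vb) {
  if (type == "binary") {
    out <- data.frame(binary_pair_feature(va, vb))
    names(out) <- paste(feat, "count", "identity", sep = "__")
    aggs <- "count"
  } else if (type == "categorical") {
    ta <- split_tokens(va)
    tb <- split_tokens(vb)
    ov <- mapply(function(a, b) unlist(categorical_overlap(a, b)), ta, tb)
    out <- as.data.frame(t(ov))
    names(out) <- paste(feat, c("n_overlap", "n_union", "pct_overlap"), "identity", sep = "__")
    aggs <- c("n_overlap", "n_union", "pct_overlap")
  } else {
    out <- continuous_pair_features(as.numeric(va), as.numeric(vb))
    aggs <- names(out)
    names(out) <- paste(feat, aggs, "identity", sep = "__")
  }
  list(values = out, aggregations = aggs)
}

#' Build the pair-level feature matrix
#'
#' Turns a gene-level attribute table into engineered pair-level features:
#' binary attributes become 0/1/2 counts, categorical annotation sets
#' become overlap/union/percent-overlap summaries, continuous attributes
#' become absolute difference/average/max/min/total aggregates. Under the
#' `"MT"` scheme each aggregate is expanded with its square, log10 and
#' reciprocal transforms plus a four-quartile binning (binary counts get
#' the three transforms only); under `"NT"` only untransformed aggregates
#' are kept. Missing aggregate values are median-imputed. Optionally the
#' top principal components of the full (standardized) engineered matrix
#' are appended as additional features.
#'
#' Everything data-dependent — imputation medians, log/reciprocal zero
#' constants, quartile-bin boundaries, the PCA rotation — is recorded in a
#' recipe so the identical mapping can be applied to new gene pairs at
#' prediction time (pass the fitted object as `recipe`).
#'
#' @param genes gene table: column `gene` plus one column per schema
#'   feature; categorical cells are `;`-separated token lists.
#' @param schema data.frame with columns `name`, `data_type`
#'   (binary/categorical/continuous), `category`.
#' @param pairs data.frame with columns `pair_id`, `gene_a`, `gene_b`.
#' @param scheme `"MT"` (multiple transformations) or `"NT"` (none).
#' @param n_pcs number of principal-component features to append
#'   (0 = none).
#' @param recipe a fitted `pair_features` object whose frozen recipe should
#'   be re-applied (for held-out or new pairs).
#' @return object of class `pair_features`: list with `features` (numeric
#'   data.frame, rownames = pair ids), `metadata` (column -> base feature,
#'   aggregation, transform, category, data type), `pair_id`, and the
#'   frozen `recipe`.
#' @export
build_pair_matrix <- function(genes, schema, pairs, scheme = c("MT", "NT"),
                              n_pcs = 0, recipe = NULL) {
  scheme <- if (!is.null(recipe)) recipe$recipe$scheme else match.arg(scheme)
  stopifnot(all(c("gene", schema$name) %in% names(genes)),
            all(c("pair_id", "gene_a", "gene_b") %in% names(pairs)))
  missing_genes <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), genes$gene)
  if (length(missing_genes) > 0) {
    stop("gene id(s) in pairs absent from gene table: ",
         paste(utils::head(missing_genes, 10), collapse = ", "))
  }
  ia <- match(pairs$gene_a, genes$gene)
  ib <- match(pairs$gene_b, genes$gene)

  frozen <- if (!is.null(recipe)) recipe$recipe else NULL
  if (!is.null(frozen)) n_pcs <- frozen$n_pcs

  feats <- list()
  meta <- list()
  impute <- if (is.null(frozen)) list() else frozen$impute
  constants <- if (is.null(frozen)) list() else frozen$constants

  for (k in seq_len(nrow(schema))) {
    feat <- schema$name[k]
    type <- schema$data_type[k]
    agg <- aggregate_feature(feat, type, genes[[feat]][ia], genes[[feat]][ib])
    vals <- agg$values
    # median imputation, frozen from the training build
    for (col in names(vals)) {
      if (is.null(frozen) && !(col %in% names(impute))) {
        impute[[col]] <- stats::median(vals[[col]], na.rm = TRUE)
      }
      vals[[col]][is.na(vals[[col]])] <- impute[[col]]
    }
    feats[[length(feats) + 1]] <- vals
    meta[[length(meta) + 1]] <- data.frame(
      column = names(vals), base = feat, aggregation = agg$aggregations,
      transform = "identity", category = schema$category[k], data_type = type
    )
    if (scheme == "MT") {
      kinds <- if (type == "binary") c("square", "log10", "reciprocal") else
        c("square", "log10", "reciprocal", "quartile_bin")
      for (j in seq_along(agg$aggregations)) {
        idcol <- names(vals)[j]
        for (kind in kinds) {
          newcol <- paste(feat, agg$aggregations[j], kind, sep = "__")
          if (!is.null(frozen)) {
            if (!(newcol %in% frozen$metadata$column)) next
            cst <- constants[[newcol]]
            tv <- transform_column(vals[[idcol]], kind,
                                   delta = cst$delta, breaks = cst$breaks)
          } else {
            tv <- withCallingHandlers(
              transform_column(vals[[idcol]], kind),
              warning = function(w) invokeRestart("muffleWarning")
            )
            if (is.null(tv)) next
            constants[[newcol]] <- list(delta = attr(tv, "delta"),
                                        breaks = attr(tv, "breaks"))
          }
          tf <- data.frame(as.numeric(tv))
          names(tf) <- newcol
          feats[[length(feats) + 1]] <- tf
          meta[[length(meta) + 1]] <- data.frame(
            column = newcol, base = feat, aggregation = agg$aggregations[j],
            transform = kind, category = schema$category[k], data_type = type
          )
        }
      }
    }
  }

  x <- do.call(cbind, feats)
  metadata <- do.call(rbind, meta)
  if (anyDuplicated(metadata$column)) {
    stop("duplicate engineered column names; base feature names must be unique")
  }

  pca_fit <- if (is.null(frozen)) NULL else frozen$pca
  if (n_pcs > 0) {
    if (is.null(frozen)) {
      pca_fit <- pca_features(as.matrix(x), n_components = n_pcs, scale. = TRUE)
    }
    xs <- as.matrix(x)[, pca_fit$cols, drop = FALSE]
    xs <- sweep(xs, 2, pca_fit$center, "-")
    if (!is.null(pca_fit$scale)) xs <- sweep(xs, 2, pca_fit$scale, "/")
    scores <- xs %*% pca_fit$rotation
    colnames(scores) <- paste0("PC", seq_len(n_pcs), "__score__identity")
    x <- cbind(x, as.data.frame(scores))
    metadata <- rbind(metadata, data.frame(
      column = colnames(scores), base = "(pca)",
      aggregation = paste0("PC", seq_len(n_pcs)), transform = "identity",
      category = "principal_component", data_type = "continuous"
    ))
  }

  if (!is.null(frozen)) {
    stopifnot(identical(sort(names(x)), sort(frozen$metadata$column)))
    x <- x[, frozen$metadata$column, drop = FALSE]
    metadata <- frozen$metadata
  }
  rownames(x) <- pairs$pair_id
  rownames(metadata) <- NULL

  structure(
    list(
      features = x,
      metadata = metadata,
      pair_id = pairs$pair_id,
      recipe = list(scheme = scheme, n_pcs = n_pcs, impute = impute,
                    constants = constants, pca = pca_fit, metadata = metadata,
                    schema = schema)
    ),
    class = "pair_features"
  )
}

#' @export
print.pair_features <- function(x, ...) {
  cat(sprintf("pair_features: %d pairs x %d engineered columns (scheme %s)\n",
              nrow(x$features), ncol(x$features), x$recipe$scheme))
  cat("feature types:",
      paste(sprintf("%s=%d", names(table(x$metadata$data_type)),
                    table(x$metadata$data_type)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene attribute table and its schema sidecar
#'
#' @param genes_path TSV with column `gene` and one column per feature.
#' @param schema_path TSV sidecar with columns `name`, `data_type`,
#'   `category`.
#' @return list with `genes` and `schema` data.frames.
#' @export
read_gene_table <- function(genes_path, schema_path) {
  schema <- utils::read.delim(schema_path, colClasses = "character")
  stopifnot(all(c("name", "data_type", "category") %in% names(schema)),
            all(schema$data_type %in% c("binary", "categorical", "continuous")))
  genes <- utils::read.delim(genes_path, check.names = FALSE)
  miss <- setdiff(schema$name, names(genes))
  if (length(miss) > 0) {
    stop("gene table is missing schema feature(s): ", paste(miss, collapse = ", "))
  }
  list(genes = genes, schema = schema)
}
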