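#' Derive named sub-seeds from a master seed
#'
#' A single master seed fans out into independent, named sub-seeds so that
#' each stochastic component of the pipeline (holdout split, balanced
#' replicates, fold assignment, model fitting) is individually reproducible.
#'
#' @param master integer master seed.
#' @param names character vector of component names.
#' @return named integer vector of sub-seeds, each in `[1, 2^31 - 2]`.
#' @export
seed_stream <- function(master, names) {
  stopifnot(is.numeric(master), length(master) == 1L, length(names) >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master %% 2147483647))
  s <- sample.int(2147483646L, length(names))
  names(s) <- names
  s
}

#' Fit a per-column min-max scaler
#'
#' @param x numeric matrix (training data).
#' @return an object of class `minmax_scaler` holding per-column ranges and
#'   the names of zero-variance (degenerate) columns.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2, min, na.rm = TRUE)
  hi <- apply(x, 2, max, na.rm = TRUE)
  structure(
    list(lo = lo, hi = hi, degenerate = colnames(x)[hi - lo == 0]),
    class = "minmax_scaler"
  )
}

#' Apply a fitted min-max scaler
#'
#' Values are mapped to `(x - min) / (max - min)` using the training ranges;
#' out-of-range values on new data are clipped to `[0, 1]`. Degenerate
#' (zero-range) columns map to 0.
#'
#' @param scaler a `minmax_scaler`.
#' @param x numeric matrix with the scaler's columns.
#' @return scaled matrix.
#' @export
apply_minmax <- function(scaler, x) {
  x <- as.matrix(x)[, names(scaler$lo), drop = FALSE]
  rng <- scaler$hi - scaler$lo
  rng[rng == 0] <- 1
  out <- sweep(sweep(x, 2, scaler$lo, "-"), 2, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out[, colnames(x) %in% scaler$degenerate] <- 0
  out
}

# internal: run an expression under a temporary seed, restoring RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
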