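#' First-derivative spectral transform
#'
#' Replaces each spectrum by its gap-difference first derivative,
#' `d[i] = x[i + gap] - x[i]`, the usual flattening of baseline drift before
#' modeling milk MIR spectra. The output grid keeps the first
#' `n_points - gap` wavenumbers (left-anchored convention).
#'
#' @param dataset a `mir_dataset` at stage `"raw"`.
#' @param gap difference gap in grid points (default 5).
#' @return A `mir_dataset` at stage `"derived"` with `gap` fewer grid points.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_herds = 2, grid = wn_grid(1000, 2000, 50)))$dataset
#' d1 <- first_derivative(ds)
first_derivative <- function(dataset, gap = 5L) {
  gap <- as.integer(gap)
  p <- length(dataset$grid)
  if (gap < 1L || gap >= p) stop("gap must be in [1, n_points - 1]")
  idx <- seq_len(p - gap)
  deriv <- dataset$spectra[, idx + gap, drop = FALSE] -
    dataset$spectra[, idx, drop = FALSE]
  grid <- structure(as.numeric(dataset$grid)[idx], class = "wn_grid")
  mir_dataset(dataset$info, deriv, grid, stage = "derived")
}

#' Subset spectra to wavenumber regions
#'
#' Keeps exactly the grid points whose wavenumber lies in the closed union
#' of the supplied intervals, preserving order and the original wavenumber
#' identity of each retained column.
#'
#' @param dataset a `mir_dataset`.
#' @param intervals two-column matrix of `(lo, hi)` bounds in cm^-1 (e.g.
#'   [hso_intervals()]); intervals must be non-overlapping with `lo < hi`.
#' @return A `mir_dataset` on the restricted grid. Note the restricted axis
#'   is generally no longer uniformly spaced; it is kept as a plain numeric
#'   wavenumber vector.
#' @export
select_regions <- function(dataset, intervals) {
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2 || any(intervals[, 1] >= intervals[, 2]))
    stop("intervals must be rows of (lo, hi) with lo < hi")
  o <- order(intervals[, 1])
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1 &&
      any(intervals[-1, 1] <= intervals[-nrow(intervals), 2]))
    stop("intervals must be non-overlapping")
  wn <- as.numeric(dataset$grid)
  keep <- Reduce(`|`, lapply(seq_len(nrow(intervals)), function(i)
    wn >= intervals[i, 1] & wn <= intervals[i, 2]))
  if (!any(keep)) stop("empty selection: no grid point falls in the intervals")
  out <- dataset
  out$spectra <- dataset$spectra[, keep, drop = FALSE]
  out$grid <- structure(wn[keep], class = "wn_grid")
  out
}

#' Center-and-scale transforms
#'
#' `fit_scale()` learns per-feature means and sample standard deviations
#' (n - 1 denominator) on a training design matrix; `apply_scale()` applies a
#' frozen transform to any matrix carrying the same feature columns. All
#' predictors are standardized before PLS modeling so each carries the same
#' prior importance.
#'
#' @param X numeric matrix with feature column names.
#' @return `fit_scale` returns a `"scale_transform"`; `apply_scale` the
#'   standardized matrix (columns aligned to the transform's feature order).
#' @export
fit_scale <- function(X) {
  if (nrow(X) < 2) stop("need at least 2 records to fit a scale transform")
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  bad <- which(sds <= 0 | !is.finite(sds))
  if (length(bad))
    stop("zero-variance feature(s): ",
         paste(utils::head(colnames(X)[bad], 5), collapse = ", "))
  structure(list(feature_ids = colnames(X), means = means, sds = sds),
            class = "scale_transform")
}

#' @rdname fit_scale
#' @param transform a `"scale_transform"` from [fit_scale()].
#' @export
apply_scale <- function(transform, X) {
  miss <- setdiff(transform$feature_ids, colnames(X))
  if (length(miss))
    stop("matrix lacks feature(s): ", paste(utils::head(miss, 5), collapse = ", "))
  X <- X[, transform$feature_ids, drop = FALSE]
  sweep(sweep(X, 2, transform$means, "-"), 2, transform$sds, "/")
}
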