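#' Wavenumber grids
#'
#' A wavenumber grid is the uniform axis on which every spectrum of a dataset
#' is aligned. Grids are plain numeric vectors of wavenumbers (cm^-1) with
#' class `"wn_grid"`; points must be strictly increasing and evenly spaced.
#'
#' @param start,end first and last wavenumber (cm^-1).
#' @param n_points number of grid points (>= 2).
#' @return A `"wn_grid"` numeric vector of length `n_points`.
#' @export
#' @examples
#' g <- wn_grid(1000, 2000, 101)
#' wn_step(g)
wn_grid <- function(start, end, n_points) {
  stopifnot(is.numeric(start), is.numeric(end), n_points >= 2, end > start)
  g <- seq(start, end, length.out = n_points)
  structure(g, class = "wn_grid")
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("<wn_grid> %d points, %.2f..%.2f cm^-1, step %.6f cm^-1\n",
              length(x), x[1], x[length(x)], wn_step(x)))
  invisible(x)
}

#' @rdname wn_grid
#' @param grid a `"wn_grid"` object.
#' @export
wn_step <- function(grid) (grid[length(grid)] - grid[1]) / (length(grid) - 1)

# validate uniform spacing; used when grids are reconstructed from file headers
assert_uniform_grid <- function(values, tol = 1e-6) {
  if (length(values) < 2 || is.unsorted(values, strictly = TRUE))
    stop("grid wavenumbers must be strictly increasing")
  steps <- diff(values)
  if (max(steps) - min(steps) > tol)
    stop("grid wavenumbers are not uniformly spaced")
  invisible(values)
}

#' Canonical 797-point MIR grid
#'
#' The fixed mid-infrared wavenumber axis shared by the common dairy
#' spectrometer brands: 797 points from 925.66 to 3995.78 cm^-1
#' (step (3995.78 - 925.66)/796 = 3.8572 cm^-1).
#'
#' @return A `"wn_grid"` of 797 wavenumbers.
#' @export
#' @examples
#' g <- make_canonical_grid()
#' g[c(7, 8, 28)]  # 948.80, 952.66, 1029.80 cm^-1
make_canonical_grid <- function() {
  wn_grid(925.66, 3995.78, 797L)
}

#' Standard expert-preselected spectral windows
#'
#' The three wavenumber windows classically retained as informative for milk
#' composition: 950-1600, 1750-1800 and 2600-3000 cm^-1. Used as the "HSO"
#' starting subset for feature selection.
#'
#' @return A two-column matrix of closed interval bounds (cm^-1).
#' @export
hso_intervals <- function() {
  m <- rbind(c(950, 1600), c(1750, 1800), c(2600, 3000))
  colnames(m) <- c("lo", "hi")
  m
}
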