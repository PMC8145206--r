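# Reduced-scale synthetic fixtures shared across the suite. All fixtures are
# generated in code at test time; grids are coarser than the canonical 797
# points so PLS/RFE runs stay fast while keeping the spectral structure.

test_grid <- function(n_points = 120) wn_grid(925.66, 3995.78, n_points)

test_config <- function(seed = 1, n_herds = 5, n_points = 120, ...) {
  args <- utils::modifyList(
    list(n_herds = n_herds, cows_per_herd = c(10, 20),
         records_per_cow = c(2, 5), grid = test_grid(n_points),
         zone_width = 60, seed = seed),
    list(...))
  do.call(generator_config, args)
}

test_dataset <- function(seed = 1, ...) generate_dataset(test_config(seed, ...))

# plain random regression instance for PLS unit tests
random_instance <- function(n, p, seed = 1, signal = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- if (signal) c(rep(2, min(3, p)), rep(0, p - min(3, p))) else rep(0, p)
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y, beta = beta)
}

# hand-built dataset with arbitrary spectra, for exact-value tests
manual_dataset <- function(spectra, bw = NULL, grid = NULL) {
  n <- nrow(spectra)
  if (is.null(grid)) grid <- wn_grid(1000, 1000 + (ncol(spectra) - 1) * 4, ncol(spectra))
  info <- data.frame(record_id = sprintf("r%03d", seq_len(n)),
                     herd_id = rep(sprintf("h%02d", 1:2), length.out = n),
                     cow_id = sprintf("c%03d", seq_len(n)),
                     parity = rep(1:4, length.out = n),
                     dim = rep(c(30, 90, 150, 210, 280), length.out = n),
                     my = rep(c(18, 24, 30), length.out = n),
                     bw = if (is.null(bw)) rep(600, n) else bw,
                     stringsAsFactors = FALSE)
  mir_dataset(info, as.matrix(spectra), grid)
}
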