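#' Spectral datasets
#'
#' A `mir_dataset` bundles one milking-test record per row: identifiers
#' (record, herd, cow), covariates (parity, parity class, days in milk, milk
#' yield), the bodyweight response when known, and a spectrum aligned to a
#' shared wavenumber grid.
#'
#' @param info data.frame with columns `record_id`, `herd_id`, `cow_id`,
#'   `parity`, `dim`, `my` and optionally `bw` (NA allowed for
#'   prediction-only records).
#' @param spectra numeric matrix, one row per record, one column per grid
#'   point; column names `wn_<wavenumber to 2 dp>`.
#' @param grid the `"wn_grid"` the columns of `spectra` are aligned to.
#' @param stage processing stage tag: `"raw"`, `"derived"`, `"cleaned"` or
#'   `"scaled"`.
#' @return An object of class `"mir_dataset"`.
#' @export
mir_dataset <- function(info, spectra, grid, stage = "raw") {
  stopifnot(is.data.frame(info), is.matrix(spectra))
  required <- c("record_id", "herd_id", "cow_id", "parity", "dim", "my")
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols))
    stop("info is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(info$record_id))
    stop("record_id values must be unique")
  if (nrow(info) != nrow(spectra))
    stop("info and spectra disagree on the number of records")
  if (ncol(spectra) != length(grid))
    stop("spectrum length (", ncol(spectra), ") does not match grid (",
         length(grid), " points)")
  stage <- match.arg(stage, c("raw", "derived", "cleaned", "scaled"))
  if (!"bw" %in% names(info)) info$bw <- NA_real_
  info$parity_class <- parity_class(info$parity)
  colnames(spectra) <- wn_names(grid)
  rownames(spectra) <- info$record_id
  structure(list(info = info, spectra = spectra, grid = grid, stage = stage),
            class = "mir_dataset")
}

wn_names <- function(grid) sprintf("wn_%.2f", as.numeric(grid))

#' @export
print.mir_dataset <- function(x, ...) {
  cat(sprintf("<mir_dataset> %d records, %d herds, %d spectral points [%s]\n",
              nrow(x$info), length(unique(x$info$herd_id)),
              length(x$grid), x$stage))
  invisible(x)
}

#' @rdname mir_dataset
#' @param dataset a `mir_dataset`.
#' @export
n_records <- function(dataset) nrow(dataset$info)

#' Subset a dataset by record position or id
#'
#' @param dataset a `mir_dataset`.
#' @param which logical/integer vector of record positions, or a character
#'   vector of record ids.
#' @return A `mir_dataset` with the selected records, same grid and stage.
#' @export
subset_records <- function(dataset, which) {
  if (is.character(which)) which <- match(which, dataset$info$record_id)
  if (anyNA(which)) stop("unknown record id in subset")
  mir_dataset(dataset$info[which, , drop = FALSE],
              dataset$spectra[which, , drop = FALSE],
              dataset$grid, dataset$stage)
}

#' Assemble the predictor matrix of a dataset
#'
#' Builds the numeric design matrix used for modeling: the ordinal parity
#' class (1..4), days in milk, milk yield, then one column per spectral
#' point. Parity enters as a single ordinal feature so that the candidate
#' count equals `n_points + 3`.
#'
#' @param dataset a `mir_dataset`.
#' @param features optional character vector of feature ids (column names)
#'   to keep, in that order.
#' @return A numeric matrix with rownames = record ids.
#' @export
design_matrix <- function(dataset, features = NULL) {
  X <- cbind(parity = as.numeric(dataset$info$parity_class),
             dim = as.numeric(dataset$info$dim),
             my = as.numeric(dataset$info$my),
             dataset$spectra)
  rownames(X) <- dataset$info$record_id
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(X))
    if (length(miss))
      stop("features absent from dataset: ", paste(utils::head(miss, 5), collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  X
}

#' Read and write datasets as delimited text
#'
#' The canonical on-disk format is a CSV with header columns `record_id`,
#' `herd_id`, `cow_id`, `parity`, `dim`, `my`, `bw`, then one column per
#' wavenumber named `wn_<value to 2 dp>`. The grid is inferred from the
#' headers on read; a malformed header is a hard error.
#'
#' @param dataset a `mir_dataset`.
#' @param path file path.
#' @param stage stage tag to attach on read.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` a
#'   `mir_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  df <- cbind(dataset$info[c("record_id", "herd_id", "cow_id",
                             "parity", "dim", "my", "bw")],
              as.data.frame(dataset$spectra))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, stage = "raw") {
  df <- data.table::fread(path, data.table = FALSE)
  wn_cols <- grep("^wn_", names(df), value = TRUE)
  if (!length(wn_cols)) stop("no wn_<wavenumber> columns found in ", path)
  values <- as.numeric(sub("^wn_", "", wn_cols))
  if (anyNA(values)) stop("malformed wavenumber column names in ", path)
  assert_uniform_grid(values, tol = 0.011)  # names carry 2 dp only
  grid <- structure(values, class = "wn_grid")
  spectra <- as.matrix(df[wn_cols])
  info <- df[setdiff(names(df), wn_cols)]
  mir_dataset(info, spectra, grid, stage = stage)
}
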