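#' Parity classing
#'
#' Lactation number is pooled into four classes: 1, 2, 3 and 4+ (cows in or
#' beyond their fourth parity), reflecting that Holsteins approach mature
#' weight around the fourth lactation.
#'
#' @param parity integer vector of lactation numbers (>= 1).
#' @return An ordered factor with levels `"1" < "2" < "3" < "4plus"`.
#' @export
#' @examples
#' parity_class(c(1, 2, 4, 7))
parity_class <- function(parity) {
  if (any(parity < 1)) stop("parity must be >= 1")
  cls <- ifelse(parity >= 4, "4plus", as.character(parity))
  factor(cls, levels = c("1", "2", "3", "4plus"), ordered = TRUE)
}

#' Default parity-wise bodyweight plausibility intervals
#'
#' Closed kg intervals (mean +/- one within-class SD on reference Holstein
#' data) outside which a test-day bodyweight is considered implausible for
#' its parity class. These are configuration defaults, not re-derived here.
#'
#' @return Named list of `c(low, high)` kg per parity class.
#' @export
default_bw_intervals <- function() {
  list(`1` = c(376, 705), `2` = c(449, 767),
       `3` = c(487, 838), `4plus` = c(492, 875))
}

#' Parity-specific bodyweight range filter
#'
#' Keeps a record iff `low <= bw <= high` for its parity class (intervals
#' treated as closed).
#'
#' @param dataset a `mir_dataset` whose records all carry `bw`.
#' @param intervals per-class intervals, as from [default_bw_intervals()].
#' @return `list(dataset = filtered mir_dataset, removed = record ids)`.
#' @export
bw_range_filter <- function(dataset, intervals = default_bw_intervals()) {
  bw <- dataset$info$bw
  if (anyNA(bw)) stop("bw missing for some records; range filter needs bw")
  cls <- as.character(dataset$info$parity_class)
  lo <- vapply(intervals, `[`, numeric(1), 1)[cls]
  hi <- vapply(intervals, `[`, numeric(1), 2)[cls]
  keep <- bw >= lo & bw <= hi
  list(dataset = subset_records(dataset, which(keep)),
       removed = dataset$info$record_id[!keep])
}

#' Global-H spectral distance filter
#'
#' Flags atypical spectra by their standardized distance in principal
#' component space. Spectra are centered, a PCA retains the smallest number
#' k of components whose cumulative explained variance reaches
#' `var_explained`, and the global H (GH) statistic of record i is the
#' squared standardized score distance averaged over those components:
#' `GH_i = (1/k) * sum_a t[i,a]^2 / lambda_a`. Records with GH above
#' `threshold` are dropped.
#'
#' @param dataset a `mir_dataset` (>= 3 records).
#' @param var_explained cumulative variance proportion to retain (default 0.99).
#' @param threshold GH removal threshold (default 3).
#' @return `list(dataset, removed, gh, k)` where `gh` is the per-record GH
#'   named by record id and `k` the number of retained components.
#' @export
gh_filter <- function(dataset, var_explained = 0.99, threshold = 3) {
  if (n_records(dataset) < 3) stop("gh_filter needs at least 3 records")
  pc <- stats::prcomp(dataset$spectra, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2
  total <- sum(lambda)
  if (total <= .Machine$double.eps)
    stop("degenerate spectral variance: PCA has no components to retain")
  k <- which(cumsum(lambda) / total >= var_explained - 1e-12)[1]
  if (is.na(k)) k <- length(lambda)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  gh <- rowSums(sweep(scores^2, 2, lambda[seq_len(k)], "/")) / k
  names(gh) <- dataset$info$record_id
  keep <- gh <= threshold
  list(dataset = subset_records(dataset, which(keep)),
       removed = dataset$info$record_id[!keep], gh = gh, k = k)
}

#' Iterative PLS-residual outlier removal
#'
#' Repeatedly fits a PLS regression of bodyweight on all predictors, removes
#' every record whose residual deviates from the mean residual by more than
#' `sd_threshold` residual standard deviations, and refits, stopping when an
#' iteration removes nothing.
#'
#' @param dataset a `mir_dataset` with `bw` on every record.
#' @param n_components PLS components for the screening fits (default 10,
#'   capped at `min(p, n - 1)` as the data shrink).
#' @param sd_threshold removal threshold in residual SDs (default 3).
#' @return `list(dataset, removed_per_iteration, n_iterations)`.
#' @export
iterative_residual_clean <- function(dataset, n_components = 10, sd_threshold = 3) {
  if (anyNA(dataset$info$bw)) stop("bw missing for some records")
  if (n_components < 1) stop("n_components must be >= 1")
  removed <- list()
  repeat {
    n <- n_records(dataset)
    X <- design_matrix(dataset)
    if (n <= n_components + 1)
      stop("dataset shrank below the minimum size for a ",
           n_components, "-component fit")
    sc <- fit_scale(X)
    fit <- fit_pls(apply_scale(sc, X), dataset$info$bw,
                   min(n_components, ncol(X), n - 1))
    r <- dataset$info$bw - predict(fit, apply_scale(sc, X))
    out <- abs(r - mean(r)) > sd_threshold * stats::sd(r)
    if (!any(out)) break
    removed[[length(removed) + 1L]] <- dataset$info$record_id[out]
    dataset <- subset_records(dataset, which(!out))
  }
  list(dataset = dataset, removed_per_iteration = removed,
       n_iterations = length(removed) + 1L)
}

#' Full three-stage record cleaning
#'
#' Applies, in order, the parity-wise bodyweight range filter, the global-H
#' spectral distance filter, and the iterative PLS-residual screen, and
#' assembles a [cleaning_report()].
#'
#' @param dataset a `mir_dataset` with `bw`.
#' @param intervals parity-wise bodyweight intervals.
#' @param var_explained,gh_threshold see [gh_filter()].
#' @param n_components,sd_threshold see [iterative_residual_clean()].
#' @return `list(dataset, report)` with the cleaned dataset (stage
#'   `"cleaned"`) and its `"cleaning_report"`.
#' @export
clean_dataset <- function(dataset, intervals = default_bw_intervals(),
                          var_explained = 0.99, gh_threshold = 3,
                          n_components = 10, sd_threshold = 3) {
  n_input <- n_records(dataset)
  s1 <- bw_range_filter(dataset, intervals)
  s2 <- gh_filter(s1$dataset, var_explained, gh_threshold)
  s3 <- iterative_residual_clean(s2$dataset, n_components, sd_threshold)
  out <- s3$dataset
  out$stage <- "cleaned"
  report <- cleaning_report(n_input = n_input,
                            removed_bw_range = s1$removed,
                            removed_gh = s2$removed,
                            removed_residual = s3$removed_per_iteration,
                            n_output = n_records(out))
  list(dataset = out, report = report)
}

#' Cleaning report
#'
#' Bookkeeping for the three cleaning stages: counts in/out, the removal id
#' sets (pairwise disjoint by construction), and the overall fraction
#' removed, `(n_input - n_output) / n_input`.
#'
#' @param n_input,n_output record counts before/after cleaning.
#' @param removed_bw_range,removed_gh record ids removed at each stage.
#' @param removed_residual list of id vectors, one per residual iteration.
#' @return A `"cleaning_report"` list.
#' @export
cleaning_report <- function(n_input, removed_bw_range, removed_gh,
                            removed_residual, n_output) {
  all_removed <- c(removed_bw_range, removed_gh, unlist(removed_residual))
  if (anyDuplicated(all_removed)) stop("a record was removed twice")
  if (n_output != n_input - length(all_removed))
    stop("cleaning report arithmetic is inconsistent")
  structure(list(n_input = n_input,
                 removed_bw_range = removed_bw_range,
                 removed_gh = removed_gh,
                 removed_residual = removed_residual,
                 n_iterations = length(removed_residual) + 1L,
                 n_output = n_output,
                 fraction_removed = (n_input - n_output) / n_input),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(paste0("<cleaning_report> %d -> %d records (%.2f%% removed)\n",
                     "  bw range: %d | GH: %d | residual: %d in %d iteration(s)\n"),
              x$n_input, x$n_output, 100 * x$fraction_removed,
              length(x$removed_bw_range), length(x$removed_gh),
              length(unlist(x$removed_residual)), x$n_iterations - 1L))
  invisible(x)
}

#' @rdname cleaning_report
#' @param report a `"cleaning_report"`.
#' @param path file path for the JSON serialization.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
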