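#' Quartile strata on bodyweight
#'
#' Boundaries at the minimum, the three quartiles (type-7, linear
#' interpolation) and the maximum of the supplied bodyweights; the four
#' resulting intervals are the strata used by stratified cross-validation.
#'
#' @param bw numeric bodyweights (>= 4 distinct values).
#' @return A `"bw_strata"` list: `boundaries` (length 5) and per-record
#'   integer `labels` in 1..4.
#' @export
make_strata <- function(bw) {
  if (length(unique(bw)) < 4) stop("need at least 4 distinct bw values")
  boundaries <- stats::quantile(bw, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                                names = FALSE)
  labels <- as.integer(cut(bw, boundaries, include.lowest = TRUE))
  structure(list(boundaries = boundaries, labels = labels),
            class = "bw_strata")
}

#' Stratified fold assignment
#'
#' Within each stratum, records are shuffled (seeded) and dealt round-robin
#' to the k folds, so per-stratum fold counts differ by at most one.
#'
#' @param strata integer/character stratum label per record.
#' @param k number of folds.
#' @param seed RNG seed for the shuffles.
#' @return Integer fold label (1..k) per record.
#' @export
stratified_kfold <- function(strata, k = 10, seed = 1L) {
  n <- length(strata)
  if (n < k) stop("fewer records than folds")
  folds <- integer(n)
  with_stream(stream_seed(seed, 7L), {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) < k)
        warning("stratum ", s, " has fewer records (", length(idx),
                ") than folds (", k, ")")
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

#' Herd-disjoint repeated partitions
#'
#' Enumerates every non-empty proper subset of herds whose record share
#' lies in the closed `fraction_range`, then samples `n_repeats` of them
#' uniformly — without replacement when enough feasible subsets exist, with
#' replacement (and a warning) otherwise. Each repeat's validation herds
#' never contribute to its calibration side.
#'
#' @param herd_sizes named integer vector, records per herd.
#' @param fraction_range closed validation-share bounds (default
#'   `c(0.10, 0.30)`).
#' @param n_repeats number of partitions (default 101).
#' @param seed RNG seed.
#' @return A `"partition_scheme"`: list `repeats` of
#'   `list(train_herds, validation_herds, fraction)`, plus the inputs.
#' @export
herd_partitions <- function(herd_sizes, fraction_range = c(0.10, 0.30),
                            n_repeats = 101, seed = 1L) {
  h <- length(herd_sizes)
  if (h < 2) stop("need at least 2 herds")
  if (h > 24) stop("subset enumeration supports at most 24 herds")
  if (is.null(names(herd_sizes))) names(herd_sizes) <- paste0("h", seq_len(h))
  total <- sum(herd_sizes)
  masks <- seq_len(2^h - 2)  # non-empty proper subsets
  in_val <- vapply(masks, function(m) as.logical(bitwAnd(m, 2^(seq_len(h) - 1))),
                   logical(h))
  fractions <- colSums(herd_sizes * in_val) / total
  feasible <- which(fractions >= fraction_range[1] & fractions <= fraction_range[2])
  if (!length(feasible)) stop("no herd subset satisfies the fraction constraint")
  with_stream(stream_seed(seed, 13L), {
    if (length(feasible) >= n_repeats) {
      chosen <- sample(feasible, n_repeats)
    } else {
      warning("only ", length(feasible), " feasible subsets; sampling with replacement")
      chosen <- sample(feasible, n_repeats, replace = TRUE)
    }
  })
  repeats <- lapply(chosen, function(m) {
    val <- names(herd_sizes)[in_val[, m]]
    list(train_herds = setdiff(names(herd_sizes), val),
         validation_herds = val, fraction = fractions[m])
  })
  structure(list(repeats = repeats, fraction_range = fraction_range,
                 n_repeats = n_repeats, herd_sizes = herd_sizes, seed = seed,
                 n_feasible = length(feasible)),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  fr <- vapply(x$repeats, `[[`, numeric(1), "fraction")
  cat(sprintf("<partition_scheme> %d repeats over %d herds, validation share %.2f..%.2f\n",
              length(x$repeats), length(x$herd_sizes), min(fr), max(fr)))
  invisible(x)
}

#' Herd-independent repeated evaluation of a feature subset
#'
#' For every partition repeat and every component count A in
#' `1..max_components`, standardizes predictors on the calibration herds,
#' fits a PLS model and scores the held-out herds. The optimal A minimizes
#' the mean held-out RMSE across repeats (ties to the smaller A); the
#' summary reports that mean and SD, plus a stratified 10-fold CV RMSE and
#' R2 of the same subset at the same A on the full dataset.
#'
#' @param feature_ids feature subset to evaluate.
#' @param dataset a cleaned `mir_dataset`.
#' @param scheme a [herd_partitions()] scheme.
#' @param max_components PLS component cap (default 10).
#' @param family_tag label carried into the summary.
#' @param cv_seed seed for the stratified CV folds.
#' @return An `"evaluation_summary"` list.
#' @export
evaluate_iv <- function(feature_ids, dataset, scheme, max_components = 10,
                        family_tag = NULL, cv_seed = 1L) {
  X <- design_matrix(dataset, feature_ids)
  y <- dataset$info$bw
  herd <- dataset$info$herd_id
  a_cap <- min(max_components, ncol(X))
  rmse_mat <- matrix(NA_real_, length(scheme$repeats), a_cap)
  for (r in seq_along(scheme$repeats)) {
    tr <- herd %in% scheme$repeats[[r]]$train_herds
    a_r <- min(a_cap, sum(tr) - 1)
    if (sum(tr) <= 2 || a_r < 1) {
      warning("repeat ", r, " has too few calibration records; skipped")
      next
    }
    sc <- fit_scale_lenient(X[tr, , drop = FALSE])
    fit <- fit_pls(apply_scale(sc, X[tr, , drop = FALSE]), y[tr], a_r)
    ph <- predict(fit, apply_scale(sc, X[!tr, , drop = FALSE]),
                  n_components = seq_len(fit$n_components))
    ph <- matrix(ph, nrow = sum(!tr))
    rmse_mat[r, seq_len(fit$n_components)] <- sqrt(colMeans((y[!tr] - ph)^2))
  }
  means <- colMeans(rmse_mat, na.rm = TRUE)
  best_a <- which.min(means)
  folds <- stratified_kfold(make_strata(y)$labels, k = 10, seed = cv_seed)
  cv <- cv_pls(X, y, folds, best_a)  # CV reported at the iv-optimal A
  fold_rmse <- cv$fold_rmse_mat[, best_a]
  structure(list(family_tag = family_tag, feature_ids = feature_ids,
                 n_features = length(feature_ids),
                 n_components = best_a,
                 rmse_iv_mean = means[best_a],
                 rmse_iv_sd = stats::sd(rmse_mat[, best_a], na.rm = TRUE),
                 rmse_scv_mean = mean(fold_rmse),
                 rmse_scv_sd = stats::sd(fold_rmse),
                 r2_scv = r2(y, cv$pred_mat[, best_a]),
                 rmse_v = NA_real_),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("<evaluation_summary> %s: %d features, %d comp, RMSEiv %.2f +/- %.2f kg\n",
              x$family_tag %||% "?", x$n_features, x$n_components,
              x$rmse_iv_mean, x$rmse_iv_sd))
  invisible(x)
}

#' Pick the best retained model of each family
#'
#' Per family, minimizes the herd-independent RMSE mean; ties broken by
#' smaller RMSE SD, then smaller stratified-CV RMSE mean, then fewer
#' features.
#'
#' @param summaries list of `"evaluation_summary"` objects.
#' @return Named list, one summary per family.
#' @export
pick_best_per_family <- function(summaries) {
  tags <- vapply(summaries, function(s) s$family_tag %||% "model", character(1))
  out <- lapply(split(summaries, tags), function(group) {
    key <- vapply(group, function(s)
      c(s$rmse_iv_mean, s$rmse_iv_sd, s$rmse_scv_mean, s$n_features),
      numeric(4))
    group[[order(key[1, ], key[2, ], key[3, ], key[4, ])[1]]]
  })
  out[unique(tags)]
}

#' Refit finalists on all training data and validate externally
#'
#' Each selected model is refit on the entire training dataset at its
#' chosen component count (standardization fitted on training only, then
#' frozen), scored on the external dataset (`RMSE_v`), and the pairwise
#' Pearson correlation of the external predictions is reported.
#'
#' @param selected list of `"selected_model"` or `"evaluation_summary"`
#'   objects (must carry `feature_ids` and `n_components`).
#' @param training,external `mir_dataset`s sharing grid and covariates; the
#'   external set never touches fitting or scaling.
#' @return list `summaries` (data.frame with `family_tag`, `n_features`,
#'   `n_components`, `rmse_train`, `rmse_v`), `models` (fitted
#'   `"pls_model"`s), `predictions` (external prediction matrix) and
#'   `correlations` (pairwise Pearson matrix).
#' @export
finalize_and_external_validate <- function(selected, training, external) {
  y_tr <- training$info$bw
  y_ex <- external$info$bw
  fits <- lapply(selected, function(m) {
    X <- design_matrix(training, m$feature_ids)
    sc <- fit_scale(X)
    fit <- fit_pls(apply_scale(sc, X), y_tr,
                   min(m$n_components, ncol(X), nrow(X) - 1))
    fit$scale <- sc
    fit
  })
  tags <- vapply(seq_along(selected), function(i)
    selected[[i]]$family_tag %||% paste0("model", i), character(1))
  names(fits) <- make.unique(tags)
  preds <- vapply(fits, function(f)
    predict(f, design_matrix(external, f$feature_ids)), numeric(n_records(external)))
  rmse_v <- apply(preds, 2, function(ph) rmse(y_ex, ph))
  rmse_train <- vapply(fits, function(f)
    rmse(y_tr, predict(f, design_matrix(training, f$feature_ids))), numeric(1))
  const <- apply(preds, 2, stats::sd) == 0
  if (any(const)) warning("constant external predictions for: ",
                          paste(names(fits)[const], collapse = ", "))
  summaries <- data.frame(family_tag = names(fits),
                          n_features = vapply(selected, function(m)
                            length(m$feature_ids), integer(1)),
                          n_components = vapply(fits, `[[`, integer(1),
                                                "n_components"),
                          rmse_train = rmse_train, rmse_v = rmse_v,
                          row.names = NULL, stringsAsFactors = FALSE)
  list(summaries = summaries, models = fits, predictions = preds,
       correlations = stats::cor(preds))
}
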