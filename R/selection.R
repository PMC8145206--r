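#' Univariate GAM filter screen ("selected by filter", SBF)
#'
#' Each candidate predictor X is used alone to fit a generalized additive
#' model `bw = b0 + s(X) + e` with a penalized cubic regression spline
#' (basis dimension 10, smoothness by GCV). The null hypothesis of no
#' functional relationship is tested by the approximate F-test of the
#' smooth term (which is well calibrated under penalized smoothing, unlike
#' a naive model-vs-null comparison); predictors with p < `alpha` are
#' retained. Covariates (parity, DIM, MY) compete like any spectral point.
#' Predictors with too few distinct values for a spline are tested with a
#' linear term; constant predictors cannot reject the null and are dropped
#' with a warning.
#'
#' @param dataset a `mir_dataset` with `bw`.
#' @param alpha significance level (default 0.05, no multiplicity
#'   correction by design: the filter is meant to be permissive).
#' @param features candidate feature ids (default: all design-matrix
#'   columns).
#' @return An `"sbf_result"`: data.frame (`feature`, `p_value`, `retained`)
#'   plus attribute `alpha`.
#' @export
sbf_filter <- function(dataset, alpha = 0.05, features = NULL) {
  X <- design_matrix(dataset, features)
  y <- dataset$info$bw
  if (anyNA(y)) stop("bw missing for some records")
  if (nrow(X) < 30) stop("sbf_filter needs at least ~30 records for spline fits")
  pvals <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    nu <- length(unique(x))
    if (nu < 2) return(NA_real_)
    smooth <- nu >= 4
    fml <- if (smooth) y ~ s(x, bs = "cr", k = min(10, nu)) else y ~ x
    fit <- try(mgcv::gam(fml, method = "GCV.Cp"), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    sm <- summary(fit)
    p <- if (smooth) sm$s.table[1, "p-value"] else sm$p.table[2, "Pr(>|t|)"]
    if (!is.finite(p)) p <- 1  # smooth penalized to a constant
    p
  }, numeric(1))
  if (anyNA(pvals))
    warning(sum(is.na(pvals)), " constant/degenerate predictor(s) excluded")
  res <- data.frame(feature = colnames(X), p_value = pvals,
                    retained = !is.na(pvals) & pvals < alpha,
                    stringsAsFactors = FALSE)
  structure(res, alpha = alpha, class = c("sbf_result", "data.frame"))
}

#' Recursive-feature-elimination subset-size schedule
#'
#' Subset sizes start at the full feature count and descend with a gap that
#' shrinks as the set shrinks: step 5 while the size exceeds 255, step 2
#' while in 201..255, step 1 at or below 200, stopping before any size
#' drops under 2. Starting sizes of 379, 280 and 159 give 251, 231 and 158
#' subsets respectively.
#'
#' @param n_features starting feature count (>= 2).
#' @return Integer vector of strictly decreasing subset sizes, beginning
#'   with `n_features`.
#' @export
#' @examples
#' length(rfe_schedule(379))  # 251
rfe_schedule <- function(n_features) {
  n_features <- as.integer(n_features)
  if (n_features < 2) stop("n_features must be >= 2")
  sizes <- integer(0)
  cur <- n_features
  while (cur >= 2) {
    sizes <- c(sizes, cur)
    cur <- cur - if (cur > 255L) 5L else if (cur > 200L) 2L else 1L
  }
  sizes
}

# internal scaling that tolerates constant columns (they get sd 1 and hence
# zero PLS weight after centering); used inside CV folds only
fit_scale_lenient <- function(X) {
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds <= 0 | !is.finite(sds)] <- 1
  structure(list(feature_ids = colnames(X), means = means, sds = sds),
            class = "scale_transform")
}

# stratified k-fold CV of PLS over 1..max_components; returns the per-fold
# RMSE matrix, the best component count (argmin of the fold mean, ties to
# the smaller count), and pooled out-of-fold predictions at the best count
cv_pls <- function(X, y, folds, max_components) {
  k <- max(folds)
  a_cap <- min(max_components, ncol(X))
  rmse_mat <- matrix(NA_real_, k, a_cap)
  pred <- matrix(NA_real_, length(y), a_cap)
  for (f in seq_len(k)) {
    tr <- folds != f
    a_f <- min(a_cap, sum(tr) - 1)
    sc <- fit_scale_lenient(X[tr, , drop = FALSE])
    fit <- fit_pls(apply_scale(sc, X[tr, , drop = FALSE]), y[tr], a_f)
    a_f <- fit$n_components  # may stop early on rank deficiency
    ph <- predict(fit, apply_scale(sc, X[!tr, , drop = FALSE]),
                  n_components = seq_len(a_f))
    ph <- matrix(ph, nrow = sum(!tr))
    rmse_mat[f, seq_len(a_f)] <- sqrt(colMeans((y[!tr] - ph)^2))
    pred[!tr, seq_len(a_f)] <- ph
  }
  means <- colMeans(rmse_mat)
  best_a <- which.min(means)  # ties resolve to the smaller component count
  list(best_a = best_a, rmse_mean = means[best_a],
       rmse_sd = stats::sd(rmse_mat[, best_a]),
       rmse_by_a = means, fold_rmse_mat = rmse_mat,
       fold_rmse = rmse_mat[, best_a], pred_mat = pred,
       pred_best = pred[, best_a])
}

#' Recursive feature elimination with PLS re-ranking
#'
#' Backward wrapper selection: features are first ranked by a PLS fit on
#' the full starting set (VIP or absolute-coefficient BETA scores); then,
#' for every size of [rfe_schedule()], the top-ranked features are kept, a
#' PLS model is fit on them (component count 1..`max_components` chosen by
#' stratified 10-fold CV), its stratified-CV RMSE mean and SD are recorded,
#' and the ranking is recomputed within the subset before the next cut.
#'
#' @param dataset a cleaned `mir_dataset` with `bw`.
#' @param starting_features character vector of design-matrix columns to
#'   start from.
#' @param ranking_method `"VIP"` or `"BETA"`.
#' @param strata per-record stratum labels for the CV folds (default:
#'   quartile strata of bw via [make_strata()]).
#' @param k number of CV folds (default 10).
#' @param max_components PLS component cap (default 10).
#' @param seed seed for the fold assignment.
#' @param family_tag label carried into the trace (e.g. `"HSO_VIP"`).
#' @return An `"rfe_trace"`: `steps` data.frame (`subset_size`,
#'   `rmse_scv_mean`, `rmse_scv_sd`, `n_components`) and parallel list
#'   `features` of retained feature ids per step.
#' @export
run_rfe <- function(dataset, starting_features, ranking_method = c("VIP", "BETA"),
                    strata = NULL, k = 10, max_components = 10, seed = 1L,
                    family_tag = NULL) {
  ranking_method <- match.arg(ranking_method)
  X <- design_matrix(dataset, starting_features)
  y <- dataset$info$bw
  n <- nrow(X)
  if (n <= k) stop("fewer records than folds")
  if (is.null(strata)) strata <- make_strata(y)$labels
  folds <- stratified_kfold(strata, k = k, seed = seed)
  rank_fun <- if (ranking_method == "VIP") vip_scores else beta_scores
  rank_fit <- function(Xs) {
    sc <- fit_scale_lenient(Xs)
    fit <- fit_pls(apply_scale(sc, Xs), y, min(max_components, ncol(Xs), n - 1))
    rank_fun(fit)$feature
  }
  ranking <- rank_fit(X)
  sizes <- rfe_schedule(length(starting_features))
  steps <- vector("list", length(sizes))
  feats <- vector("list", length(sizes))
  for (s in seq_along(sizes)) {
    keep <- ranking[seq_len(sizes[s])]
    Xs <- X[, keep, drop = FALSE]
    cv <- cv_pls(Xs, y, folds, max_components)
    steps[[s]] <- data.frame(subset_size = sizes[s],
                             rmse_scv_mean = cv$rmse_mean,
                             rmse_scv_sd = cv$rmse_sd,
                             n_components = cv$best_a)
    feats[[s]] <- keep
    if (s < length(sizes)) ranking <- rank_fit(Xs)
  }
  structure(list(family_tag = family_tag %||% ranking_method,
                 ranking_method = ranking_method,
                 steps = do.call(rbind, steps), features = feats),
            class = "rfe_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rfe_trace <- function(x, ...) {
  best <- which.min(x$steps$rmse_scv_mean)
  cat(sprintf("<rfe_trace> %s: %d subset(s) from %d features; best RMSE %.2f at size %d\n",
              x$family_tag, nrow(x$steps), x$steps$subset_size[1],
              x$steps$rmse_scv_mean[best], x$steps$subset_size[best]))
  invisible(x)
}

#' Tolerance-based retention of RFE models
#'
#' For each tolerance t (percent), the threshold is
#' `min(RMSE_SCV) * (1 + t/100)`; among trace steps at or under the
#' threshold the one with the smallest subset size is retained (ties by
#' lower RMSE). The default grid 0..12 keeps 13 models per trace; the same
#' subset may be retained by several tolerances and is then listed once per
#' tolerance.
#'
#' @param trace an `"rfe_trace"`.
#' @param tolerances integer percent tolerances (default `0:12`).
#' @return A list of `"selected_model"` entries with fields `family_tag`,
#'   `tolerance`, `feature_ids`, `subset_size`, `rmse_scv`, `n_components`.
#' @export
tolerance_select <- function(trace, tolerances = 0:12) {
  if (!length(tolerances)) stop("empty tolerance list")
  st <- trace$steps
  min_rmse <- min(st$rmse_scv_mean)
  lapply(tolerances, function(t) {
    ok <- which(st$rmse_scv_mean <= min_rmse * (1 + t / 100))
    ok <- ok[order(st$subset_size[ok], st$rmse_scv_mean[ok])]
    i <- ok[1]
    structure(list(family_tag = trace$family_tag, tolerance = t,
                   feature_ids = trace$features[[i]],
                   subset_size = st$subset_size[i],
                   rmse_scv = st$rmse_scv_mean[i],
                   n_components = st$n_components[i]),
              class = "selected_model")
  })
}
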