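#' Partial least squares regression (single response, NIPALS)
#'
#' Fits PLS1 by the NIPALS algorithm with X-deflation: at each step the
#' weight vector `w_a` is the (normalized) covariance direction `X'y`, scores
#' `t_a = X w_a`, loadings `p_a = X't_a / (t_a't_a)` and
#' `q_a = y't_a / (t_a't_a)`, followed by deflation of X and y. Predictors
#' are expected to be standardized by the caller (see [fit_scale()]); the
#' fit centers X and y internally so predictions carry the intercept.
#'
#' @param X numeric matrix (n x p) with feature column names, finite.
#' @param y numeric response vector of length n.
#' @param n_components number of latent components A,
#'   `A <= min(p, n - 1)`.
#' @param scale optional `"scale_transform"` used to standardize `X`; stored
#'   so that [predict.pls_model()] can be applied to raw matrices.
#' @return A `"pls_model"` with weights `W` (p x A, unit-norm columns),
#'   loadings `P`, y-loadings `q`, score norms `tt` (`t_a' t_a`),
#'   `coefficients` on the (standardized) predictor scale, `intercept`, and
#'   centering vectors.
#' @export
fit_pls <- function(X, y, n_components, scale = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("X and y must be finite")
  A <- as.integer(n_components)
  if (A < 1 || A > min(p, n - 1))
    stop("n_components must be in [1, min(p, n - 1)]")
  feature_ids <- colnames(X)
  if (is.null(feature_ids)) feature_ids <- paste0("x", seq_len(p))

  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center, "-")
  yc <- y - y_center

  W <- P <- matrix(0, p, A)
  q <- tt <- numeric(A)
  Tmat <- matrix(0, n, A)
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(yc^2)))) {
      warning("rank deficiency: stopping at ", a_done, " components")
      break
    }
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt_a <- sum(t_a^2)
    if (tt_a < 1e-24) {
      warning("degenerate score vector: stopping at ", a_done, " components")
      break
    }
    p_a <- drop(crossprod(Xc, t_a)) / tt_a
    q_a <- sum(yc * t_a) / tt_a
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a; tt[a] <- tt_a
    Tmat[, a] <- t_a
    a_done <- a
  }
  if (a_done == 0L) stop("no PLS component could be extracted (X'y is null)")
  keep <- seq_len(a_done)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  q <- q[keep]; tt <- tt[keep]; Tmat <- Tmat[, keep, drop = FALSE]

  # R = W (P'W)^{-1}; P'W is unit upper triangular for NIPALS PLS1
  R <- W %*% backsolve(crossprod(P, W), diag(a_done))
  coefficients <- drop(R %*% q)
  names(coefficients) <- feature_ids

  structure(list(n_components = a_done, feature_ids = feature_ids,
                 W = W, P = P, q = q, tt = tt, scores = Tmat,
                 coefficients = coefficients,
                 x_center = x_center, y_center = y_center,
                 intercept = y_center - sum(x_center * coefficients),
                 R = R, scale = scale),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d feature(s)\n",
              x$n_components, length(x$feature_ids)))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' Columns of `newdata` are aligned to the model's feature ids; the model's
#' stored scale transform (if any) is applied first; no refitting occurs.
#'
#' @param object a `"pls_model"`.
#' @param newdata numeric matrix carrying (at least) the model's features.
#' @param n_components predict with the first `n_components` components
#'   (default: all fitted). May be a vector, in which case a matrix with one
#'   column per requested component count is returned.
#' @param ... unused.
#' @return Numeric vector of predictions, or a matrix if `n_components` has
#'   length > 1.
#' @export
predict.pls_model <- function(object, newdata, n_components = object$n_components, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$scale)) newdata <- apply_scale(object$scale, newdata)
  miss <- setdiff(object$feature_ids, colnames(newdata))
  if (length(miss))
    stop("newdata lacks feature(s): ", paste(utils::head(miss, 5), collapse = ", "))
  X <- newdata[, object$feature_ids, drop = FALSE]
  Xc <- sweep(X, 2, object$x_center, "-")
  if (any(n_components < 1 | n_components > object$n_components))
    stop("n_components out of range")
  out <- vapply(n_components, function(a) {
    b <- drop(object$R[, seq_len(a), drop = FALSE] %*% object$q[seq_len(a)])
    drop(Xc %*% b) + object$y_center
  }, numeric(nrow(X)))
  if (length(n_components) == 1L) drop(out) else
    `colnames<-`(as.matrix(out), paste0("ncomp", n_components))
}

#' Feature-relevance scores from a PLS model
#'
#' `vip_scores()` computes the variable importance in the projection,
#' `VIP_j = sqrt( p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a SSY_a )` with
#' `SSY_a = q_a^2 (t_a' t_a)`, which satisfies `sum_j VIP_j^2 = p`.
#' `beta_scores()` ranks by the absolute standardized regression coefficient.
#' Both return rankings sorted by descending score, ties broken by ascending
#' feature index for reproducibility.
#'
#' @param model a fitted `"pls_model"`.
#' @return A `"feature_ranking"` data.frame with columns `feature`, `score`,
#'   ordered by decreasing relevance, and attribute `method`.
#' @export
vip_scores <- function(model) {
  ssy <- model$q^2 * model$tt
  denom <- sum(ssy)
  if (denom <= 0) stop("no explained y-variance: VIP undefined")
  p <- length(model$feature_ids)
  # W columns are unit-norm already; keep the normalization for safety
  W2 <- sweep(model$W^2, 2, colSums(model$W^2), "/")
  vip <- sqrt(p * drop(W2 %*% ssy) / denom)
  new_ranking(model$feature_ids, vip, "VIP")
}

#' @rdname vip_scores
#' @export
beta_scores <- function(model) {
  new_ranking(model$feature_ids, abs(model$coefficients), "BETA")
}

new_ranking <- function(features, scores, method) {
  o <- order(-scores, seq_along(scores))
  structure(data.frame(feature = features[o], score = unname(scores[o]),
                       stringsAsFactors = FALSE),
            method = method, class = c("feature_ranking", "data.frame"))
}

#' Fit metrics
#'
#' `rmse()` is `sqrt(mean((y - yhat)^2))`; `r2()` is
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y observed values.
#' @param yhat predictions of the same length.
#' @return A single number.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || !length(y)) stop("lengths must match and be >= 1")
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse
#' @export
r2 <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2) stop("lengths must match and be >= 2")
  ss <- sum((y - mean(y))^2)
  if (ss <= 0) stop("zero variance in y: r2 undefined")
  1 - sum((y - yhat)^2) / ss
}

#' Serialize a PLS model to JSON and back
#'
#' Stores weights, loadings, coefficients, centering, and the scale
#' transform with their feature ids, so a model can be reloaded and applied
#' without refitting.
#'
#' @param model a `"pls_model"`.
#' @param path file path.
#' @export
write_pls_model <- function(model, path) {
  obj <- unclass(model)
  obj$scores <- NULL  # training scores are not needed for prediction
  obj$scale <- if (!is.null(model$scale)) unclass(model$scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W", "P", "R")) obj[[nm]] <- as.matrix(obj[[nm]])
  obj$coefficients <- stats::setNames(as.numeric(obj$coefficients), obj$feature_ids)
  obj$x_center <- stats::setNames(as.numeric(obj$x_center), obj$feature_ids)
  if (!is.null(obj$scale)) {
    obj$scale$means <- stats::setNames(as.numeric(obj$scale$means), obj$scale$feature_ids)
    obj$scale$sds <- stats::setNames(as.numeric(obj$scale$sds), obj$scale$feature_ids)
    class(obj$scale) <- "scale_transform"
  }
  structure(obj, class = "pls_model")
}
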