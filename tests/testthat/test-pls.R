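test_that("full-rank PLS equals the normal-equations OLS solution", {
  inst <- random_instance(20, 4, seed = 2)
  fit <- fit_pls(inst$X, inst$y, n_components = 4)
  XtX <- crossprod(cbind(1, inst$X))
  b_ols <- solve(XtX, crossprod(cbind(1, inst$X), inst$y))
  expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(drop(b_ols)),
               tolerance = 1e-8)
  expect_equal(unname(predict(fit, inst$X)),
               drop(cbind(1, inst$X) %*% b_ols), tolerance = 1e-8)
})

test_that("one-predictor PLS is the simple least-squares line", {
  set.seed(4)
  x <- matrix(rnorm(30), dimnames = list(NULL, "x1"))
  y <- 2 + 3 * x[, 1] + rnorm(30, 0, 0.3)
  fit <- fit_pls(x, y, 1)
  lmfit <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
})

test_that("model structure satisfies the PLS invariants", {
  for (seed in 1:5) {
    inst <- random_instance(40, 12, seed = seed)
    fit <- fit_pls(scale(inst$X), inst$y, 6)
    # unit-norm weights
    expect_equal(unname(colSums(fit$W^2)), rep(1, 6), tolerance = 1e-10)
    # mutually orthogonal scores
    G <- crossprod(fit$scores)
    offdiag <- abs(G[upper.tri(G)])
    expect_lt(max(offdiag / sqrt(tcrossprod(diag(G))[upper.tri(G)])), 1e-8)
    # training RMSE non-increasing in the number of components
    tr <- predict(fit, scale(inst$X), n_components = 1:6)
    rmses <- sqrt(colMeans((inst$y - tr)^2))
    expect_true(all(diff(rmses) <= 1e-12))
  }
})

test_that("predictions align features by id and handle centered rows", {
  inst <- random_instance(25, 5, seed = 9)
  fit <- fit_pls(inst$X, inst$y, 3)
  perm <- inst$X[, c(3, 1, 5, 2, 4)]
  expect_equal(predict(fit, perm), predict(fit, inst$X))
  at_center <- matrix(fit$x_center, 1, dimnames = list(NULL, colnames(inst$X)))
  expect_equal(unname(predict(fit, at_center)), mean(inst$y))
  expect_error(predict(fit, inst$X[, 1:3]), "lacks")
})

test_that("VIP matches an independent transcription of its formula", {
  inst <- random_instance(30, 5, seed = 13)
  fit <- fit_pls(scale(inst$X), inst$y, 2)
  # brute-force evaluation from W, q, t
  ssy <- vapply(1:2, function(a) fit$q[a]^2 * sum(fit$scores[, a]^2), numeric(1))
  vip_manual <- sqrt(5 * sapply(1:5, function(j)
    sum(ssy * (fit$W[j, ]^2 / colSums(fit$W^2)))) / sum(ssy))
  vr <- vip_scores(fit)
  expect_equal(vr$score[match(paste0("x", 1:5), vr$feature)],
               unname(vip_manual), tolerance = 1e-10)
})

test_that("VIP normalization holds for every fitted model", {
  for (seed in 1:6) {
    n <- 20 + seed * 5; p <- 3 + seed * 2
    inst <- random_instance(n, p, seed = seed)
    fit <- fit_pls(inst$X, inst$y, min(4, p))
    expect_equal(sum(vip_scores(fit)$score^2), p, tolerance = 1e-8)
  }
  one <- random_instance(15, 1, seed = 3)
  expect_equal(vip_scores(fit_pls(one$X, one$y, 1))$score, 1, tolerance = 1e-12)
})

test_that("BETA ranks pure-noise features last in a strong-signal instance", {
  last <- vapply(1:20, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(200), 50, 4,
                dimnames = list(NULL, c("s1", "s2", "s3", "noise")))
    y <- 3 * X[, 1] + 2 * X[, 2] + X[, 3] + rnorm(50, 0, 0.2)
    fitted <- fit_pls(scale(X), y, 3)
    utils::tail(beta_scores(fitted)$feature, 1) == "noise"
  }, logical(1))
  expect_gte(mean(last), 0.9)
})

test_that("collinear duplicates split relevance instead of zeroing out", {
  set.seed(7)
  X <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  X <- cbind(X, adup = X[, "a"] + rnorm(40, 0, 1e-3))
  y <- 2 * X[, "a"] + rnorm(40, 0, 0.3)
  fitted <- fit_pls(scale(X), y, 2)
  bs <- beta_scores(fitted)
  expect_gt(bs$score[bs$feature == "a"], 0)
  expect_gt(bs$score[bs$feature == "adup"], 0)
})

test_that("fit metrics follow their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(rmse(y, y), 0)
  expect_equal(r2(y, y), 1)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(r2(y, rep(mean(y), 4)), 0)
  expect_error(r2(c(1, 1), c(1, 2)), "variance")
  expect_error(rmse(1:3, 1:2), "lengths")
})

test_that("JSON serialization round-trips predictions exactly", {
  ds <- test_dataset(seed = 21, n_herds = 2)$dataset
  X <- design_matrix(ds)
  sc <- fit_scale(X)
  fit <- fit_pls(apply_scale(sc, X), ds$info$bw, 4, scale = sc)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(fit, path)
  back <- read_pls_model(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  inst <- random_instance(40, 8, seed = 17)
  Xs <- scale(inst$X)
  fit <- fit_pls(Xs, inst$y, 3)
  ref <- mixOmics::pls(Xs, inst$y, ncomp = 3, mode = "regression", scale = FALSE)
  ref_pred <- predict(ref, Xs)$predict[, 1, 3]
  expect_equal(unname(predict(fit, Xs)), unname(ref_pred), tolerance = 1e-6)
})

test_that("rank-deficient inputs stop early with a warning", {
  set.seed(5)
  X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  X <- cbind(X, c = X[, 1])  # rank 2
  y <- X[, 1] + X[, 2]       # fully explained by 2 components
  expect_warning(fitted <- fit_pls(X, y, 3), "stopping at 2")
  expect_equal(fitted$n_components, 2)
})
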