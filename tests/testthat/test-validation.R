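test_that("strata boundaries are the type-7 quartiles of bodyweight", {
  st <- make_strata(1:100)
  expect_equal(st$boundaries, c(1, 25.75, 50.5, 75.25, 100))
  expect_equal(sort(unique(st$labels)), 1:4)
  st4 <- make_strata(c(500, 550, 600, 650))
  expect_equal(sort(st4$labels), 1:4)  # one record per stratum
  expect_error(make_strata(rep(600, 10)), "distinct")
})

test_that("stratified folds are balanced within one record per stratum", {
  strata <- rep(1:4, each = 10)
  folds <- stratified_kfold(strata, k = 10, seed = 2)
  tab <- table(folds, strata)
  expect_true(all(tab == 1))

  strata41 <- c(strata, 1)
  folds41 <- stratified_kfold(strata41, k = 10, seed = 2)
  tab41 <- table(folds41, strata41)
  expect_true(all(tab41[, 2:4] == 1))
  expect_equal(sort(unname(tab41[, 1])), c(rep(1, 9), 2))

  expect_identical(stratified_kfold(strata, 10, seed = 7),
                   stratified_kfold(strata, 10, seed = 7))
  expect_warning(stratified_kfold(rep(1:2, c(30, 3)), k = 10, seed = 1),
                 "fewer records")
})

test_that("herd partitions are herd-disjoint with in-range validation shares", {
  sizes <- c(h01 = 31, h02 = 39, h03 = 146, h04 = 377, h05 = 153,
             h06 = 174, h07 = 630, h08 = 174, h09 = 125)
  expect_equal(sum(sizes), 1849)
  # single-herd feasibility arithmetic on the printed cleaned herd sizes
  expect_true(sizes[["h04"]] / 1849 >= 0.10 && sizes[["h04"]] / 1849 <= 0.30)
  expect_gt(sizes[["h07"]] / 1849, 0.30)

  scheme <- herd_partitions(sizes, n_repeats = 101, seed = 3)
  expect_length(scheme$repeats, 101)
  for (rp in scheme$repeats) {
    expect_length(intersect(rp$train_herds, rp$validation_herds), 0)
    expect_setequal(c(rp$train_herds, rp$validation_herds), names(sizes))
    fr <- sum(sizes[rp$validation_herds]) / sum(sizes)
    expect_gte(fr, 0.10); expect_lte(fr, 0.30)
  }
  # h07 alone exceeds the 30% cap, so it never stands alone
  solo <- vapply(scheme$repeats, function(rp)
    identical(rp$validation_herds, "h07"), logical(1))
  expect_false(any(solo))

  expect_error(herd_partitions(c(a = 50, b = 50)), "no herd subset")
  expect_warning(herd_partitions(c(a = 80, b = 15, c = 5), n_repeats = 101,
                                 seed = 1), "replacement")
})

test_that("herd-independent evaluation is reproducible and picks sane components", {
  g <- test_dataset(seed = 31, n_herds = 6)
  ds <- g$dataset
  sizes <- table(ds$info$herd_id)
  scheme <- herd_partitions(setNames(as.integer(sizes), names(sizes)),
                            n_repeats = 10, seed = 4)
  feats <- c("parity", "dim", "my", g$truth$informative_features)
  ev1 <- evaluate_iv(feats, ds, scheme, family_tag = "A")
  ev2 <- evaluate_iv(feats, ds, scheme, family_tag = "A")
  expect_equal(ev1$rmse_iv_mean, ev2$rmse_iv_mean)
  expect_gte(ev1$n_components, 1)
  expect_lte(ev1$n_components, 10)
  ev_one <- evaluate_iv(feats, ds, scheme, max_components = 1)
  expect_equal(ev_one$n_components, 1)
})

test_that("herd effects make herd-disjoint validation harder than stratified CV", {
  run_at <- function(herd_sd) {
    g <- generate_dataset(test_config(seed = 31, n_herds = 8,
                                      herd_sd = herd_sd))
    ds <- g$dataset
    sizes <- table(ds$info$herd_id)
    scheme <- herd_partitions(setNames(as.integer(sizes), names(sizes)),
                              n_repeats = 20, seed = 4)
    feats <- c("parity", "dim", "my", g$truth$informative_features)
    evaluate_iv(feats, ds, scheme)
  }
  no_herd <- run_at(0)
  expect_lt(abs(no_herd$rmse_iv_mean - no_herd$rmse_scv_mean),
            2 * no_herd$rmse_iv_sd)
  big_herd <- run_at(40)
  expect_gt(big_herd$rmse_iv_mean, big_herd$rmse_scv_mean)
})

test_that("per-family finalists minimize iv RMSE with documented tie-breaks", {
  mk <- function(tag, m, s, scv = 50, nf = 10)
    structure(list(family_tag = tag, rmse_iv_mean = m, rmse_iv_sd = s,
                   rmse_scv_mean = scv, n_features = nf),
              class = "evaluation_summary")
  single <- pick_best_per_family(list(mk("A", 55, 3)))
  expect_equal(single$A$rmse_iv_mean, 55)
  tie <- pick_best_per_family(list(mk("A", 55, 3), mk("A", 55, 2)))
  expect_equal(tie$A$rmse_iv_sd, 2)
  six <- pick_best_per_family(unlist(lapply(LETTERS[1:6], function(f)
    list(mk(f, 55, 3), mk(f, 54, 3))), recursive = FALSE))
  expect_length(six, 6)
  expect_true(all(vapply(six, `[[`, numeric(1), "rmse_iv_mean") == 54))
})

test_that("external validation freezes training scaling and round-trips models", {
  g <- generate_dataset(test_config(seed = 9, n_herds = 4))
  ext <- generate_dataset(mirbw:::generator_config_modify(test_config(seed = 9, n_herds = 4),
                                                          n_herds = 1),
                          truth = g$truth, herd_offset = 4)
  ds <- g$dataset
  feats <- c("parity", "dim", "my", g$truth$informative_features)
  sel <- list(structure(list(family_tag = "Z", feature_ids = feats,
                             n_components = 5), class = "selected_model"),
              structure(list(family_tag = "Y", feature_ids = feats[-1],
                             n_components = 4), class = "selected_model"))
  res <- finalize_and_external_validate(sel, ds, ext$dataset)
  expect_equal(dim(res$correlations), c(2, 2))
  expect_equal(diag(res$correlations), c(Z = 1, Y = 1))
  expect_gt(res$correlations[1, 2], 0.9)

  # external copy of training scores at the training RMSE
  same <- finalize_and_external_validate(sel[1], ds, ds)
  expect_equal(same$summaries$rmse_v, same$summaries$rmse_train)

  # serialization fidelity of a finalist
  m <- res$models[[1]]
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, path)
  back <- read_pls_model(path)
  Xe <- design_matrix(ext$dataset, m$feature_ids)
  expect_equal(predict(back, Xe), predict(m, Xe), tolerance = 1e-12)

  # the external herd never influences the fit: rmse_v within a sane band
  expect_lt(res$summaries$rmse_v[1], 0.75 * sd(ds$info$bw))
})
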