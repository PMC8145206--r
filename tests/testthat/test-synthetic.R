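test_that("generation is deterministic and per-herd streams are stable", {
  cfg <- test_config(seed = 42, n_herds = 3)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset, g2$dataset)
  expect_identical(g1$truth$informative_indices, g2$truth$informative_indices)

  # adding herds must not change the existing ones
  g5 <- generate_dataset(test_config(seed = 42, n_herds = 5))
  keep <- g5$dataset$info$herd_id %in% sprintf("h%02d", 1:3)
  expect_equal(g5$dataset$spectra[keep, ], g1$dataset$spectra)
  expect_equal(g5$dataset$info[keep, -1], g1$dataset$info[-1],
               ignore_attr = TRUE)
})

test_that("generated covariates sit in plausible Holstein ranges", {
  ds <- test_dataset(seed = 8)$dataset
  expect_true(all(ds$info$dim >= 5 & ds$info$dim <= 365))
  expect_true(all(ds$info$my > 0))
  expect_gt(mean(ds$info$bw), 550)
  expect_lt(mean(ds$info$bw), 680)
  expect_true(all(table(ds$info$herd_id) >= 10))
  # milk yield rises then falls along the lactation (Wood curve shape)
  dim_bins <- cut(ds$info$dim, c(0, 60, 200, 400))
  mids <- tapply(ds$info$my, dim_bins, mean)
  expect_gt(mids[2], mids[3] * 0.95)
})

test_that("adjacent spectral points are strongly correlated", {
  ds <- test_dataset(seed = 15)$dataset
  p <- ncol(ds$spectra)
  lag1 <- vapply(seq_len(p - 1), function(j)
    cor(ds$spectra[, j], ds$spectra[, j + 1]), numeric(1))
  expect_gt(mean(lag1), 0.9)
})

test_that("zero signal-to-noise leaves spectra uninformative about bodyweight", {
  g <- generate_dataset(test_config(seed = 7, n_herds = 6, signal_to_noise = 0))
  ds <- g$dataset
  y <- ds$info$bw
  cors <- abs(apply(ds$spectra, 2, cor, y = y))
  expect_lt(mean(cors), 0.12)
  folds <- stratified_kfold(make_strata(y)$labels, 10, seed = 3)
  cv <- mirbw:::cv_pls(ds$spectra, y, folds, 10)
  expect_lt(abs(cv$rmse_mean / sd(y) - 1), 0.1)
})

test_that("a single high-SNR zone supports near-perfect 1-component recovery", {
  cfg <- test_config(seed = 11, n_herds = 6, n_informative_zones = 1,
                     zone_width = 120, signal_to_noise = 100,
                     herd_sd = 0, resid_sd = 0.01)
  g <- generate_dataset(cfg)
  Xz <- design_matrix(g$dataset, g$truth$informative_features)
  y <- g$dataset$info$bw
  sc <- fit_scale(Xz)
  fit <- fit_pls(apply_scale(sc, Xz), y, 1)
  expect_lt(rmse(y, predict(fit, apply_scale(sc, Xz))), 0.05 * sd(y))
})

test_that("outlier injection perturbs exactly the requested records", {
  g <- test_dataset(seed = 5)
  none <- inject_outliers(g$dataset, g$truth, 0, 0)
  expect_identical(none$dataset, g$dataset)

  inj <- inject_outliers(g$dataset, g$truth, n_spectral = 0, n_bw = 3,
                         magnitude = 12)
  expect_equal(nrow(inj$truth$outlier_ids), 3)
  flt <- bw_range_filter(inj$dataset)
  expect_setequal(flt$removed, inj$truth$outlier_ids$record_id)

  both <- inject_outliers(g$dataset, g$truth, n_spectral = 2, n_bw = 2)
  changed <- which(rowSums(abs(both$dataset$spectra - g$dataset$spectra)) > 0)
  expect_length(changed, 2)
  expect_error(inject_outliers(g$dataset, g$truth, 1, 0, magnitude = -1),
               "magnitude")
})

test_that("external herds share the spectral ground truth of the training set", {
  cfg <- test_config(seed = 9, n_herds = 3)
  g <- generate_dataset(cfg)
  ext <- generate_dataset(mirbw:::generator_config_modify(cfg, n_herds = 1),
                          truth = g$truth, herd_offset = 3)
  expect_identical(ext$truth$informative_indices, g$truth$informative_indices)
  expect_identical(unique(ext$dataset$info$herd_id), "h04")
  # the zone signal learned on training herds transfers to the external herd
  feats <- c("parity", "dim", "my", g$truth$informative_features)
  X <- design_matrix(g$dataset, feats)
  sc <- fit_scale(X)
  fit <- fit_pls(apply_scale(sc, X), g$dataset$info$bw, 5, scale = sc)
  fit$scale <- sc
  ev <- rmse(ext$dataset$info$bw, predict(fit, design_matrix(ext$dataset, feats)))
  expect_lt(ev, 0.75 * sd(g$dataset$info$bw))
})

test_that("truth serialization writes valid JSON", {
  g <- test_dataset(seed = 2, n_herds = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(g$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$informative_indices, g$truth$informative_indices)
  expect_equal(back$noise_floor_rmse, g$truth$noise_floor_rmse)
})

test_that("config validation rejects impossible settings", {
  expect_error(generator_config(parity_probs = rep(0.2, 6)), "sum to 1")
  expect_error(generator_config(signal_to_noise = -1))
  expect_error(generator_config(n_informative_zones = 40, zone_width = 60,
                                grid = test_grid(50)), "zones")
})
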