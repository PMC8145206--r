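#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its standard default:
#' derivative gap 5, GH threshold 3 on components explaining 99% of
#' spectral variance, filter significance 5%, tolerance grid 0..12,
#' validation share 10-30% over 101 herd-disjoint repeats, at most 10 PLS
#' components, 10 CV folds. Configurations round-trip losslessly through
#' YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param generator a [generator_config()] describing the synthetic study
#'   population (ignored when an input CSV is supplied to [run_pipeline()]).
#' @param derivative_gap first-derivative gap in grid points.
#' @param hso intervals (cm^-1) of the expert-preselected subset.
#' @param gh_threshold,gh_var_explained GH filter tunables.
#' @param alpha filter-selection significance level.
#' @param tolerances tolerance grid (percent) for model retention.
#' @param fraction_range,n_repeats herd-partition tunables.
#' @param max_components PLS component cap.
#' @param k_folds stratified CV folds.
#' @param n_external_herds herds generated for external validation.
#' @param seed master seed for every stochastic stage.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            derivative_gap = 5,
                            hso = hso_intervals(),
                            gh_threshold = 3, gh_var_explained = 0.99,
                            alpha = 0.05,
                            tolerances = 0:12,
                            fraction_range = c(0.10, 0.30), n_repeats = 101,
                            max_components = 10, k_folds = 10,
                            n_external_herds = 1, seed = 1L) {
  structure(list(generator = generator, derivative_gap = derivative_gap,
                 hso = hso, gh_threshold = gh_threshold,
                 gh_var_explained = gh_var_explained, alpha = alpha,
                 tolerances = tolerances, fraction_range = fraction_range,
                 n_repeats = n_repeats, max_components = max_components,
                 k_folds = k_folds, n_external_herds = n_external_herds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `"pipeline_config"`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$generator <- unclass(obj$generator)
  obj$generator$grid <- list(start = config$generator$grid[1],
                             end = config$generator$grid[length(config$generator$grid)],
                             n_points = length(config$generator$grid))
  obj$hso <- apply(obj$hso, 1, function(r) list(lo = r[[1]], hi = r[[2]]))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- obj$generator
  grid <- wn_grid(g$grid$start, g$grid$end, g$grid$n_points)
  obj$generator <- generator_config(
    n_herds = g$n_herds, cows_per_herd = unlist(g$cows_per_herd),
    records_per_cow = unlist(g$records_per_cow),
    parity_probs = unlist(g$parity_probs), dim_range = unlist(g$dim_range),
    grid = grid, n_informative_zones = g$n_informative_zones,
    zone_width = g$zone_width, signal_to_noise = g$signal_to_noise,
    herd_sd = g$herd_sd, cow_sd = g$cow_sd, resid_sd = g$resid_sd,
    seed = g$seed)
  obj$hso <- do.call(rbind, lapply(obj$hso, function(r) c(lo = r$lo, hi = r$hi)))
  obj$tolerances <- unlist(obj$tolerances)
  obj$fraction_range <- unlist(obj$fraction_range)
  do.call(pipeline_config, obj[setdiff(names(obj), character(0))])
}

#' Run the full analysis chain
#'
#' Simulate (or load) -> first derivative -> three-stage cleaning -> filter
#' and wrapper feature selection on the ALL and HSO starting subsets (six
#' families: ALL_SBF/HSO with VIP/BETA rankings, plus HSO_SBF) ->
#' tolerance-based retention -> herd-independent repeated evaluation ->
#' per-family finalists -> refit on all training records and external-herd
#' validation -> reporting (performance table, lactation curves, inter-model
#' prediction correlations, manifest).
#'
#' @param config a [pipeline_config()].
#' @param out_dir directory for artifacts (created if needed); `NULL`
#'   writes nothing.
#' @param stages subset of `c("simulate", "clean", "select", "validate",
#'   "report")` to run (prior stages are always needed and run; the toggle
#'   truncates the chain).
#' @param input_csv optional path of a raw dataset to use instead of the
#'   generator (external validation then requires simulated herds too, so
#'   the generator grid must match).
#' @param verbose log per-stage record counts to stderr.
#' @return A list with the artifacts of every executed stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         stages = c("simulate", "clean", "select",
                                    "validate", "report"),
                         input_csv = NULL, verbose = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  art <- list(config = config)

  # -- simulate ------------------------------------------------------------
  if (is.null(input_csv)) {
    gen <- generate_dataset(config$generator)
    ext <- generate_dataset(
      generator_config_modify(config$generator, n_herds = config$n_external_herds),
      truth = gen$truth, herd_offset = config$generator$n_herds)
    art$truth <- ext$truth
    raw <- gen$dataset; raw_ext <- ext$dataset
  } else {
    raw <- read_dataset(input_csv)
    raw_ext <- NULL
  }
  log_msg("simulate: %d training records (%d herds)", n_records(raw),
          length(unique(raw$info$herd_id)))
  art$raw <- raw
  if (!is.null(out_dir) && is.null(input_csv)) {
    write_dataset(raw, file.path(out_dir, "training_raw.csv"))
    write_truth(art$truth, file.path(out_dir, "truth.json"))
  }
  if (!"clean" %in% stages && !"select" %in% stages &&
      !"validate" %in% stages && !"report" %in% stages)
    return(finish_pipeline(art, config, out_dir))

  # -- preprocess + clean ---------------------------------------------------
  der <- first_derivative(raw, gap = config$derivative_gap)
  cl <- clean_dataset(der, gh_threshold = config$gh_threshold,
                      var_explained = config$gh_var_explained,
                      n_components = config$max_components)
  art$cleaned <- cl$dataset
  art$cleaning_report <- cl$report
  log_msg("clean: %d -> %d records (%.2f%% removed)", cl$report$n_input,
          cl$report$n_output, 100 * cl$report$fraction_removed)
  if (!is.null(out_dir))
    write_cleaning_report(cl$report, file.path(out_dir, "cleaning_report.json"))
  if (!any(c("select", "validate", "report") %in% stages))
    return(finish_pipeline(art, config, out_dir))

  # -- feature selection ----------------------------------------------------
  ds <- art$cleaned
  all_features <- colnames(design_matrix(ds))
  hso_ds <- select_regions(ds, config$hso)
  hso_features <- c("parity", "dim", "my", wn_names(hso_ds$grid))
  strata <- make_strata(ds$info$bw)$labels
  sbf_all <- sbf_filter(ds, alpha = config$alpha, features = all_features)
  sbf_hso <- sbf_filter(ds, alpha = config$alpha, features = hso_features)
  art$sbf <- list(ALL = sbf_all, HSO = sbf_hso)
  starting <- list(
    ALL_SBF = sbf_all$feature[sbf_all$retained],
    HSO = hso_features,
    HSO_SBF = sbf_hso$feature[sbf_hso$retained])
  log_msg("select: starting sizes ALL=%d ALL_SBF=%d HSO=%d HSO_SBF=%d",
          length(all_features), length(starting$ALL_SBF),
          length(starting$HSO), length(starting$HSO_SBF))
  families <- c("ALL_SBF_VIP", "ALL_SBF_BETA", "HSO_VIP", "HSO_BETA",
                "HSO_SBF_VIP", "HSO_SBF_BETA")
  art$traces <- lapply(families, function(fam) {
    base <- sub("_(VIP|BETA)$", "", fam)
    method <- sub("^.*_", "", fam)
    run_rfe(ds, starting[[base]], ranking_method = method, strata = strata,
            k = config$k_folds, max_components = config$max_components,
            seed = config$seed, family_tag = fam)
  })
  names(art$traces) <- families
  art$selected <- unlist(lapply(art$traces, tolerance_select,
                                tolerances = config$tolerances),
                         recursive = FALSE)
  log_msg("select: %d retained subsets (%d per family)",
          length(art$selected), length(config$tolerances))
  if (!any(c("validate", "report") %in% stages))
    return(finish_pipeline(art, config, out_dir))

  # -- herd-independent validation + external validation --------------------
  herd_sizes <- table(ds$info$herd_id)
  scheme <- herd_partitions(stats::setNames(as.integer(herd_sizes),
                                            names(herd_sizes)),
                            fraction_range = config$fraction_range,
                            n_repeats = config$n_repeats, seed = config$seed)
  art$scheme <- scheme
  art$summaries <- lapply(art$selected, function(m)
    evaluate_iv(m$feature_ids, ds, scheme,
                max_components = config$max_components,
                family_tag = m$family_tag, cv_seed = config$seed))
  art$finalists <- pick_best_per_family(art$summaries)
  log_msg("validate: %d models evaluated over %d repeats; %d finalists",
          length(art$summaries), config$n_repeats, length(art$finalists))
  if (!is.null(raw_ext)) {
    ext_clean <- first_derivative(raw_ext, gap = config$derivative_gap)
    art$external <- finalize_and_external_validate(art$finalists,
                                                   ds, ext_clean)
  }
  if (!"report" %in% stages) return(finish_pipeline(art, config, out_dir))

  # -- report ---------------------------------------------------------------
  perf <- do.call(rbind, lapply(art$finalists, function(s)
    data.frame(family = s$family_tag, n_features = s$n_features,
               rmse_iv_mean = s$rmse_iv_mean, rmse_iv_sd = s$rmse_iv_sd,
               rmse_scv_mean = s$rmse_scv_mean, rmse_scv_sd = s$rmse_scv_sd,
               n_components = s$n_components, r2_scv = s$r2_scv,
               stringsAsFactors = FALSE)))
  if (!is.null(art$external))
    perf$rmse_v <- art$external$summaries$rmse_v[match(perf$family,
                                                       art$external$summaries$family_tag)]
  rownames(perf) <- NULL
  art$performance <- perf
  if (!is.null(art$external)) {
    ext_info <- first_derivative(raw_ext, gap = config$derivative_gap)$info
    best <- which.min(art$external$summaries$rmse_v)
    art$lactation_curves <- lactation_curve(
      data.frame(dim = ext_info$dim, parity_class = ext_info$parity_class,
                 pred_bw = art$external$predictions[, best]))
  }
  if (!is.null(out_dir)) {
    utils::write.csv(perf, file.path(out_dir, "performance.csv"),
                     row.names = FALSE)
    if (!is.null(art$external)) {
      utils::write.csv(art$lactation_curves,
                       file.path(out_dir, "lactation_curves.csv"),
                       row.names = FALSE)
      utils::write.csv(art$external$correlations,
                       file.path(out_dir, "prediction_correlations.csv"))
    }
  }
  finish_pipeline(art, config, out_dir)
}

# modify selected fields of a generator config, revalidating
generator_config_modify <- function(config, ...) {
  args <- utils::modifyList(unclass(config), list(...))
  do.call(generator_config, args)
}

finish_pipeline <- function(art, config, out_dir) {
  if (!is.null(out_dir)) {
    cfg_path <- file.path(out_dir, "config.yaml")
    write_pipeline_config(config, cfg_path)
    manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                     seed = config$seed,
                     package_version = as.character(utils::packageVersion("mirbw")),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  invisible(art)
}

#' Average predicted bodyweight by lactation stage
#'
#' Bins predictions on days in milk (default 5-day bins) within each parity
#' class and reports the mean predicted bodyweight per bin — the standard
#' summary of a predicted bodyweight lactation curve, where the
#' early-lactation dip should be visible.
#'
#' @param predictions data.frame with columns `dim`, `parity_class` and
#'   `pred_bw`.
#' @param bin_width bin width in days (default 5).
#' @return A data.frame `parity_class`, `dim_mid`, `mean_bw`, `n` (bins
#'   with at least one record only).
#' @export
lactation_curve <- function(predictions, bin_width = 5) {
  stopifnot(all(c("dim", "parity_class", "pred_bw") %in% names(predictions)))
  if (!nrow(predictions)) stop("empty predictions")
  bin <- floor((predictions$dim - 1) / bin_width)
  agg <- stats::aggregate(pred_bw ~ parity_class + bin, data =
                            cbind(predictions, bin = bin), FUN = mean)
  cnt <- stats::aggregate(pred_bw ~ parity_class + bin, data =
                            cbind(predictions, bin = bin), FUN = length)
  out <- data.frame(parity_class = agg$parity_class,
                    dim_mid = agg$bin * bin_width + (bin_width + 1) / 2,
                    mean_bw = agg$pred_bw, n = cnt$pred_bw)
  out[order(out$parity_class, out$dim_mid), ]
}

#' Pairwise Pearson correlation of model predictions
#'
#' @param models list of fitted `"pls_model"`s (with stored scale
#'   transforms).
#' @param dataset a `mir_dataset` to predict on.
#' @return Symmetric correlation matrix with unit diagonal; entries
#'   involving a constant prediction are NA with a warning.
#' @export
prediction_correlation <- function(models, dataset) {
  if (length(models) < 2) stop("need at least 2 models")
  preds <- vapply(models, function(f)
    predict(f, design_matrix(dataset, f$feature_ids)),
    numeric(n_records(dataset)))
  if (any(apply(preds, 2, stats::sd) == 0))
    warning("constant predictions: correlation undefined for some pairs")
  suppressWarnings(cc <- stats::cor(preds))
  diag(cc) <- 1
  cc
}
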