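#' Configuration of the synthetic multi-herd generator
#'
#' Describes the study population the generator emulates: several herds of
#' unequal size, cows with repeated test-day records, parities 1..6 (pooled
#' to 1..4+ downstream), lactation-stage-dependent milk yield and bodyweight
#' (with an early-lactation dip), and spectra whose informative wavenumber
#' zones carry a bodyweight-related signal.
#'
#' @param n_herds number of herds.
#' @param cows_per_herd inclusive `c(min, max)` cows per herd.
#' @param records_per_cow inclusive `c(min, max)` test-day records per cow.
#' @param parity_probs probability vector over parities 1..6 (sums to 1).
#' @param dim_range inclusive `c(min, max)` days in milk.
#' @param grid the `"wn_grid"` spectra are generated on.
#' @param n_informative_zones number of informative wavenumber zones.
#' @param zone_width width of each informative zone (cm^-1).
#' @param signal_to_noise peak-amplitude signal per 1 SD of the latent
#'   bodyweight signal, expressed in units of the spectral noise SD
#'   (0 = spectra carry no bodyweight information).
#' @param herd_sd,cow_sd,resid_sd SDs (kg) of the herd effect, the cow
#'   effect, and the residual bodyweight noise.
#' @param seed integer seed; the random stream is partitioned per herd so
#'   that adding herds leaves existing ones unchanged.
#' @return A validated `"generator_config"` list.
#' @export
generator_config <- function(n_herds = 9,
                             cows_per_herd = c(12, 45),
                             records_per_cow = c(2, 8),
                             parity_probs = c(0.32, 0.25, 0.18, 0.12, 0.08, 0.05),
                             dim_range = c(5, 365),
                             grid = make_canonical_grid(),
                             n_informative_zones = 4,
                             zone_width = 20,
                             signal_to_noise = 5,
                             herd_sd = 12, cow_sd = 20, resid_sd = 18,
                             seed = 1L) {
  stopifnot(n_herds >= 1, all(cows_per_herd >= 1), all(records_per_cow >= 1),
            length(parity_probs) == 6, all(parity_probs >= 0),
            dim_range[1] >= 1, dim_range[2] >= dim_range[1],
            n_informative_zones >= 1, zone_width > 0,
            signal_to_noise >= 0, herd_sd >= 0, cow_sd >= 0, resid_sd >= 0)
  if (abs(sum(parity_probs) - 1) > 1e-9)
    stop("parity_probs must sum to 1 (within 1e-9)")
  span <- grid[length(grid)] - grid[1]
  if (n_informative_zones * 3 * zone_width > span)
    stop("informative zones do not fit inside the grid range")
  structure(list(n_herds = as.integer(n_herds),
                 cows_per_herd = as.integer(cows_per_herd),
                 records_per_cow = as.integer(records_per_cow),
                 parity_probs = parity_probs, dim_range = dim_range,
                 grid = grid,
                 n_informative_zones = as.integer(n_informative_zones),
                 zone_width = zone_width, signal_to_noise = signal_to_noise,
                 herd_sd = herd_sd, cow_sd = cow_sd, resid_sd = resid_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# fixed biological/spectral constants of the generator (documented in the
# methods vignette; magnitudes chosen as plausible Holstein values)
gen_const <- list(
  bw_base = c(`1` = 560, `2` = 615, `3` = 648, `4plus` = 665),  # kg
  dip_kg = 25, dip_tau = 50,        # early-lactation loss, nadir ~50 DIM
  gain_per_day = 0.12,              # slow within-lactation regain, kg/day
  wood_a = 16, wood_b = 0.20, wood_c = 0.0035,
  my_parity_scale = c(0.85, 1, 1.06, 1.10), my_noise_sd = 2.5,
  ref_mean = 615, ref_sd = 45,      # standardization of the latent signal
  n_background_peaks = 8, background_amp_sd = 0.05,
  sigma_smooth = 0.006, sigma_white = 0.0012, smooth_kernel_sd = 2.5,
  my_mix = 0.10, zone_noise = 0.02  # milk-yield admixture (background peaks)
)

# run code under a private RNG stream without disturbing the caller's state
with_stream <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

stream_seed <- function(seed, k) as.integer((as.numeric(seed) + 104729 * k) %% 2147483629 + 1)

# white noise convolved with a gaussian kernel, rescaled to unit sd
smooth_noise <- function(p, kernel_sd) {
  half <- max(1L, ceiling(3 * kernel_sd))
  kern <- stats::dnorm(seq(-half, half), sd = kernel_sd)
  z <- stats::rnorm(p + 2 * half)
  sm <- stats::filter(z, kern, sides = 2)[(half + 1):(half + p)]
  as.numeric(sm) / sqrt(sum(kern^2))
}

gauss_peak <- function(grid, center, sd) exp(-0.5 * ((as.numeric(grid) - center) / sd)^2)

# sample one integer from an inclusive range (safe when lo == hi)
sample_range <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1) - 1L

# draw the spectral ground truth (zone centers, weights, background layout)
draw_truth <- function(config) {
  grid <- as.numeric(config$grid)
  span <- grid[length(grid)] - grid[1]
  with_stream(stream_seed(config$seed, 0L), {
    # non-overlapping zone centers: jittered around equally spaced anchors
    anchors <- grid[1] + span * (seq_len(config$n_informative_zones) - 0.5) /
      config$n_informative_zones
    centers <- anchors + stats::runif(length(anchors),
                                      -0.15 * span / config$n_informative_zones,
                                      0.15 * span / config$n_informative_zones)
    bg_centers <- grid[1] + span * stats::runif(gen_const$n_background_peaks, 0.02, 0.98)
    bg_sd <- span * stats::runif(gen_const$n_background_peaks, 0.01, 0.04)
    bg_amp <- stats::runif(gen_const$n_background_peaks, 0.5, 1.5) * 0.05
    my_w <- stats::rnorm(gen_const$n_background_peaks, 0, gen_const$my_mix)
    list(centers = centers, bg_centers = bg_centers, bg_sd = bg_sd,
         bg_amp = bg_amp, my_w = my_w)
  })
}

#' Generate a synthetic multi-herd dataset with known ground truth
#'
#' Milk yield follows a parity-scaled Wood lactation curve
#' `a * DIM^b * exp(-c * DIM)` plus noise. Bodyweight is a parity-class
#' baseline plus herd and cow effects, an early-lactation dip
#' `-L * (DIM / tau) * exp(1 - DIM / tau)` (nadir of depth L near
#' `DIM = tau`), a slow within-lactation gain, and residual noise.
#' Each spectrum is a sum of smooth background peaks (whose amplitudes vary
#' with milk yield and record-level noise), informative-zone peaks whose
#' amplitudes are linear in the standardized non-herd systematic bodyweight
#' signal, a per-herd smooth spectral shift, smooth autocorrelated noise,
#' and white noise. The
#' signal-to-noise ratio scales the informative amplitudes against the
#' fixed spectral noise floor.
#'
#' @param config a [generator_config()].
#' @param truth optionally, the `"synthetic_truth"` of a previous call with
#'   the same grid, so extra herds (e.g. an external validation herd) share
#'   the same spectral ground truth.
#' @param herd_offset integer added to herd indices (ids and random
#'   streams), used to generate herds disjoint from an earlier call.
#' @return `list(dataset, truth)`: a `"raw"` [mir_dataset()] and a
#'   `"synthetic_truth"` with fields `informative_indices`, `zone_centers`,
#'   `zone_effects` (kg per unit peak amplitude), `herd_effects`,
#'   `cow_effects`, `outlier_ids`, and `noise_floor_rmse` (kg; the
#'   irreducible error `sqrt(resid_sd^2 + herd_sd^2)` when predicting
#'   unseen herds).
#' @export
generate_dataset <- function(config, truth = NULL, herd_offset = 0L) {
  grid <- config$grid
  p <- length(grid)
  tr <- if (is.null(truth)) draw_truth(config) else truth$layout
  zone_sd <- config$zone_width / 4
  zone_shapes <- vapply(tr$centers, function(ct) gauss_peak(grid, ct, zone_sd),
                        numeric(p))
  bg_shapes <- vapply(seq_along(tr$bg_centers), function(b)
    gauss_peak(grid, tr$bg_centers[b], tr$bg_sd[b]), numeric(p))
  sigma_tot <- sqrt(gen_const$sigma_smooth^2 + gen_const$sigma_white^2)
  amp_per_m <- config$signal_to_noise * sigma_tot  # peak height per 1 sd of signal

  herds <- lapply(seq_len(config$n_herds), function(h) {
    hid <- h + herd_offset
    with_stream(stream_seed(config$seed, hid), {
      herd_eff <- stats::rnorm(1, 0, config$herd_sd)
      herd_shift <- smooth_noise(p, gen_const$smooth_kernel_sd) * sigma_tot
      n_cows <- sample_range(config$cows_per_herd[1], config$cows_per_herd[2])
      cows <- lapply(seq_len(n_cows), function(cw) {
        cow_eff <- stats::rnorm(1, 0, config$cow_sd)
        parity <- sample(1:6, 1, prob = config$parity_probs)
        cls <- as.character(parity_class(parity))
        n_rec <- sample_range(config$records_per_cow[1], config$records_per_cow[2])
        dim <- round(stats::runif(n_rec, config$dim_range[1], config$dim_range[2]))
        my <- pmax(2, gen_const$wood_a * dim^gen_const$wood_b *
                     exp(-gen_const$wood_c * dim) *
                     gen_const$my_parity_scale[min(parity, 4)] +
                     stats::rnorm(n_rec, 0, gen_const$my_noise_sd))
        sys <- gen_const$bw_base[cls] + cow_eff -
          gen_const$dip_kg * (dim / gen_const$dip_tau) *
            exp(1 - dim / gen_const$dip_tau) +
          gen_const$gain_per_day * dim
        bw <- sys + herd_eff + stats::rnorm(n_rec, 0, config$resid_sd)
        m <- (sys - gen_const$ref_mean) / gen_const$ref_sd
        my_std <- (my - 25) / 8
        amps <- amp_per_m *
          (outer(m, rep(1, ncol(zone_shapes))) +
             matrix(stats::rnorm(n_rec * ncol(zone_shapes), 0, gen_const$zone_noise),
                    n_rec))
        bg_amps <- outer(rep(1, n_rec), tr$bg_amp) *
          (1 + outer(my_std, tr$my_w) +
             matrix(stats::rnorm(n_rec * ncol(bg_shapes), 0,
                                 gen_const$background_amp_sd), n_rec))
        noise <- t(vapply(seq_len(n_rec), function(i)
          smooth_noise(p, gen_const$smooth_kernel_sd) * gen_const$sigma_smooth +
            stats::rnorm(p, 0, gen_const$sigma_white), numeric(p)))
        spectra <- amps %*% t(zone_shapes) + bg_amps %*% t(bg_shapes) +
          outer(rep(1, n_rec), herd_shift) + noise
        list(info = data.frame(
               herd_id = sprintf("h%02d", hid),
               cow_id = sprintf("h%02d_c%03d", hid, cw),
               parity = parity, dim = dim, my = my, bw = bw,
               stringsAsFactors = FALSE),
             spectra = spectra, cow_eff = cow_eff)
      })
      list(info = do.call(rbind, lapply(cows, `[[`, "info")),
           spectra = do.call(rbind, lapply(cows, `[[`, "spectra")),
           herd_eff = herd_eff,
           cow_effs = vapply(cows, `[[`, numeric(1), "cow_eff"))
    })
  })

  info <- do.call(rbind, lapply(herds, `[[`, "info"))
  info <- cbind(record_id = sprintf("r%05d", seq_len(nrow(info))), info,
                stringsAsFactors = FALSE)
  spectra <- do.call(rbind, lapply(herds, `[[`, "spectra"))
  dataset <- mir_dataset(info, spectra, grid, stage = "raw")

  informative <- sort(unique(unlist(lapply(tr$centers, function(ct)
    which(abs(as.numeric(grid) - ct) <= config$zone_width / 2)))))
  herd_effects <- vapply(herds, `[[`, numeric(1), "herd_eff")
  names(herd_effects) <- sprintf("h%02d", seq_len(config$n_herds) + herd_offset)
  new_truth <- structure(list(
    layout = tr,
    informative_indices = informative,
    informative_features = wn_names(grid)[informative],
    zone_centers = tr$centers,
    zone_effects = if (amp_per_m > 0) rep(gen_const$ref_sd / amp_per_m,
                                          length(tr$centers)) else
                     rep(Inf, length(tr$centers)),
    herd_effects = herd_effects,
    cow_effects = unlist(lapply(herds, `[[`, "cow_effs")),
    outlier_ids = data.frame(record_id = character(), kind = character(),
                             stringsAsFactors = FALSE),
    noise_floor_rmse = sqrt(config$resid_sd^2 + config$herd_sd^2),
    config = config), class = "synthetic_truth")
  if (!is.null(truth)) {
    new_truth$outlier_ids <- truth$outlier_ids
    new_truth$herd_effects <- c(truth$herd_effects, herd_effects)
  }
  list(dataset = dataset, truth = new_truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d informative point(s) in %d zone(s), noise floor %.1f kg\n",
              length(x$informative_indices), length(x$zone_centers),
              x$noise_floor_rmse))
  invisible(x)
}

#' Inject spectral and bodyweight outliers
#'
#' Perturbs randomly chosen records: spectral outliers get an additive
#' aberrant Gaussian peak of height `magnitude` times the dataset's mean
#' per-wavenumber SD at a random position; bodyweight outliers are pushed out of their
#' parity-class plausibility interval. Injected ids are appended to
#' `truth$outlier_ids`.
#'
#' @param dataset a `mir_dataset`.
#' @param truth the matching `"synthetic_truth"`.
#' @param n_spectral,n_bw numbers of records to perturb (disjoint sets).
#' @param magnitude positive perturbation multiplier.
#' @param intervals parity-wise bodyweight intervals used to push bw values
#'   outside their class range.
#' @return `list(dataset, truth)` with perturbed records.
#' @export
inject_outliers <- function(dataset, truth, n_spectral = 0, n_bw = 0,
                            magnitude = 10, intervals = default_bw_intervals()) {
  if (magnitude <= 0) stop("magnitude must be > 0")
  n <- n_records(dataset)
  if (n_spectral + n_bw > n) stop("more outliers requested than records")
  if (n_spectral + n_bw == 0) return(list(dataset = dataset, truth = truth))
  grid <- as.numeric(dataset$grid)
  col_sd <- apply(dataset$spectra, 2, stats::sd)
  with_stream(stream_seed(truth$config$seed, 999983L), {
    ids <- sample(n, n_spectral + n_bw)
    sp_ids <- ids[seq_len(n_spectral)]
    bw_ids <- ids[n_spectral + seq_len(n_bw)]
    for (i in sp_ids) {
      center <- stats::runif(1, grid[1], grid[length(grid)])
      width <- (grid[length(grid)] - grid[1]) * 0.08
      # scaled to the local spectral variability so the aberration is
      # atypical wherever it lands
      sp_scale <- col_sd[which.min(abs(grid - center))]
      dataset$spectra[i, ] <- dataset$spectra[i, ] +
        magnitude * sp_scale * gauss_peak(grid, center, width)
    }
    for (i in bw_ids) {
      cls <- as.character(dataset$info$parity_class[i])
      bounds <- intervals[[cls]]
      up <- stats::runif(1) < 0.5
      dataset$info$bw[i] <- if (up)
        bounds[2] + magnitude * max(truth$config$resid_sd, 1) else
        bounds[1] - magnitude * max(truth$config$resid_sd, 1)
    }
    kind <- rep(c("spectral", "bw"), c(n_spectral, n_bw))
    truth$outlier_ids <- rbind(truth$outlier_ids,
                               data.frame(record_id = dataset$info$record_id[ids],
                                          kind = kind, stringsAsFactors = FALSE))
  })
  list(dataset = dataset, truth = truth)
}

#' Serialize the generator ground truth to JSON
#'
#' @param truth a `"synthetic_truth"`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  obj <- unclass(truth)
  obj$config$grid <- list(start = truth$config$grid[1],
                          end = truth$config$grid[length(truth$config$grid)],
                          n_points = length(truth$config$grid))
  obj$config <- unclass(obj$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
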