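#' Phantom configuration
#'
#' Describes one synthetic CT phantom: a lumpy ellipsoidal tumor embedded in
#' a soft-tissue background, optionally abutted by a bone-like slab (high
#' intensity) and/or an air-like cavity (low intensity) so that the
#' peritumoral region shows the large intensity fluctuations that make
#' delineation-uncertainty experiments non-trivial.
#'
#' @param shape Grid size (default 64^3 voxels).
#' @param spacing_mm Voxel spacing (default 1 mm isotropic).
#' @param center_vox Tumor center in voxel coordinates (default grid center).
#' @param radii_mm Ellipsoid semi-axes in mm (default `c(10, 9, 8)`).
#' @param lumpiness Relative amplitude of the smooth radial boundary
#'   modulation (0 = exact ellipsoid; default 0.15).
#' @param lump_sigma_mm Smoothing SD of the modulation field (default 3).
#' @param tumor_hu,soft_hu,bone_hu,air_hu Tissue intensities (defaults 60,
#'   40, 700, -950 HU; air < soft tissue < bone by construction).
#' @param texture_sd Tumor heterogeneity: SD of the smoothed intensity
#'   texture inside the tumor (default 30 HU).
#' @param adjacency Character subset of `c("bone", "air")`: which structures
#'   touch the tumor boundary (default both).
#' @param noise_sd Global acquisition-noise SD (default 10 HU).
#' @param margin_vox Required clearance between tumor support and the volume
#'   boundary (default 8; must cover the fuzzification truncation radius).
#' @param seed Integer seed; the phantom is fully deterministic given it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 64), spacing_mm = c(1, 1, 1),
                           center_vox = NULL, radii_mm = c(10, 9, 8),
                           lumpiness = 0.15, lump_sigma_mm = 3,
                           tumor_hu = 60, soft_hu = 40, bone_hu = 700,
                           air_hu = -950, texture_sd = 30,
                           adjacency = c("bone", "air"), noise_sd = 10,
                           margin_vox = 8, seed = 0L) {
  if (!(air_hu < soft_hu && soft_hu < bone_hu)) {
    abort("tissue intensities must satisfy air < soft tissue < bone.")
  }
  if (is.null(center_vox)) center_vox <- (shape + 1) / 2
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 center_vox = center_vox, radii_mm = radii_mm,
                 lumpiness = lumpiness, lump_sigma_mm = lump_sigma_mm,
                 tumor_hu = tumor_hu, soft_hu = soft_hu, bone_hu = bone_hu,
                 air_hu = air_hu, texture_sd = texture_sd,
                 adjacency = adjacency, noise_sd = noise_sd,
                 margin_vox = margin_vox, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a synthetic CT phantom
#'
#' Rasterizes the lumpy ellipsoid of a [phantom_config()] to a binary mask
#' and builds the matching CT image: soft-tissue background, optional bone
#' slab and air cavity touching the tumor boundary, heterogeneous tumor
#' texture (smoothed noise of SD `texture_sd`) and global Gaussian noise.
#'
#' @param cfg A [phantom_config()].
#' @return List `image` ([image_volume()]), `mask` (binary
#'   [membership_mask()]), `cfg`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_config(shape = c(32, 32, 32), radii_mm = c(6, 6, 6),
#'                                   lumpiness = 0, seed = 1))
#' sum(ph$mask$data)  # close to 4/3*pi*6^3
make_phantom <- function(cfg) {
  d <- cfg$shape; sp <- cfg$spacing_mm
  rad_vox <- cfg$radii_mm / sp
  if (any(cfg$center_vox - rad_vox * (1 + cfg$lumpiness) < cfg$margin_vox + 1) ||
      any(cfg$center_vox + rad_vox * (1 + cfg$lumpiness) > d - cfg$margin_vox)) {
    abort("tumor (plus margin) does not fit inside the volume.")
  }
  with_seed(cfg$seed, {
    ii <- array(seq_len(d[1]), d)
    jj <- array(rep(seq_len(d[2]), each = d[1]), d)
    kk <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
    rho <- sqrt(((ii - cfg$center_vox[1]) / rad_vox[1])^2 +
                ((jj - cfg$center_vox[2]) / rad_vox[2])^2 +
                ((kk - cfg$center_vox[3]) / rad_vox[3])^2)
    if (cfg$lumpiness > 0) {
      lump <- gaussian_smooth3(array(rnorm(prod(d)), d), cfg$lump_sigma_mm / sp)
      lump <- lump / sd(lump)
      mask <- (rho <= 1 + cfg$lumpiness * lump) * 1
    } else {
      mask <- (rho <= 1) * 1
    }

    img <- array(cfg$soft_hu, d)
    inside <- mask > 0
    # adjacent structures touch the tumor's bounding box along the x axis
    xs <- range(which(apply(inside, 1, any)))
    if ("bone" %in% cfg$adjacency) {
      i0 <- xs[2] + 1
      img[i0:min(i0 + 4, d[1]), , ] <- cfg$bone_hu
    }
    if ("air" %in% cfg$adjacency) {
      i1 <- xs[1] - 1
      img[max(i1 - 4, 1):i1, , ] <- cfg$air_hu
    }
    tex <- gaussian_smooth3(array(rnorm(prod(d)), d), 2 / sp)
    tex <- tex / sd(tex)
    img[inside] <- cfg$tumor_hu + cfg$texture_sd * tex[inside]
    if (cfg$noise_sd > 0) img <- img + array(rnorm(prod(d), 0, cfg$noise_sd), d)

    list(image = image_volume(img, sp),
         mask = membership_mask(mask, sp, kind = "binary"),
         cfg = cfg)
  })
}

#' Cohort configuration
#'
#' Describes a synthetic patient cohort: tumor volumes drawn uniformly from
#' `volume_range_vox` (spanning several 5k-voxel strata by default), a
#' per-patient heterogeneity parameter (tumor texture SD), and survival
#' times from an exponential hazard whose log is a linear combination of
#' standardized generator parameters, with independent exponential
#' censoring calibrated to the requested censoring fraction.
#'
#' @param n_patients Number of patients (>= 10).
#' @param shape,spacing_mm Phantom grid (default 48^3, 1 mm).
#' @param volume_range_vox Tumor volume range in voxels (default
#'   `c(1000, 9000)`).
#' @param texture_sd_range Heterogeneity range in HU (default `c(10, 50)`).
#' @param tumor_hu_range Per-patient mean tumor intensity range in HU
#'   (default `c(40, 80)`), emulating inter-patient density differences.
#' @param lumpiness As in [phantom_config()] (default 0.1).
#' @param adjacency Peritumoral structures, as in [phantom_config()].
#' @param hazard_coef Named log-hazard coefficients on standardized
#'   generator parameters; names among `"heterogeneity"`, `"volume"`.
#'   Default `c(heterogeneity = log(2))` (hazard ratio 2 per SD).
#' @param baseline_rate Baseline event rate per year (default 0.25).
#' @param censoring_rate Target censoring fraction in \[0, 1) (default 0.3).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 60, shape = c(48, 48, 48),
                          spacing_mm = c(1, 1, 1),
                          volume_range_vox = c(1000, 9000),
                          texture_sd_range = c(10, 50),
                          tumor_hu_range = c(40, 80), lumpiness = 0.1,
                          adjacency = c("bone", "air"),
                          hazard_coef = c(heterogeneity = log(2)),
                          baseline_rate = 0.25, censoring_rate = 0.3,
                          seed = 0L) {
  if (n_patients < 10) abort("`n_patients` must be >= 10.")
  if (censoring_rate < 0 || censoring_rate >= 1) abort("`censoring_rate` must be in [0, 1).")
  if (!all(names(hazard_coef) %in% c("heterogeneity", "volume"))) {
    abort("hazard coefficients must be named 'heterogeneity' and/or 'volume'.")
  }
  structure(list(n_patients = n_patients, shape = shape,
                 spacing_mm = spacing_mm, volume_range_vox = volume_range_vox,
                 texture_sd_range = texture_sd_range,
                 tumor_hu_range = tumor_hu_range, lumpiness = lumpiness,
                 adjacency = adjacency, hazard_coef = hazard_coef,
                 baseline_rate = baseline_rate, censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort with linked survival
#'
#' Draws per-patient generator parameters, optionally rasterizes the
#' phantoms, and simulates survival: `log h_i = sum(coef * z_i)` with
#' standardized parameters `z`, event times exponential with rate
#' `baseline_rate * exp(log h_i)`, and independent exponential censoring
#' whose rate is solved numerically so the expected censoring fraction
#' matches the configuration. The ground-truth table (all parameters and
#' the true linear predictor) supports recovery tests.
#'
#' @param cfg A [cohort_config()].
#' @param rasterize Build the image/mask pairs (default `TRUE`); set
#'   `FALSE` for modeling-scale cohorts where only parameters and survival
#'   are needed.
#' @return List `patients` (named list of `list(image, mask)`, or `NULL`),
#'   `survival` (tibble `patient_id`, `time`, `event`), `truth` (tibble of
#'   generator parameters and `true_lp`).
#' @export
make_cohort <- function(cfg, rasterize = TRUE) {
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  pars <- with_seed(cfg$seed, {
    tibble(patient_id = ids,
           volume_vox = runif(n, cfg$volume_range_vox[1], cfg$volume_range_vox[2]),
           heterogeneity = runif(n, cfg$texture_sd_range[1], cfg$texture_sd_range[2]),
           tumor_hu = runif(n, cfg$tumor_hu_range[1], cfg$tumor_hu_range[2]))
  })
  z <- list(heterogeneity = as.numeric(scale(pars$heterogeneity)),
            volume = as.numeric(scale(pars$volume_vox)))
  lp <- rep(0, n)
  for (nm in names(cfg$hazard_coef)) lp <- lp + cfg$hazard_coef[[nm]] * z[[nm]]
  rate <- cfg$baseline_rate * exp(lp)

  surv <- with_seed(cfg$seed + 1L, {
    t_event <- rexp(n, rate)
    if (cfg$censoring_rate > 0) {
      # censoring fraction for exp censoring at rate mu: mean(mu/(mu+rate))
      mu <- uniroot(function(m) mean(m / (m + rate)) - cfg$censoring_rate,
                    interval = c(1e-8, 1e4 * max(rate)))$root
      t_cens <- rexp(n, mu)
    } else t_cens <- rep(Inf, n)
    tibble(patient_id = ids,
           time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens),
           censor_time = t_cens)
  })

  patients <- NULL
  if (rasterize) {
    patients <- lapply(seq_len(n), function(i) {
      r_vox <- (3 * pars$volume_vox[i] / (4 * pi))^(1 / 3)
      ph <- make_phantom(phantom_config(
        shape = cfg$shape, spacing_mm = cfg$spacing_mm,
        radii_mm = rep(r_vox, 3) * cfg$spacing_mm,
        lumpiness = cfg$lumpiness, adjacency = cfg$adjacency,
        texture_sd = pars$heterogeneity[i], tumor_hu = pars$tumor_hu[i],
        seed = cfg$seed + 1000L + i))
      list(image = ph$image, mask = ph$mask)
    })
    names(patients) <- ids
  }
  truth <- dplyr::mutate(pars, true_lp = lp)
  list(patients = patients,
       survival = surv[, c("patient_id", "time", "event")],
       truth = dplyr::left_join(truth,
                                dplyr::select(surv, "patient_id", "time",
                                              "event", "censor_time"),
                                by = "patient_id"))
}
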