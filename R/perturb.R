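#' One realization of the delineation-uncertainty perturbation chain
#'
#' @param translation_mm Length-3 translation in mm.
#' @param rotation_deg Rotation about the z-axis through the mask centroid,
#'   in degrees.
#' @param noise_sigma_HU SD of the additive Gaussian image noise (HU).
#' @param contour_magnitude_mm Per-component SD of the smooth random
#'   displacement field used for contour randomization.
#' @param contour_seed,noise_seed Integer seeds for the two stochastic
#'   operators.
#' @param chain_seed Seed the spec was sampled under (bookkeeping).
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(translation_mm = c(0, 0, 0), rotation_deg = 0,
                              noise_sigma_HU = 0, contour_magnitude_mm = 0,
                              contour_seed = 0L, noise_seed = 0L,
                              chain_seed = NA_integer_) {
  if (noise_sigma_HU < 0) abort("`noise_sigma_HU` must be >= 0.")
  if (contour_magnitude_mm < 0) abort("`contour_magnitude_mm` must be >= 0.")
  structure(list(translation_mm = as.numeric(translation_mm),
                 rotation_deg = as.numeric(rotation_deg),
                 noise_sigma_HU = as.numeric(noise_sigma_HU),
                 contour_magnitude_mm = as.numeric(contour_magnitude_mm),
                 contour_seed = as.integer(contour_seed),
                 noise_seed = as.integer(noise_seed),
                 chain_seed = chain_seed),
            class = "perturbation_spec")
}

#' Default perturbation parameter bounds
#'
#' Sub-voxel translations, small rotations, CT-scale noise and millimetre-
#' scale contour displacement, all configurable.
#'
#' @return Named list of `c(low, high)` bounds.
#' @export
perturbation_bounds <- function() {
  list(translation_mm = c(-1, 1),
       rotation_deg = c(-10, 10),
       noise_sigma_HU = c(0, 20),
       contour_magnitude_mm = c(0.5, 2))
}

#' Sample random perturbation specs
#'
#' Draws `n` specs uniformly within the bounds from a seeded generator;
#' deterministic given the seed.
#'
#' @param n Number of specs (the reliability protocol uses 20).
#' @param bounds Named list as from [perturbation_bounds()].
#' @param seed Integer seed.
#' @return List of `perturbation_spec`s.
#' @export
sample_perturbations <- function(n = 20, bounds = perturbation_bounds(),
                                 seed = 0L) {
  stopifnot(n >= 1)
  for (b in bounds) if (b[1] > b[2]) abort("invalid bounds: low > high.")
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      perturbation_spec(
        translation_mm = runif(3, bounds$translation_mm[1], bounds$translation_mm[2]),
        rotation_deg = runif(1, bounds$rotation_deg[1], bounds$rotation_deg[2]),
        noise_sigma_HU = runif(1, bounds$noise_sigma_HU[1], bounds$noise_sigma_HU[2]),
        contour_magnitude_mm = runif(1, bounds$contour_magnitude_mm[1],
                                     bounds$contour_magnitude_mm[2]),
        contour_seed = sample.int(.Machine$integer.max, 1),
        noise_seed = sample.int(.Machine$integer.max, 1),
        chain_seed = as.integer(seed))
    })
  })
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Apply a rigid transform to an image/mask pair
#'
#' Rotation about the z-axis through the mask centroid (world coordinates),
#' then translation. The image is resampled with trilinear interpolation;
#' the mask uses the same interpolation and is re-binarized at 0.5. The
#' identity transform returns the inputs bit-exactly, and integer-voxel
#' translations are exact array shifts.
#'
#' @param image An `image_volume`.
#' @param mask A binary `membership_mask` on the same grid.
#' @param translation_mm Length-3 translation (mm).
#' @param rotation_deg Rotation angle (degrees) about z.
#' @return List `image`, `mask`.
#' @export
apply_rigid <- function(image, mask, translation_mm = c(0, 0, 0),
                        rotation_deg = 0) {
  check_same_grid(image, mask)
  t <- as.numeric(translation_mm)
  th <- rotation_deg * pi / 180
  if (all(t == 0) && th == 0) return(list(image = image, mask = mask))
  d <- dim(image$data)
  sp <- image$spacing; or <- image$origin
  idx <- which(mask$data > 0)
  if (length(idx) == 0) abort("empty mask.")
  ijk <- arrayInd(idx, d)
  cen <- or + (colMeans(ijk) - 1) * sp  # centroid, world mm

  # forward FOV check: transformed mask voxel centers must stay on the grid
  pw <- sweep((ijk - 1) %*% diag(sp), 2, or, "+")
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  q <- sweep(sweep(pw, 2, cen) %*% t(R), 2, cen + t, "+")
  fi <- sweep(sweep(q, 2, or), 2, sp, "/") + 1
  lost <- sum(fi[, 1] < 1 | fi[, 1] > d[1] | fi[, 2] < 1 | fi[, 2] > d[2] |
              fi[, 3] < 1 | fi[, 3] > d[3])
  if (lost > 0) {
    abort(sprintf("rigid transform pushes %d mask voxels outside the field of view.",
                  lost))
  }

  # backward map: output voxel p reads input at Rinv(p - t - cen) + cen
  wc <- world_coords(d, sp, or)
  px0 <- wc$x - t[1] - cen[1]; py0 <- wc$y - t[2] - cen[2]; pz0 <- wc$z - t[3] - cen[3]
  ct <- cos(-th); st <- sin(-th)
  sx <- ct * px0 - st * py0 + cen[1]
  sy <- st * px0 + ct * py0 + cen[2]
  sz <- pz0 + cen[3]
  img2 <- resample_trilinear(image$data, sp, or, sx, sy, sz, fill = min(image$data))
  msk2 <- resample_trilinear(mask$data, sp, or, sx, sy, sz, fill = 0)
  list(image = image_volume(img2, sp, or),
       mask = membership_mask((msk2 >= 0.5) * 1, sp, or, kind = "binary"))
}

#' Add Gaussian image noise
#'
#' Zero-mean additive Gaussian noise with the given SD; `sigma_HU = 0` is
#' the exact identity. Seeded and reproducible.
#'
#' @param image An `image_volume`.
#' @param sigma_HU Noise SD in HU (>= 0).
#' @param seed Integer seed.
#' @return An `image_volume`.
#' @export
add_noise <- function(image, sigma_HU, seed = 0L) {
  if (sigma_HU < 0) abort("`sigma_HU` must be >= 0.")
  if (sigma_HU == 0) return(image)
  d <- dim(image$data)
  noise <- with_seed(seed, rnorm(prod(d), 0, sigma_HU))
  image_volume(image$data + array(noise, d), image$spacing, image$origin)
}

#' Randomize a mask contour with a smooth displacement field
#'
#' Draws three independent white-noise fields, smooths them with a Gaussian
#' of 4 mm SD, rescales each component to the requested per-component SD
#' (in mm), and warps the mask backward through the field with linear
#' interpolation, re-binarizing at 0.5. Magnitude 0 is the exact identity.
#'
#' @param mask A binary `membership_mask`.
#' @param magnitude_mm Per-component displacement SD in mm.
#' @param seed Integer seed.
#' @param field_sigma_mm Smoothing SD of the displacement field (default 4).
#' @return A binary `membership_mask`.
#' @export
randomize_contour <- function(mask, magnitude_mm, seed = 0L, field_sigma_mm = 4) {
  if (sum(mask$data) == 0) abort("empty mask.")
  if (magnitude_mm < 0) abort("`magnitude_mm` must be >= 0.")
  if (magnitude_mm == 0) return(mask)
  d <- dim(mask$data)
  sp <- mask$spacing; or <- mask$origin
  sig_vox <- field_sigma_mm / sp
  disp <- with_seed(seed, lapply(1:3, function(a) array(rnorm(prod(d)), d)))
  disp <- lapply(disp, function(f) {
    f <- gaussian_smooth3(f, sig_vox)
    f * (magnitude_mm / sd(f))
  })
  wc <- world_coords(d, sp, or)
  m2 <- resample_trilinear(mask$data, sp, or,
                           wc$x - disp[[1]], wc$y - disp[[2]], wc$z - disp[[3]],
                           fill = 0)
  m2 <- (m2 >= 0.5) * 1
  if (sum(m2) == 0) abort("contour randomization emptied the mask.")
  membership_mask(m2, sp, or, kind = "binary")
}

#' Apply the full perturbation chain
#'
#' Fixed order: contour randomization (mask only) -> rigid rotation +
#' translation (image and mask together) -> additive noise (image only).
#' Contour randomization is defined in the native frame and noise is never
#' resampled. The perturbed mask stays binary; fuzzification of perturbed
#' masks reuses [fuzzify()] downstream.
#'
#' @param image An `image_volume`.
#' @param mask A binary `membership_mask` on the same grid.
#' @param spec A [perturbation_spec()].
#' @return List `image`, `mask`, `spec` (a perturbed pair).
#' @export
perturb_chain <- function(image, mask, spec) {
  check_same_grid(image, mask)
  m <- randomize_contour(mask, spec$contour_magnitude_mm, spec$contour_seed)
  rp <- apply_rigid(image, m, spec$translation_mm, spec$rotation_deg)
  img <- add_noise(rp$image, spec$noise_sigma_HU, spec$noise_seed)
  list(image = img, mask = rp$mask, spec = spec)
}
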