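#' Gaussian fuzzification of a binary mask
#'
#' Turns a binary tumor delineation into a fuzzy membership mask by 3D
#' Gaussian filtering. The physical smoothing scale is tied to the in-plane
#' pixel size `u` of the grid: `sigma_mm = multiplier * u` isotropically,
#' then converted per axis to voxel units (`sigma_mm / spacing`), so
#' anisotropic slice spacing does not inflate the smoothing in mm. The
#' kernel is normalized and truncated at 4 sigma; with the support at least a
#' truncation radius inside the volume, total membership mass equals the
#' binary voxel count to high precision.
#'
#' @param bin_mask A binary `membership_mask`.
#' @param multiplier Positive fuzziness multiplier (the sweep values used for
#'   sensitivity analysis are 0.5, 1 and 1.5; default 1).
#' @return A `membership_mask` of kind `"fuzzy"` with `sigma_mm` recorded.
#' @export
#' @examples
#' m <- membership_mask(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3)))
#' f <- fuzzify(m, multiplier = 1)
#' sum(f$data) <= 1  # mass leaks past the 3^3 box for a 1-voxel tumor
fuzzify <- function(bin_mask, multiplier = 1) {
  stopifnot(inherits(bin_mask, "membership_mask"))
  if (bin_mask$kind != "binary") abort("fuzzify() expects a binary mask.")
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0) {
    abort("`multiplier` must be a single positive number.")
  }
  if (sum(bin_mask$data) == 0) abort("cannot fuzzify an empty mask.")
  sp <- bin_mask$spacing
  if (abs(sp[1] - sp[2]) > 0.05 * max(sp[1], sp[2])) {
    abort("in-plane spacing is not approximately isotropic (x vs y differ > 5%).")
  }
  u <- sp[1]  # patient-specific in-plane pixel size
  sigma_mm <- rep(multiplier * u, 3)
  sigma_vox <- sigma_mm / sp
  sm <- gaussian_smooth3(bin_mask$data, sigma_vox)
  sm[sm < 0] <- 0
  sm[sm > 1] <- 1
  membership_mask(sm, spacing = sp, origin = bin_mask$origin,
                  kind = "fuzzy", sigma_mm = sigma_mm)
}

EPS_CORE <- 1e-6
EPS_SUPP <- 1e-6

#' Alpha-cut core of a fuzzy mask
#'
#' The shrunk mask: voxels whose membership is (numerically) 1, i.e.
#' `mu >= 1 - 1e-6`. For small tumors (fewer than ~100 voxels) all fuzzy
#' memberships can fall below 1 and the core is empty; this is a valid
#' outcome and is flagged with a structured warning of class
#' `fuzzrad_empty_core` so cohort logic can drop the patient from
#' core-mask analyses.
#'
#' @param fuzzy A `membership_mask` of kind `"fuzzy"`.
#' @return A binary `membership_mask` of kind `"core"`.
#' @export
alpha_cut_core <- function(fuzzy) {
  stopifnot(inherits(fuzzy, "membership_mask"))
  if (fuzzy$kind != "fuzzy") abort("alpha_cut_core() expects a fuzzy mask.")
  core <- (fuzzy$data >= 1 - EPS_CORE) * 1
  if (sum(core) == 0) {
    warn("empty core: all fuzzy memberships fall below 1 (small tumor).",
         class = "fuzzrad_empty_core")
  }
  membership_mask(array(core, dim(fuzzy$data)), spacing = fuzzy$spacing,
                  origin = fuzzy$origin, kind = "core", sigma_mm = fuzzy$sigma_mm)
}

#' Support of a fuzzy mask
#'
#' The extended mask: all voxels with non-zero membership
#' (`mu > 1e-6`). Always a superset of the binary mask the fuzzy mask was
#' generated from.
#'
#' @param fuzzy A `membership_mask` of kind `"fuzzy"`.
#' @return A binary `membership_mask` of kind `"support"`.
#' @export
support_mask <- function(fuzzy) {
  stopifnot(inherits(fuzzy, "membership_mask"))
  if (fuzzy$kind != "fuzzy") abort("support_mask() expects a fuzzy mask.")
  supp <- (fuzzy$data > EPS_SUPP) * 1
  membership_mask(array(supp, dim(fuzzy$data)), spacing = fuzzy$spacing,
                  origin = fuzzy$origin, kind = "support", sigma_mm = fuzzy$sigma_mm)
}

#' Generate the four comparative masks
#'
#' Convenience wrapper returning the binary input together with its fuzzy,
#' core (alpha-cut) and support (extended) companions.
#'
#' @inheritParams fuzzify
#' @return Named list `bin`, `fuzzy`, `core`, `support`.
#' @export
comparative_masks <- function(bin_mask, multiplier = 1) {
  fz <- fuzzify(bin_mask, multiplier)
  core <- withCallingHandlers(
    alpha_cut_core(fz),
    fuzzrad_empty_core = function(w) invokeRestart("muffleWarning")
  )
  list(bin = bin_mask, fuzzy = fz, core = core, support = support_mask(fz))
}
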