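#' Read a NIfTI volume
#'
#' Loads a 3D NIfTI image into an [image_volume()]. Spacing and origin are
#' taken from the header affine; only axis-aligned affines are accepted
#' (off-diagonal rotation terms are rejected rather than silently resampled).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An `image_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- array(img[, , , 1], d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3) {
    abort(sprintf("%s: expected a 3D image, got %d dimensions.", path, length(d)))
  }
  aff <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(aff, "try-error") || is.null(aff)) {
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- c(0, 0, 0)
  } else {
    rot <- aff[1:3, 1:3]
    sc <- sqrt(colSums(rot^2))
    off <- rot - diag(diag(rot))
    if (any(abs(off) > 1e-4 * max(sc))) {
      abort(sprintf("%s: non-axis-aligned affine; oblique grids are not supported.",
                    path))
    }
    spacing <- abs(diag(rot))
    origin <- aff[1:3, 4]
  }
  bad <- sum(!is.finite(img))
  if (bad > 0) {
    abort(sprintf("%s: %d NaN/Inf voxels; refusing to load.", path, bad))
  }
  image_volume(array(as.numeric(img), d), spacing = spacing, origin = origin)
}

#' Write a volume or mask to NIfTI
#'
#' Binary masks are written as unsigned 8-bit integers, fuzzy masks as 32-bit
#' float, images as 32-bit float. Geometry is stored in both the q-form and
#' s-form as an axis-aligned affine.
#'
#' @param x An `image_volume` or `membership_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  datatype <- "float"
  if (inherits(x, "membership_mask") && x$kind != "fuzzy") datatype <- "uint8"
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a mask from NIfTI
#'
#' @param path NIfTI path.
#' @param kind Mask kind, see [membership_mask()].
#' @param sigma_mm Optional smoothing SDs to record for fuzzy masks.
#' @return A `membership_mask`.
#' @export
read_mask <- function(path, kind = "binary", sigma_mm = NULL) {
  v <- read_volume(path)
  membership_mask(v$data, spacing = v$spacing, origin = v$origin,
                  kind = kind, sigma_mm = sigma_mm)
}

#' Write a feature table to CSV
#'
#' A feature table is a tibble with a `patient_id` column and one numeric
#' column per feature, named in `family_FeatureName3D` style
#' (e.g. `ngldm_DependenceCountPercentage3D`).
#'
#' @param table Feature tibble with `patient_id` plus feature columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  if (!"patient_id" %in% names(table)) abort("feature table needs a `patient_id` column.")
  if (anyDuplicated(table$patient_id)) {
    abort(sprintf("duplicate patient IDs: %s",
                  paste(unique(table$patient_id[duplicated(table$patient_id)]),
                        collapse = ", ")))
  }
  if (anyDuplicated(names(table))) {
    abort(sprintf("duplicate feature names: %s",
                  paste(unique(names(table)[duplicated(names(table))]),
                        collapse = ", ")))
  }
  readr::write_csv(table, path)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path as written by [write_feature_table()].
#' @return A tibble with `patient_id` (character) plus numeric feature columns.
#' @export
read_feature_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(patient_id = readr::col_character(),
                                                .default = readr::col_double()))
  as_tibble(tb)
}

#' Read a survival table from CSV
#'
#' Expects columns `patient_id`, `time` (years, > 0) and `event`
#' (1 = death, 0 = censored).
#'
#' @param path CSV path.
#' @return A tibble with validated columns.
#' @export
read_survival_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  validate_survival(tb)
}

validate_survival <- function(tb) {
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, names(tb))
  if (length(miss)) abort(sprintf("survival table missing columns: %s",
                                  paste(miss, collapse = ", ")))
  if (any(!is.finite(tb$time)) || any(tb$time <= 0)) {
    abort("survival `time` must be finite and > 0.")
  }
  if (!all(tb$event %in% c(0, 1))) abort("survival `event` must be 0 or 1.")
  as_tibble(tb[, c(need, setdiff(names(tb), need))])
}
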