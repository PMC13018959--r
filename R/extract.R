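#' Extract all membership-weighted radiomic features
#'
#' Runs the full four-family extraction (first-order intensity, intensity
#' histogram, GLCM, NGLDM) for an image/mask pair and returns one row of
#' family-prefixed features. A failing family yields NaN values for its
#' features together with a note, never a silent drop.
#'
#' @param image An `image_volume`.
#' @param mask A `membership_mask` on the same grid (any kind).
#' @param cfg A [discretization_config()].
#' @param glcm_pair_weight Pair-weight rule for the GLCM, see
#'   [build_weighted_glcm()].
#' @param ngldm_alpha Level-difference tolerance for the NGLDM.
#' @return A one-row tibble of features; attributes `provenance` (mask kind,
#'   sigma, configuration) and `notes`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_config(shape = c(24, 24, 24), radii_mm = c(6, 6, 6),
#'                                   seed = 1))
#' fv <- extract_all(ph$image, ph$mask)
#' fv$stat_Mean3D
extract_all <- function(image, mask, cfg = discretization_config(),
                        glcm_pair_weight = "product", ngldm_alpha = 0) {
  check_same_grid(image, mask)
  disc <- discretize(image, mask, cfg)
  notes <- character()

  fo <- weighted_first_order(image, mask, cfg)
  notes <- c(notes, attr(fo, "notes"))

  gl <- tryCatch(
    glcm_features(build_weighted_glcm(disc, pair_weight = glcm_pair_weight)),
    error = function(e) {
      nm <- names(glcm_features(build_weighted_glcm(
        list(levels = array(c(1L, 2L), c(2, 1, 1)), L = 2L,
             support = array(TRUE, c(2, 1, 1)),
             weights = array(1, c(2, 1, 1))))))
      structure(setNames(rep(NaN, length(nm)), nm),
                notes = paste("glcm failed:", conditionMessage(e)))
    })
  notes <- c(notes, attr(gl, "notes"))

  ng <- ngldm_features(build_weighted_ngldm(disc, alpha = ngldm_alpha))

  out <- as_tibble(as.list(c(fo, gl, ng)))
  attr(out, "provenance") <- list(mask_kind = mask$kind,
                                  sigma_mm = mask$sigma_mm,
                                  discretization = cfg,
                                  glcm_pair_weight = glcm_pair_weight,
                                  ngldm_alpha = ngldm_alpha)
  attr(out, "notes") <- notes
  out
}

#' Feature family from a feature name
#'
#' Maps `family_Name3D` column names to their family prefix
#' (`stat`, `ih`, `glcm`, `ngldm`).
#'
#' @param names Character vector of feature names.
#' @return Character vector of family prefixes.
#' @export
feature_family <- function(names) sub("_.*$", "", names)

#' Extract a feature table for a cohort
#'
#' @param pairs Named list of `list(image =, mask =)` pairs; names are
#'   patient IDs.
#' @param ... Passed to [extract_all()].
#' @return A feature tibble with `patient_id` plus one column per feature.
#' @export
extract_cohort <- function(pairs, ...) {
  ids <- names(pairs)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(pairs))
  rows <- purrr::map(seq_along(pairs), function(i) {
    fv <- extract_all(pairs[[i]]$image, pairs[[i]]$mask, ...)
    dplyr::bind_cols(tibble(patient_id = ids[i]), fv)
  })
  dplyr::bind_rows(rows)
}
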