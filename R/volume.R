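#' Construct an image volume
#'
#' An `image_volume` is a 3D scalar field of CT intensities (Hounsfield
#' units) together with its voxel geometry. World coordinates follow
#' `world = origin + index * spacing` per axis with 0-based voxel indices;
#' the direction matrix is assumed axis-aligned.
#'
#' @param data Numeric 3D array of intensities.
#' @param spacing Length-3 positive numeric, voxel size in mm per axis.
#' @param origin Length-3 numeric, world position (mm) of voxel (0,0,0).
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' dim(v$data)
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as_array3(data, "data")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive finite numbers.")
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    abort("`origin` must be 3 finite numbers.")
  }
  if (any(!is.finite(data))) {
    abort(sprintf("volume contains %d non-finite (NaN/Inf) voxels.",
                  sum(!is.finite(data))))
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a membership mask
#'
#' A `membership_mask` stores a per-voxel tumor membership field mu in
#' \[0, 1\] on the same grid convention as [image_volume()]. Binary masks are
#' the \{0, 1\} special case (`kind = "binary"`); Gaussian-fuzzified masks
#' have `kind = "fuzzy"`; their alpha-cut core and support are `"core"` and
#' `"support"` and are again strictly binary.
#'
#' @param data Numeric 3D array of memberships in \[0, 1\].
#' @param spacing,origin Grid geometry, see [image_volume()].
#' @param kind One of `"binary"`, `"fuzzy"`, `"core"`, `"support"`.
#' @param sigma_mm Length-3 smoothing standard deviations in mm (fuzzy kinds
#'   only), or `NULL`.
#' @return An object of class `membership_mask`.
#' @export
membership_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            kind = c("binary", "fuzzy", "core", "support"),
                            sigma_mm = NULL) {
  kind <- match.arg(kind)
  data <- as_array3(data, "data")
  if (any(!is.finite(data))) abort("mask contains non-finite voxels.")
  # numeric slack then clamp, so filtered masks never leave [0,1]
  if (min(data) < -1e-9 || max(data) > 1 + 1e-9) {
    abort("mask memberships outside [0, 1] beyond numeric slack.")
  }
  data[data < 0] <- 0
  data[data > 1] <- 1
  if (kind != "fuzzy" && !all(data == 0 | data == 1)) {
    abort(sprintf("kind '%s' requires strictly binary memberships.", kind))
  }
  vol <- image_volume(array(0, dim(data)), spacing, origin)  # validates geometry
  structure(list(data = data, spacing = vol$spacing, origin = vol$origin,
                 kind = kind, sigma_mm = sigma_mm),
            class = "membership_mask")
}

as_array3 <- function(x, what) {
  if (is.null(dim(x)) || length(dim(x)) != 3) {
    abort(sprintf("`%s` must be a 3D array, got %s.", what,
                  paste(dim(x) %||% length(x), collapse = "x")))
  }
  storage.mode(x) <- "double"
  array(as.vector(x), dim(x))  # strip extra attributes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid key of a volume or mask
#'
#' Rounds shape, spacing and origin to a fixed tolerance (1e-4 mm) so that
#' two objects with equal keys are voxel-wise comparable.
#'
#' @param x An `image_volume` or `membership_mask`.
#' @return A `grid_key` object (list of `shape`, `spacing`, `origin`).
#' @export
grid_key <- function(x) {
  structure(list(shape = dim(x$data),
                 spacing = round(x$spacing, 4),
                 origin = round(x$origin, 4)),
            class = "grid_key")
}

#' Check two volumes/masks share a grid
#'
#' @param a,b `image_volume` or `membership_mask` objects.
#' @param tol Geometric tolerance in mm (default 1e-4).
#' @return The shared [grid_key()], invisibly usable; errors otherwise with a
#'   message that names which component (shape, spacing, origin) disagrees.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$data), dim(b$data))) {
    abort(sprintf("shape mismatch: %s vs %s.",
                  paste(dim(a$data), collapse = "x"),
                  paste(dim(b$data), collapse = "x")))
  }
  if (any(abs(a$spacing - b$spacing) > tol)) {
    abort(sprintf("spacing mismatch beyond %g mm: (%s) vs (%s).", tol,
                  paste(a$spacing, collapse = ", "),
                  paste(b$spacing, collapse = ", ")))
  }
  if (any(abs(a$origin - b$origin) > tol)) {
    abort(sprintf("origin mismatch beyond %g mm: (%s) vs (%s).", tol,
                  paste(a$origin, collapse = ", "),
                  paste(b$origin, collapse = ", ")))
  }
  grid_key(a)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.membership_mask <- function(x, ...) {
  cat(sprintf("<membership_mask:%s> %s voxels, %d in support",
              x$kind, paste(dim(x$data), collapse = "x"),
              sum(x$data > 0)))
  if (!is.null(x$sigma_mm)) {
    cat(sprintf(", sigma (%s) mm", paste(signif(x$sigma_mm, 4), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
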