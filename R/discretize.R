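#' Discretization configuration
#'
#' @param method `"fixed_bin_number"` (default) or `"fixed_bin_size"`.
#' @param n_bins Number of grey levels for fixed-bin-number (default 32).
#' @param bin_width Bin width in HU for fixed-bin-size (default 25).
#' @param resegment Optional `c(low, high)` HU window applied before binning;
#'   `NULL` (default) disables intensity re-segmentation.
#' @return A `discretization_config` list.
#' @export
discretization_config <- function(method = c("fixed_bin_number", "fixed_bin_size"),
                                  n_bins = 32, bin_width = 25, resegment = NULL) {
  method <- match.arg(method)
  if (method == "fixed_bin_number" && (n_bins < 2 || n_bins != round(n_bins))) {
    abort("`n_bins` must be an integer >= 2.")
  }
  if (method == "fixed_bin_size" && bin_width <= 0) abort("`bin_width` must be > 0.")
  structure(list(method = method, n_bins = as.integer(n_bins),
                 bin_width = bin_width, resegment = resegment),
            class = "discretization_config")
}

#' Discretize intensities over a mask support
#'
#' Assigns grey levels 1..L to every voxel with membership above the support
#' threshold. For fixed bin number the rule is
#' `floor(n * (x - min) / (max - min)) + 1` capped at `n`, with min/max taken
#' over the support region, so the maximum intensity lands in the top
#' (right-closed) bin. A constant image yields a single level, which is a
#' valid degenerate case.
#'
#' @param image An `image_volume`.
#' @param mask A `membership_mask` on the same grid.
#' @param cfg A [discretization_config()].
#' @return List with `levels` (integer 3D array, 0 outside support), `L`
#'   (number of levels), `support` (logical array), `weights` (membership
#'   array restricted to the support).
#' @export
discretize <- function(image, mask, cfg = discretization_config()) {
  check_same_grid(image, mask)
  mu <- mask$data
  support <- mu > EPS_SUPP
  if (!is.null(cfg$resegment)) {
    lo <- cfg$resegment[1]; hi <- cfg$resegment[2]
    support <- support & image$data >= lo & image$data <= hi
  }
  if (!any(support)) abort("empty mask support: nothing to discretize.")
  x <- image$data[support]
  levels <- array(0L, dim(image$data))
  if (cfg$method == "fixed_bin_number") {
    lo <- min(x); hi <- max(x)
    if (hi - lo <= 0) {
      lv <- rep(1L, length(x)); L <- 1L
    } else {
      lv <- pmin(as.integer(floor(cfg$n_bins * (x - lo) / (hi - lo))) + 1L,
                 cfg$n_bins)
      L <- cfg$n_bins
    }
  } else {
    lo <- min(x)
    lv <- as.integer(floor((x - lo) / cfg$bin_width)) + 1L
    L <- max(lv)
  }
  levels[support] <- lv
  w <- array(0, dim(mu))
  w[support] <- mu[support]
  list(levels = levels, L = as.integer(L), support = support, weights = w)
}
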