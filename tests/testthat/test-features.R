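grid_pair <- function(intensities, memberships, spacing = c(1, 1, 1)) {
  d <- dim(intensities)
  list(image = image_volume(intensities, spacing),
       mask = membership_mask(memberships, spacing,
                              kind = if (all(memberships %in% c(0, 1))) "binary" else "fuzzy"))
}

test_that("fixed-bin-number discretization follows the binning formula", {
  img <- image_volume(array(c(0, 10, 20, 30, 0, 10, 20, 30), c(2, 2, 2)))
  msk <- membership_mask(array(1, c(2, 2, 2)))
  disc <- discretize(img, msk, discretization_config(n_bins = 4))
  expect_identical(sort(unique(as.vector(disc$levels))), 1:4)
  expect_identical(disc$levels[2, 2, 2], 4L)  # max intensity -> top bin

  # constant image: single level, L = 1
  disc0 <- discretize(image_volume(array(7, c(2, 2, 2))), msk,
                      discretization_config(n_bins = 8))
  expect_identical(unique(as.vector(disc0$levels)), 1L)
  expect_identical(disc0$L, 1L)

  # random patch vs direct formula
  set.seed(42)
  x <- array(rnorm(125, 0, 50), c(5, 5, 5))
  disc2 <- discretize(image_volume(x), membership_mask(array(1, c(5, 5, 5))),
                      discretization_config(n_bins = 8))
  expected <- pmin(floor(8 * (x - min(x)) / (max(x) - min(x))) + 1, 8)
  expect_identical(as.vector(disc2$levels), as.integer(expected))

  expect_error(discretize(img, membership_mask(array(0, c(2, 2, 2))),
                          discretization_config()), "empty")
})

test_that("fixed-bin-size discretization uses the configured HU width", {
  img <- image_volume(array(c(0, 10, 26, 60, 0, 0, 0, 0), c(2, 2, 2)))
  msk <- membership_mask(array(1, c(2, 2, 2)))
  disc <- discretize(img, msk, discretization_config("fixed_bin_size", bin_width = 25))
  expect_identical(disc$levels[1:4], c(1L, 1L, 2L, 3L))
})

test_that("weighted first-order matches hand arithmetic on a two-voxel case", {
  # embed the two weighted voxels in a tiny grid
  img <- array(0, c(2, 1, 1)); img[2, 1, 1] <- 10
  mu <- array(0, c(2, 1, 1)); mu[1, 1, 1] <- 0.25; mu[2, 1, 1] <- 0.75
  gp <- grid_pair(img, mu)
  fo <- weighted_first_order(gp$image, gp$mask)
  expect_equal(unname(fo["stat_Mean3D"]), 7.5)
  expect_equal(unname(fo["stat_Variance3D"]), 18.75)
})

test_that("binary weights reproduce classical unweighted statistics", {
  set.seed(7)
  x <- array(rnorm(6^3, 50, 30), c(6, 6, 6))
  m <- array(as.numeric(runif(6^3) > 0.4), c(6, 6, 6))
  gp <- grid_pair(x, m)
  fo <- weighted_first_order(gp$image, gp$mask)
  xv <- x[m > 0]
  n <- length(xv)
  mu <- mean(xv); v <- mean((xv - mu)^2)
  expect_equal(unname(fo["stat_Mean3D"]), mu, tolerance = 1e-10)
  expect_equal(unname(fo["stat_Variance3D"]), v, tolerance = 1e-10)
  expect_equal(unname(fo["stat_Skewness3D"]), mean((xv - mu)^3) / v^1.5,
               tolerance = 1e-10)
  expect_equal(unname(fo["stat_Kurtosis3D"]), mean((xv - mu)^4) / v^2 - 3,
               tolerance = 1e-10)
  expect_equal(unname(fo["stat_Median3D"]), quantile(xv, 0.5, type = 1,
                                                     names = FALSE))
  expect_equal(unname(fo["stat_P10_3D"]), quantile(xv, 0.1, type = 1,
                                                   names = FALSE))
  expect_equal(unname(fo["stat_Energy3D"]), sum(xv^2), tolerance = 1e-10)
  expect_equal(unname(fo["stat_RootMeanSquare3D"]), sqrt(mean(xv^2)),
               tolerance = 1e-10)
})

test_that("first-order features are invariant to rescaling all memberships", {
  set.seed(8)
  x <- array(rnorm(5^3, 0, 40), c(5, 5, 5))
  mu <- array(runif(5^3), c(5, 5, 5))
  f1 <- weighted_first_order(grid_pair(x, mu)$image, grid_pair(x, mu)$mask)
  mu2 <- mu * 0.5
  f2 <- weighted_first_order(grid_pair(x, mu2)$image, grid_pair(x, mu2)$mask)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("zero variance yields NaN shape moments with a note", {
  img <- image_volume(array(5, c(3, 3, 3)))
  msk <- membership_mask(array(1, c(3, 3, 3)))
  fo <- weighted_first_order(img, msk)
  expect_true(is.nan(fo[["stat_Skewness3D"]]))
  expect_true(is.nan(fo[["stat_Kurtosis3D"]]))
  expect_match(attr(fo, "notes"), "zero variance")
})

test_that("extract_all is schema-stable and reduces to the binary limit", {
  ph1 <- small_phantom(21)
  ph2 <- small_phantom(22, radius = 6)
  f1 <- extract_all(ph1$image, ph1$mask)
  f2 <- extract_all(ph2$image, ph2$mask)
  expect_identical(names(f1), names(f2))
  expect_identical(sort(unique(feature_family(names(f1)))),
                   c("glcm", "ih", "ngldm", "stat"))

  fz <- fuzzify(ph1$mask, multiplier = 1e-3)
  ffz <- extract_all(ph1$image, fz)
  expect_equal(as.numeric(f1), as.numeric(ffz), tolerance = 1e-6)
})

test_that("fuzzy weighting pulls boundary statistics toward the core (intensity equalization)", {
  # high-intensity slab abuts the tumor: the support mean is badly inflated,
  # the membership-weighted mean much less so
  ph <- make_phantom(phantom_config(shape = c(36, 36, 36), radii_mm = c(7, 7, 7),
                                    lumpiness = 0, adjacency = "bone",
                                    noise_sd = 5, seed = 31))
  masks <- comparative_masks(ph$mask, 1)
  m_bin <- extract_all(ph$image, masks$bin)$stat_Mean3D
  m_fuzz <- extract_all(ph$image, masks$fuzzy)$stat_Mean3D
  m_ext <- extract_all(ph$image, masks$support)$stat_Mean3D
  expect_lt(abs(m_fuzz - m_bin), abs(m_ext - m_bin))
})

test_that("extraction records provenance", {
  ph <- small_phantom(23)
  fz <- fuzzify(ph$mask, 1.5)
  fv <- extract_all(ph$image, fz)
  prov <- attr(fv, "provenance")
  expect_identical(prov$mask_kind, "fuzzy")
  expect_equal(prov$sigma_mm, rep(1.5, 3))
})
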