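sphere_pair <- function(seed = 9, shape = 44, radius = 10) {
  make_phantom(phantom_config(shape = rep(shape, 3), radii_mm = rep(radius, 3),
                              lumpiness = 0, noise_sd = 8, seed = seed))
}

test_that("spec sampling is deterministic, bounded and effectively random", {
  s1 <- sample_perturbations(20, seed = 3)
  s2 <- sample_perturbations(20, seed = 3)
  expect_identical(s1, s2)
  b <- perturbation_bounds()
  for (s in s1) {
    expect_true(all(abs(s$translation_mm) <= b$translation_mm[2]))
    expect_true(abs(s$rotation_deg) <= b$rotation_deg[2])
    expect_true(s$noise_sigma_HU >= 0 && s$noise_sigma_HU <= b$noise_sigma_HU[2])
    expect_true(s$contour_magnitude_mm >= b$contour_magnitude_mm[1] &&
                s$contour_magnitude_mm <= b$contour_magnitude_mm[2])
  }
  key <- vapply(s1, function(s) paste(signif(unlist(s[1:4]), 12), collapse = "|"),
                character(1))
  expect_identical(length(unique(key)), 20L)  # all distinct

  zb <- list(translation_mm = c(0, 0), rotation_deg = c(0, 0),
             noise_sigma_HU = c(0, 0), contour_magnitude_mm = c(0, 0))
  sz <- sample_perturbations(3, bounds = zb, seed = 1)
  expect_true(all(vapply(sz, function(s) all(unlist(s[1:4]) == 0), logical(1))))
  expect_error(sample_perturbations(2, bounds = list(translation_mm = c(1, -1)),
                                    seed = 1), "bounds")
})

test_that("identity transforms reproduce inputs bit-exactly", {
  ph <- sphere_pair()
  r <- apply_rigid(ph$image, ph$mask, c(0, 0, 0), 0)
  expect_identical(r$image$data, ph$image$data)
  expect_identical(r$mask$data, ph$mask$data)
  expect_identical(add_noise(ph$image, 0)$data, ph$image$data)
  expect_identical(randomize_contour(ph$mask, 0)$data, ph$mask$data)
  pp <- perturb_chain(ph$image, ph$mask, perturbation_spec())
  expect_identical(pp$image$data, ph$image$data)
  expect_identical(pp$mask$data, ph$mask$data)
})

test_that("integer-voxel translations are exact array shifts", {
  ph <- sphere_pair()
  r <- apply_rigid(ph$image, ph$mask, translation_mm = c(1, 0, 0))
  n <- dim(ph$image$data)[1]
  expect_identical(r$image$data[2:n, , ], ph$image$data[1:(n - 1), , ])
  expect_identical(r$mask$data[2:n, , ], ph$mask$data[1:(n - 1), , ])
})

test_that("rotation and its inverse nearly cancel on a sphere", {
  ph <- sphere_pair()
  r1 <- apply_rigid(ph$image, ph$mask, rotation_deg = 10)
  r2 <- apply_rigid(r1$image, r1$mask, rotation_deg = -10)
  expect_gte(dice(r2$mask$data, ph$mask$data), 0.99)
})

test_that("transforms that push the mask off the grid are rejected with a count", {
  ph <- make_phantom(phantom_config(shape = c(30, 30, 30), radii_mm = c(9, 9, 9),
                                    lumpiness = 0, noise_sd = 8, margin_vox = 4,
                                    seed = 9))
  expect_error(apply_rigid(ph$image, ph$mask, translation_mm = c(12, 0, 0)),
               "[0-9]+ mask voxels")
})

test_that("additive noise has the configured moments and is seeded", {
  ph <- sphere_pair()
  n1 <- add_noise(ph$image, 20, seed = 4)
  delta <- n1$data - ph$image$data
  expect_equal(sd(delta), 20, tolerance = 0.025)
  expect_lt(abs(mean(delta)), 0.5)
  n2 <- add_noise(ph$image, 20, seed = 4)
  expect_identical(n1$data, n2$data)
  expect_false(identical(add_noise(ph$image, 20, seed = 5)$data, n1$data))
})

test_that("contour randomization deforms within the simulated Dice band", {
  ph <- sphere_pair()
  dd <- vapply(0:9, function(s) {
    dice(randomize_contour(ph$mask, 1.5, seed = s)$data, ph$mask$data)
  }, numeric(1))
  # band frozen from a 20-seed simulation of this field design
  expect_true(all(dd > 0.70 & dd < 0.95))
  expect_false(identical(randomize_contour(ph$mask, 1.5, seed = 0)$data,
                         randomize_contour(ph$mask, 1.5, seed = 1)$data))
})

test_that("the chain is deterministic, ordered, and leaves volumes near the original", {
  ph <- sphere_pair()
  specs <- sample_perturbations(20, seed = 11)
  p1 <- perturb_chain(ph$image, ph$mask, specs[[1]])
  p2 <- perturb_chain(ph$image, ph$mask, specs[[1]])
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$mask$data, p2$mask$data)

  vols <- vapply(specs[1:20], function(s) {
    sum(perturb_chain(ph$image, ph$mask, s)$mask$data)
  }, numeric(1))
  expect_equal(mean(vols) / sum(ph$mask$data), 1, tolerance = 0.1)
  expect_gt(length(unique(vols)), 10)  # perturbations genuinely differ
})

test_that("noise only touches the image and contour randomization only the mask", {
  ph <- sphere_pair()
  spec_noise <- perturbation_spec(noise_sigma_HU = 15, noise_seed = 2)
  pn <- perturb_chain(ph$image, ph$mask, spec_noise)
  expect_identical(pn$mask$data, ph$mask$data)
  expect_false(identical(pn$image$data, ph$image$data))

  spec_cont <- perturbation_spec(contour_magnitude_mm = 1.5, contour_seed = 2)
  pc <- perturb_chain(ph$image, ph$mask, spec_cont)
  expect_identical(pc$image$data, ph$image$data)
  expect_false(identical(pc$mask$data, ph$mask$data))
})

test_that("rigid moves the mask centroid by the applied translation", {
  ph <- sphere_pair()
  t <- c(0.6, -0.4, 0.8)
  r <- apply_rigid(ph$image, ph$mask, translation_mm = t)
  cen0 <- colMeans(arrayInd(which(ph$mask$data > 0), dim(ph$mask$data)))
  cen1 <- colMeans(arrayInd(which(r$mask$data > 0), dim(r$mask$data)))
  expect_true(all(abs((cen1 - cen0) - t) < 0.5))  # within half a voxel
})
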