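# Reconstruction tests run on a coarse 64-pixel grid; the full-resolution
# round-trip lives with the acceptance suite.

geom64 <- scan_geometry(detector_pixels = 64L, detector_pitch_mm = 0.4,
                        n_angles_per_rotation = 180L)

make_sino <- function(img, angles, geom, pm = 0.4) {
  list(projections = t(vapply(angles, function(a)
    forward_project(img, a, geom, pixel_mm = pm),
    numeric(geom$detector_pixels))),
    angles_deg = angles)
}

test_that("FBP is linear, localizes point inserts, and guards coverage", {
  angles <- seq(0, 358, by = 2)
  disk <- disk_image(64, 0.4, 6, 0.02)
  sino <- make_sino(disk, angles, geom64)
  r1 <- fbp_reconstruct(sino, geom64, 64, 0.4)
  sino2 <- sino; sino2$projections <- 2 * sino$projections
  r2 <- fbp_reconstruct(sino2, geom64, 64, 0.4)
  expect_equal(r2$values, 2 * r1$values, tolerance = 1e-10)

  zero <- sino; zero$projections[] <- 0
  expect_equal(fbp_reconstruct(zero, geom64, 64, 0.4)$values,
               matrix(0, 64, 64))

  # point-like insert: centroid lands within one pixel of the truth
  pt <- disk_image(64, 0.4, 0.45, 1, center_mm = c(3.2, -2.4))
  rp <- fbp_reconstruct(make_sino(pt, angles, geom64), geom64, 64, 0.4)
  v <- pmax(rp$values, 0)
  idx <- which(v > 0.5 * max(v), arr.ind = TRUE)
  ctr <- colSums(idx * v[idx]) / sum(v[idx])
  truth_ctr <- colMeans(which(pt > 0, arr.ind = TRUE))
  expect_lt(sqrt(sum((ctr - truth_ctr)^2)), 1)

  expect_error(fbp_reconstruct(make_sino(disk, 10, geom64), geom64, 64, 0.4),
               "insufficient angular coverage")
  expect_warning(fbp_reconstruct(make_sino(disk, c(0, 20, 40), geom64),
                                 geom64, 64, 0.4),
                 "angular gap")
})

test_that("ordered-subset SIRT converges and levels match across subset sizes", {
  angles <- seq(0, 357, by = 3)
  disk <- disk_image(64, 0.4, 6, 0.02)
  sino <- make_sino(disk, angles, geom64)
  sup <- disk > 0

  zero <- sino; zero$projections[] <- 0
  expect_equal(os_iterative_reconstruct(zero, geom64, 64, 0.4,
                                        n_subsets = 12)$values,
               matrix(0, 64, 64))

  errs <- vapply(1:3, function(k)
    nrmse(os_iterative_reconstruct(sino, geom64, 64, 0.4, n_subsets = 12,
                                   n_iters = k)$values, disk, sup),
    numeric(1))
  expect_true(all(diff(errs) < 0))
  fid <- os_iterative_reconstruct(sino, geom64, 64, 0.4, n_subsets = 12,
                                  n_iters = 3)$params$fidelity
  expect_true(all(diff(fid) < 0))

  # image levels agree between unequal-count resamplings of the same scan
  set.seed(9)
  draw <- function(k) {
    i <- sample(length(angles), k, replace = TRUE)
    list(projections = sino$projections[i, ], angles_deg = angles[i])
  }
  rA <- os_iterative_reconstruct(draw(200), geom64, 64, 0.4, n_subsets = 12)
  rB <- os_iterative_reconstruct(draw(280), geom64, 64, 0.4, n_subsets = 12)
  expect_equal(mean(rA$values[sup]), mean(rB$values[sup]), tolerance = 0.02)

  # result does not depend on the order projections arrive in
  shuf <- sample(length(angles))
  rS <- os_iterative_reconstruct(
    list(projections = sino$projections[shuf, ], angles_deg = angles[shuf]),
    geom64, 64, 0.4, n_subsets = 12)
  rO <- os_iterative_reconstruct(sino, geom64, 64, 0.4, n_subsets = 12)
  expect_lt(nrmse(rS$values, rO$values, rO$values != 0), 0.01)

  expect_error(os_iterative_reconstruct(make_sino(disk, c(0, 90), geom64),
                                        geom64, 64, 0.4, n_subsets = 24),
               "n_subsets exceeds")
})

test_that("the Gaussian post-filter preserves the mean and tames variance", {
  set.seed(3)
  img <- structure(list(values = matrix(runif(64 * 64), 64),
                        pixel_mm = 0.4, bin_id = 0L, method = "fbp",
                        params = list()), class = "recon_image")
  expect_identical(post_filter(img, 0), img)
  sm <- post_filter(img, 1.2)
  expect_equal(mean(sm$values), mean(img$values), tolerance = 1e-3)
  expect_lt(var(as.vector(sm$values)), var(as.vector(img$values)))
})
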