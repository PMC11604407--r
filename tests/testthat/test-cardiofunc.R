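test_that("cavity segmentation recovers a disk and ignores intensity scale", {
  img <- disk_image(96, 0.2, 2, 0.045) +
    (disk_image(96, 0.2, 9.6, 0.022) - disk_image(96, 0.2, 2, 0.022))
  seg <- segment_lv_cavity(img, pixel_mm = 0.2)
  expect_equal(seg$volume_ul, pi * 2^2, tolerance = 0.02)
  seg10 <- segment_lv_cavity(10 * img, pixel_mm = 0.2)
  expect_identical(seg10$mask, seg$mask)
  expect_error(segment_lv_cavity(matrix(0.02, 96, 96), pixel_mm = 0.2),
               "cavity not found")
})

test_that("EF, FS and strain follow their definitions and flag degeneracies", {
  expect_equal(ejection_fraction(50, 25), 50)
  expect_equal(ejection_fraction(30, 30), 0)
  expect_warning(ef <- ejection_fraction(20, 25), "negative")
  expect_lt(ef, 0)
  expect_error(ejection_fraction(0, 10), "positive")

  expect_equal(fractional_shortening(4, 3), 25)
  expect_equal(fractional_shortening(3, 3), 0)
  expect_error(fractional_shortening(0, 1), "positive")

  expect_equal(strain(10, 8), -0.2)
  expect_equal(strain(7, 7), 0)
  expect_error(strain(0, 5), "positive")
})

test_that("LVID is the minor-axis chord through the centroid", {
  n <- 64
  mk <- function(a, b) {
    ax <- seq_len(n) - (n + 1) / 2
    X <- matrix(ax, n, n, byrow = TRUE); Y <- matrix(ax, n, n)
    (X / a)^2 + (Y / b)^2 <= 1
  }
  expect_equal(lv_internal_diameter(mk(10, 10), 0.2), 4.0, tolerance = 0.05)
  # 20 x 10 pixel semi-axes: chord along the short direction
  expect_equal(lv_internal_diameter(mk(20, 10), 0.2), 4.0, tolerance = 0.05)
  expect_error(lv_internal_diameter(matrix(FALSE, 8, 8), 0.2), "empty")
})

test_that("segmental strain vanishes under identity and tracks uniform scaling", {
  d40 <- disk_image(128, 1, 40, 1) > 0
  d32 <- disk_image(128, 1, 32, 1) > 0
  same <- segmental_strain(d40, d40)
  expect_equal(unname(same$segment_strain), rep(0, 6))
  shr <- segmental_strain(d40, d32)
  expect_equal(unname(shr$segment_strain), rep(-0.2, 6), tolerance = 0.05)
  expect_true(all(abs(shr$segment_strain - (-0.2)) < 0.01))
  expect_equal(shr$gls, mean(shr$segment_strain))
  expect_named(shr$segment_strain,
               c("posterior base", "posterior mid", "posterior apex",
                 "anterior apex", "anterior mid", "anterior base"))
})

test_that("severity classes respect the stated boundary conventions", {
  expect_equal(classify_heart_failure(15), "severe")
  expect_equal(classify_heart_failure(47.34), "mild")
  expect_equal(classify_heart_failure(20), "moderate")
  expect_equal(classify_heart_failure(40), "moderate")
  expect_equal(classify_fibrosis(45), "severe")
  expect_equal(classify_fibrosis(10), "mild")
  expect_equal(classify_fibrosis(40), "moderate")
  expect_equal(classify_fibrosis(20), "moderate")
})

test_that("cycle and phase timing arithmetic is exact", {
  expect_equal(cycle_length_ms(400), 150)
  expect_equal(phase_duration_ms(400, 12), 12.5)
  expect_equal(phase_duration_ms(600, 12), 8.333, tolerance = 1e-4)
  expect_error(cycle_length_ms(0), "positive")
  expect_error(phase_duration_ms(400, 0), ">= 1")
})

test_that("EF rises as the contraction factor falls", {
  # analytic property of the phantom ground truth the metrics target
  efs <- vapply(c(0.9, 0.75, 0.632), function(s) {
    cfg <- phantom_config(contraction_factor = s)
    a <- lv_cavity_area_truth(cfg, seq(0, 0.99, by = 0.01))
    (max(a) - min(a)) / max(a) * 100
  }, numeric(1))
  expect_true(all(diff(efs) > 0))
})
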