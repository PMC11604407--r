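test_that("forward projection conserves mass and respects symmetry", {
  geom <- scan_geometry()
  n <- 128; pm <- 0.2

  expect_equal(forward_project(matrix(0, n, n), 13, geom, pixel_mm = pm),
               numeric(geom$detector_pixels))

  # Radon mass conservation at several angles, noiseless
  im <- render_thorax(phantom_config(), 0)
  mass <- sum(im$values) * pm^2
  for (a in seq(0, 351, by = 27)) {
    p <- forward_project(im, a, geom)
    expect_equal(sum(p) * geom$detector_pitch_mm, mass, tolerance = 0.005)
  }

  # rotational symmetry of a centred disk
  disk <- disk_image(n, pm, 6, 0.02)
  expect_equal(forward_project(disk, 0, geom, pixel_mm = pm),
               forward_project(disk, 90, geom, pixel_mm = pm),
               tolerance = 1e-8)

  expect_error(forward_project(matrix(0, 4, 6), 0, geom, pixel_mm = pm),
               "square")
})

test_that("scan simulation lays out angles and timestamps and reproduces exactly", {
  cfg <- quick_phantom()
  geom <- quick_geom(duration_s = 2, n_angles_per_rotation = 60L)
  st <- simulate_scan(cfg, geom)
  expect_equal(nrow(st$projections), 80)       # 2 s at 40 fps
  expect_equal(st$angles_deg[61], 0)           # wraparound after one rotation
  expect_equal(st$angles_deg[2], 6)
  expect_true(all(diff(st$timestamps_s) > 0))
  expect_equal(st$angles_deg,
               ((seq_len(80) - 1) * 6) %% 360)

  # static phantom: identical angles give identical projections
  stat <- quick_phantom(contraction_factor = 1, diaphragm_amp_mm = 0)
  st2 <- simulate_scan(stat, geom)
  expect_equal(st2$projections[1, ], st2$projections[61, ], tolerance = 1e-12)

  # bitwise reproducibility including the noise stream
  gn <- quick_geom(duration_s = 1, photon_count_I0 = 1e4)
  expect_identical(simulate_scan(cfg, gn)$projections,
                   simulate_scan(cfg, gn)$projections)
})

test_that("photon noise follows the log-domain delta method and flags starvation", {
  p <- matrix(0.6, 100, 100)
  pn <- cardiogate:::.add_poisson_noise(p, 1e4, seed = 5)
  expect_equal(var(as.vector(pn)), exp(0.6) / 1e4, tolerance = 0.2)
  expect_equal(mean(pn), 0.6, tolerance = 0.01)
  expect_warning(cardiogate:::.add_poisson_noise(matrix(12, 2, 2), 100, 1),
                 "starvation")
})

test_that("projection streams round-trip through TIFF plus CSV sidecar", {
  st <- simulate_scan(quick_phantom(), quick_geom(duration_s = 1))
  dir <- withr::local_tempdir()
  write_stream(st, dir)
  st2 <- read_stream(dir)
  expect_identical(st2$angles_deg, st$angles_deg)
  expect_identical(st2$timestamps_s, st$timestamps_s)
  expect_identical(st2$truth$truth_resp_state, st$truth$truth_resp_state)
  expect_equal(st2$projections, st$projections, tolerance = 1e-6,
               ignore_attr = TRUE)
})
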