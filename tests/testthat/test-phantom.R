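test_that("cardiac phase is exact for jitter-free beats and rejects bad times", {
  cfg <- phantom_config(cycle_jitter_cv = 0)   # 400 bpm, 0.15 s beats
  expect_equal(cardiac_phase_truth(cfg, 0.075), 0.5)
  expect_equal(cardiac_phase_truth(cfg, 0), 0)
  expect_error(cardiac_phase_truth(cfg, -0.1), "non-negative")

  # monotone within each beat, resets at boundaries, stays in [0,1)
  t <- seq(0, 1.2, by = 1e-3)
  ph <- cardiac_phase_truth(cfg, t)
  expect_true(all(ph >= 0 & ph < 1))
  d <- diff(ph)
  expect_true(all(d > 0 | d < -0.9))          # increase or reset
  expect_equal(sum(d < -0.9), 8)              # 8 beat boundaries in 1.2 s
})

test_that("seeded beat-length jitter follows the documented recipe", {
  cfg <- phantom_config(cycle_jitter_cv = 0.05, seed = 7)
  # independent replay: one clipped standard-normal draw per beat
  n <- 32
  set.seed(7)
  z <- pmin(pmax(rnorm(n), -3), 3)
  lens <- 0.15 * (1 + 0.05 * z)
  b <- cumsum(c(0, lens))
  i <- findInterval(1.0, b)
  expect_equal(cardiac_phase_truth(cfg, 1.0), (1.0 - b[i]) / lens[i],
               tolerance = 1e-12)
  # identical seeds give bitwise-identical schedules
  expect_identical(cardiac_phase_truth(cfg, seq(0, 5, by = 0.01)),
                   cardiac_phase_truth(cfg, seq(0, 5, by = 0.01)))
})

test_that("respiratory truth partitions the cycle with a mid-inspiratory peak", {
  cfg <- phantom_config()
  t <- seq(0, 10, by = 5e-4)
  r <- resp_state_truth(cfg, t)
  expect_equal(mean(r$state == "inspiration"), 0.30, tolerance = 0.01)
  expect_equal(max(r$displacement_mm), cfg$diaphragm_amp_mm,
               tolerance = 1e-4)
  # end-expiratory plateau is exactly still
  late <- r$displacement_mm[r$state == "expiration"]
  expect_true(all(late == 0))
})

test_that("thorax rendering is periodic and matches analytic cavity geometry", {
  cfg <- phantom_config(cycle_jitter_cv = 0)   # 0.15 s cardiac, 0.5 s resp
  im0 <- render_thorax(cfg, 0)
  im1 <- render_thorax(cfg, 1.5)               # common period of both cycles
  expect_equal(im0$values, im1$values)

  # no contraction: cavity pixel count constant over time
  cfg1 <- phantom_config(contraction_factor = 1)
  counts <- vapply(c(0, 0.04, 0.09), function(t)
    sum(render_thorax(cfg1, t)$values == cfg1$mu$cavity_contrast), numeric(1))
  expect_true(all(counts == counts[1]))

  # rasterized end-diastolic cavity area within 2% of pi*a*b
  n_cav <- sum(im0$values == cfg$mu$cavity_contrast)
  expect_equal(n_cav * cfg$pixel_mm^2, pi * prod(cfg$lv_endo_semiaxes_mm),
               tolerance = 0.02)

  expect_error(render_thorax(phantom_config(grid_n = 32), 0),
               "exceed")
})

test_that("analytic cavity area reproduces the contraction model", {
  cfg <- phantom_config(contraction_factor = 0.707)
  ab <- prod(cfg$lv_endo_semiaxes_mm)
  expect_equal(lv_cavity_area_truth(cfg, 0), pi * ab)
  es <- lv_cavity_area_truth(cfg, cfg$systole_phase)
  expect_equal(es, 0.5 * pi * ab, tolerance = 1e-3)
  expect_equal((1 - es / (pi * ab)) * 100, 50, tolerance = 0.1)
})

test_that("phantom configuration rejects invalid physiology", {
  expect_error(phantom_config(inspiratory_fraction = 1.2), "inspiratory")
  expect_error(phantom_config(contraction_factor = 0), "contraction")
  expect_error(phantom_config(lv_endo_semiaxes_mm = c(4, 3)), "strictly inside")
  expect_error(phantom_config(mu = list(soft = 0.02)), "mu must name")
})
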