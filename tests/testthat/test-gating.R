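# Unit tests for the signal-extraction and phase-assignment chain. A
# coarse 30 s scan is shared by the spectral tests.

coarse_scan <- local({
  cfg <- quick_phantom(seed = 11)
  st <- simulate_scan(cfg, quick_geom(duration_s = 30))
  list(cfg = cfg, st = st)
})

test_that("MI registration recovers known shifts and matches brute force", {
  set.seed(42)
  base <- as.vector(stats::filter(rnorm(160), rep(1, 9), circular = TRUE))
  tpl <- template_model(base, c(rep(TRUE, 30), rep(FALSE, 130)),
                        c(rep(FALSE, 40), rep(TRUE, 40), rep(FALSE, 80)))
  expect_identical(register_template(base, tpl, 8), 0L)
  shifted <- base[((seq_along(base) - 1 - 5) %% 160) + 1]
  expect_identical(register_template(shifted, tpl, 8), 5L)

  # MI of a signal with itself equals its marginal entropy
  h <- local({
    b <- pmin(floor((base - min(base)) / diff(range(base)) * 32), 31)
    p <- table(b) / length(b)
    -sum(p * log(p))
  })
  expect_equal(cardiogate:::mutual_information(base, base), h)

  # 2D case: recover (5,-3) and agree with an independent exhaustive search
  set.seed(7)
  img <- matrix(rnorm(48 * 40), 48, 40)
  img <- img + 3 * outer(dnorm(1:48, 20, 6), dnorm(1:40, 25, 5))
  sh <- cardiogate:::.circshift(img, c(5, -3))
  got <- register_template(sh, img, 8)
  expect_equal(unname(got), c(5, -3))
  brute <- expand.grid(dy = -8:8, dx = -8:8)
  mi <- mapply(function(dy, dx)
    oracle_mi(img, cardiogate:::.circshift(sh, -c(dy, dx))),
    brute$dy, brute$dx)
  expect_equal(unname(unlist(brute[which.max(mi), ])), c(5, -3))

  expect_error(register_template(rep(1, 160), tpl, 4), "degenerate")
})

test_that("ROI mapping translates masks and guards the frame boundary", {
  m <- rep(FALSE, 100); m[40:60] <- TRUE
  expect_identical(map_roi(m, 0L), m)
  expect_equal(which(map_roi(m, 2L)), which(m) + 2L)
  expect_error(map_roi(m, 90L), "half")

  m2 <- matrix(FALSE, 20, 20); m2[9:12, 9:12] <- TRUE
  sh <- map_roi(m2, c(2L, 0L))
  c0 <- colMeans(which(m2, arr.ind = TRUE))
  c1 <- colMeans(which(sh, arr.ind = TRUE))
  expect_equal(unname(c1 - c0), c(2, 0))
})

test_that("signal extraction sums ROI intensities per projection", {
  st <- list(projections = matrix(3, 10, 8))
  roi <- c(TRUE, TRUE, TRUE, rep(FALSE, 5))
  expect_equal(extract_signal(st, roi), rep(9, 10))
  st$projections[] <- 0
  expect_equal(extract_signal(st, roi), rep(0, 10))
  expect_error(extract_signal(st, rep(FALSE, 8)), "empty")
})

test_that("cardiac ROI signal carries the configured heart rate", {
  st <- coarse_scan$st
  rcfg <- run_config(phantom = coarse_scan$cfg,
                     geometry = quick_geom(duration_s = 30), seed = 11)
  tpl <- make_template(rcfg, st)
  sig <- extract_signal(st, tpl$cardiac_roi)
  # periodogram argmax oracle inside the cardiac band
  x <- sig - mean(sig)
  spec <- Mod(fft(x))[seq_len(length(x) / 2)]
  fr <- (seq_along(spec) - 1) * 40 / length(x)
  pk <- fr[fr >= 5 & fr <= 12][which.max(spec[fr >= 5 & fr <= 12])]
  expect_equal(pk * 60, coarse_scan$cfg$heart_rate_bpm, tolerance = 0.02)
})

test_that("band-pass keeps in-band tones and rejects DC and out-of-band", {
  fs <- 40; t <- seq(0, 30, by = 1 / fs)
  tone <- sin(2 * pi * 8 * t)
  out <- bandpass(tone, fs, c(5, 12))
  mid <- seq(200, length(t) - 200)
  expect_equal(max(abs(out[mid])), 1, tolerance = 0.05)

  dc <- bandpass(rep(4, 1000), fs, c(5, 12))
  expect_lt(sqrt(sum(dc^2)), 1e-6 * sqrt(sum(rep(4, 1000)^2)))

  mix <- sin(2 * pi * 1 * t) + sin(2 * pi * 8 * t)
  fmix <- bandpass(mix, fs, c(5, 12))
  amp_at <- function(x, f) {
    n <- length(x)
    2 * Mod(sum(x * exp(-2i * pi * f * seq_len(n) / fs))) / n
  }
  expect_gt(20 * log10(amp_at(mix, 1) / amp_at(fmix, 1)), 20)
  expect_equal(amp_at(fmix, 8), 1, tolerance = 0.05)
})

test_that("spectral rate estimation locates pure tones and rejects silence", {
  fs <- 40; t <- seq(0, 60, by = 1 / fs)
  est <- estimate_frequency(sin(2 * pi * 6.667 * t), fs, c(5, 12))
  expect_equal(est$bpm, 400, tolerance = 1 / 400)
  expect_equal(estimate_frequency(sin(2 * pi * 10 * t), fs, c(5, 12))$bpm,
               600, tolerance = 1 / 600)
  expect_error(estimate_frequency(rep(1, 2400), fs, c(5, 12)),
               "no periodic component")
  expect_error(estimate_frequency(sin(2 * pi * 6 * t[1:20]), fs, c(5, 12)),
               "short")
})

test_that("inspiration rejection retains the expiratory duty cycle", {
  fs <- 200; rate <- 2; duty <- 0.3
  t <- seq(0, 60, by = 1 / fs)
  r <- (t * rate) %% 1
  wave <- ifelse(r < duty, 0.5 * (1 - cos(2 * pi * r / duty)), 0)
  rej <- detect_inspiration(wave - mean(wave), fs, rate)
  expect_equal(mean(!rej), 0.70, tolerance = 0.02 / 0.70)

  # counting oracle: rejected samples should be the high-amplitude ones
  expect_gt(min(wave[rej]), max(0, stats::quantile(wave, 0.5)))

  # flat signal rejects nothing; rescaling changes nothing
  expect_equal(mean(!detect_inspiration(rep(0.3, 1000), fs, rate)), 1.0)
  expect_identical(rej, detect_inspiration(2 * (wave - mean(wave)), fs, rate))
})

test_that("phase assignment interpolates between peaks, however long the beats", {
  fs <- 1000
  bump <- function(t, centers, width = 0.05) {
    rowSums(sapply(centers, function(c0)
      ifelse(abs(t - c0) < width, cos(pi * (t - c0) / (2 * width))^2, 0)))
  }
  t <- seq(0, 0.65, by = 1 / fs)
  x <- bump(t, c(0.05, 0.20, 0.40, 0.60))     # beats of 0.15 then 0.20 s
  ph <- assign_cardiac_phase(x, fs, 60 / 0.17)
  at <- function(tt) ph$fraction[which.min(abs(t - tt))]
  expect_equal(at(0.125), 0.5, tolerance = 0.01)
  expect_equal(at(0.20), 0.0, tolerance = 0.01)
  expect_equal(at(0.30), 0.5, tolerance = 0.01)   # (0.30-0.20)/0.20

  # affine rescaling of the signal leaves the assignment unchanged
  ph2 <- assign_cardiac_phase(5 * x + 2, fs, 60 / 0.17)
  expect_equal(ph2$fraction, ph$fraction)

  expect_error(assign_cardiac_phase(bump(t, 0.3), fs, 400), "unusable")
})

test_that("phase binning follows the half-open 12-bin convention", {
  expect_identical(bin_phases(0), 0L)
  expect_identical(bin_phases(1 / 12), 1L)
  expect_identical(bin_phases(0.0832), 0L)     # just inside the first phase
  expect_error(bin_phases(1.0), "\\[0,1\\)")
  expect_error(bin_phases(-0.01), "\\[0,1\\)")

  set.seed(1)
  f <- runif(1200)
  b <- bin_phases(f)
  counts <- tabulate(b + 1L, 12L)
  expect_equal(sum(counts), 1200)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})
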