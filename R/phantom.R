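# 4D digital mouse-thorax phantom: a single axial slice with a beating,
# contrast-enhanced LV cavity and respiratory diaphragm motion. All
# downstream stages (acquisition, gating, reconstruction, function metrics)
# are validated against the analytically known cardiac/respiratory state
# this module provides.

# Fixed slice anatomy (mm, relative to rotation centre). The heart stays
# put during breathing; only the diaphragm/lung boundary moves.
.anatomy <- list(
  body_center  = c(0, -0.5), body_semiaxes = c(11.5, 9.0),
  lung_centers = list(c(-5.8, 1.2), c(5.8, 1.2)), lung_semiaxes = c(3.0, 4.6),
  spine_center = c(0, -7.2), spine_radius = 1.2,
  heart_center = c(-1.0, 1.5),
  diaphragm_y0 = -2.5
)

#' Phantom configuration
#'
#' Parametric description of the synthetic 4D thorax slice. Defaults model a
#' healthy anaesthetised mouse: 400 bpm heart rate with 5% per-beat
#' cycle-length jitter, 120 breaths/min with an inspiratory sub-phase
#' occupying 30% of each respiratory cycle, and an end-diastolic
#' contrast-filled LV cavity that shrinks isotropically to
#' `contraction_factor` of its semi-axes at end-systole
#' (default 0.632, i.e. a ground-truth area ejection fraction of 60%).
#'
#' @param grid_n pixels per side of the square slice (>= 32)
#' @param pixel_mm pixel pitch in mm
#' @param heart_rate_bpm mean heart rate, beats/min
#' @param resp_rate_bpm respiratory rate, breaths/min
#' @param inspiratory_fraction fraction of each respiratory cycle spent in
#'   inspiration, in (0,1)
#' @param cycle_jitter_cv coefficient of variation of per-beat cycle length
#' @param lv_epi_semiaxes_mm epicardial ellipse semi-axes (a,b) in mm
#' @param lv_endo_semiaxes_mm end-diastolic endocardial (cavity) semi-axes
#' @param contraction_factor multiplicative shrink of the endocardial
#'   semi-axes at end-systole, in (0,1]
#' @param diaphragm_amp_mm peak craniocaudal diaphragm displacement
#' @param systole_phase cardiac-cycle fraction at which contraction peaks
#' @param mu attenuation coefficients (mm^-1) per tissue: soft, myocardium,
#'   cavity_contrast, lung, bone
#' @param seed integer seed for the beat-length jitter stream
#' @return an object of class `phantom_config`
#' @export
phantom_config <- function(grid_n = 128L, pixel_mm = 0.2,
                           heart_rate_bpm = 400, resp_rate_bpm = 120,
                           inspiratory_fraction = 0.30,
                           cycle_jitter_cv = 0.05,
                           lv_epi_semiaxes_mm = c(3.2, 2.8),
                           lv_endo_semiaxes_mm = c(2.4, 2.0),
                           contraction_factor = 0.632,
                           diaphragm_amp_mm = 1.5,
                           systole_phase = 0.35,
                           mu = list(soft = 0.022, myocardium = 0.024,
                                     cavity_contrast = 0.045, lung = 0.005,
                                     bone = 0.060),
                           seed = 1L) {
  grid_n <- as.integer(grid_n)
  stopifnot(grid_n >= 32L, pixel_mm > 0,
            heart_rate_bpm > 0, resp_rate_bpm > 0)
  if (!(inspiratory_fraction > 0 && inspiratory_fraction < 1))
    stop("inspiratory_fraction must lie in (0,1)")
  if (!(contraction_factor > 0 && contraction_factor <= 1))
    stop("contraction_factor must lie in (0,1]")
  if (cycle_jitter_cv < 0) stop("cycle_jitter_cv must be >= 0")
  if (!all(lv_endo_semiaxes_mm < lv_epi_semiaxes_mm))
    stop("endocardial semi-axes must lie strictly inside epicardial ones")
  need <- c("soft", "myocardium", "cavity_contrast", "lung", "bone")
  if (!all(need %in% names(mu))) stop("mu must name tissues: ",
                                      paste(need, collapse = ", "))
  if (any(unlist(mu[need]) < 0)) stop("all attenuation coefficients must be >= 0")
  structure(list(grid_n = grid_n, pixel_mm = pixel_mm,
                 heart_rate_bpm = heart_rate_bpm,
                 resp_rate_bpm = resp_rate_bpm,
                 inspiratory_fraction = inspiratory_fraction,
                 cycle_jitter_cv = cycle_jitter_cv,
                 lv_epi_semiaxes_mm = lv_epi_semiaxes_mm,
                 lv_endo_semiaxes_mm = lv_endo_semiaxes_mm,
                 contraction_factor = contraction_factor,
                 diaphragm_amp_mm = diaphragm_amp_mm,
                 systole_phase = systole_phase,
                 mu = mu[need], seed = as.integer(seed)),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("phantom_config:", x$grid_n, "x", x$grid_n, "px @", x$pixel_mm, "mm\n")
  cat("  heart", x$heart_rate_bpm, "bpm (jitter CV", x$cycle_jitter_cv,
      "), resp", x$resp_rate_bpm, "/min (insp fraction",
      x$inspiratory_fraction, ")\n")
  cat("  ground-truth area EF:",
      round(100 * (1 - x$contraction_factor^2), 1), "%\n")
  invisible(x)
}

# Beat-length RNG recipe (documented so the truth is reproducible in any
# language): with the config seed, draw one standard-normal deviate per
# beat in order (R default Mersenne-Twister + inversion), clip it to
# [-3, 3], and set beat_len = mean * (1 + cv * z) with mean = 60/bpm s.
# cv = 0 consumes no random numbers.
beat_schedule <- function(config, t_max) {
  mean_len <- 60 / config$heart_rate_bpm
  cv <- config$cycle_jitter_cv
  n <- ceiling(t_max / (mean_len * max(1 - 3 * cv, 0.1))) + 2L
  if (cv == 0) {
    lens <- rep(mean_len, n)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(config$seed)
    z <- pmin(pmax(stats::rnorm(n), -3), 3)
    lens <- mean_len * (1 + cv * z)
  }
  list(boundaries = cumsum(c(0, lens)), lengths = lens)
}

#' Ground-truth cardiac phase
#'
#' Piecewise-linear cardiac-cycle fraction across a seeded sequence of beat
#' lengths drawn with mean `60/heart_rate_bpm` s and coefficient of
#' variation `cycle_jitter_cv` (normal deviates clipped at +/-3 sd).
#' Deterministic for a fixed seed.
#'
#' @param config a [phantom_config()]
#' @param t time(s) in seconds, vectorised
#' @return cardiac-cycle fraction(s) in \[0,1)
#' @export
cardiac_phase_truth <- function(config, t) {
  if (any(t < 0)) stop("t must be non-negative")
  sch <- beat_schedule(config, max(t))
  i <- findInterval(t, sch$boundaries, rightmost.closed = FALSE)
  frac <- (t - sch$boundaries[i]) / sch$lengths[i]
  pmin(pmax(frac, 0), 1 - 1e-12)
}

#' Ground-truth respiratory state
#'
#' The respiratory cycle (fixed period `60/resp_rate_bpm` s) is partitioned
#' so inspiration occupies `inspiratory_fraction` of each cycle, starting at
#' cycle onset. Diaphragm displacement is a raised-cosine pulse peaking at
#' mid-inspiration and exactly zero on the end-expiratory plateau.
#'
#' @inheritParams cardiac_phase_truth
#' @return list with `state` ("inspiration"/"expiration") and
#'   `displacement_mm`, each one element per time point
#' @export
resp_state_truth <- function(config, t) {
  if (any(t < 0)) stop("t must be non-negative")
  period <- 60 / config$resp_rate_bpm
  r <- (t %% period) / period
  f <- config$inspiratory_fraction
  insp <- r < f
  disp <- ifelse(insp,
                 config$diaphragm_amp_mm * 0.5 * (1 - cos(2 * pi * r / f)),
                 0)
  list(state = ifelse(insp, "inspiration", "expiration"),
       displacement_mm = disp)
}

# Contraction waveform: raised cosine, w(0)=0 at end-diastole, w=1 at
# end-systole (phase `ps`), back to 0 at the next end-diastole.
contraction_waveform <- function(phase, ps = 0.35) {
  ifelse(phase <= ps,
         0.5 * (1 - cos(pi * phase / ps)),
         0.5 * (1 + cos(pi * (phase - ps) / (1 - ps))))
}

.ellipse_mask <- function(X, Y, center, semiaxes) {
  ((X - center[1]) / semiaxes[1])^2 + ((Y - center[2]) / semiaxes[2])^2 <= 1
}

#' Render the thorax slice at a time point
#'
#' Composites background soft tissue, two lung fields clipped at the
#' (moving) diaphragm boundary, a spine disk, and a myocardial annulus
#' around the contrast-filled LV cavity whose endocardial semi-axes are
#' scaled by `s(t) = 1 - (1 - contraction_factor) * w(phase)` with `w` the
#' raised-cosine contraction waveform. Periodic in both cycles when the
#' beat jitter is zero.
#'
#' @inheritParams cardiac_phase_truth
#' @param t a single time in seconds
#' @return object of class `thorax_image`: `values` (grid_n x grid_n
#'   attenuation map, mm^-1; rows index y, columns x), `timestamp_s`,
#'   `truth_cardiac_fraction`, `truth_resp_state`, `pixel_mm`
#' @export
render_thorax <- function(config, t) {
  stopifnot(length(t) == 1L)
  an <- .anatomy
  half_fov <- config$grid_n * config$pixel_mm / 2
  if (max(abs(an$body_center) + an$body_semiaxes) > half_fov)
    stop("structures exceed grid: enlarge grid_n or pixel_mm")
  phase <- cardiac_phase_truth(config, t)
  resp <- resp_state_truth(config, t)
  s <- 1 - (1 - config$contraction_factor) *
    contraction_waveform(phase, config$systole_phase)

  n <- config$grid_n
  ax <- (seq_len(n) - (n + 1) / 2) * config$pixel_mm
  X <- matrix(ax, n, n, byrow = TRUE)   # columns index x
  Y <- matrix(ax, n, n)                 # rows index y
  v <- matrix(0, n, n)

  mu <- config$mu
  body <- .ellipse_mask(X, Y, an$body_center, an$body_semiaxes)
  v[body] <- mu$soft
  y_dia <- an$diaphragm_y0 + resp$displacement_mm
  for (lc in an$lung_centers) {
    lung <- .ellipse_mask(X, Y, lc, an$lung_semiaxes) & (Y > y_dia) & body
    v[lung] <- mu$lung
  }
  spine <- .ellipse_mask(X, Y, an$spine_center, rep(an$spine_radius, 2))
  v[spine] <- mu$bone
  epi <- .ellipse_mask(X, Y, an$heart_center, config$lv_epi_semiaxes_mm)
  v[epi] <- mu$myocardium
  endo <- .ellipse_mask(X, Y, an$heart_center, s * config$lv_endo_semiaxes_mm)
  v[endo] <- mu$cavity_contrast

  structure(list(values = v, timestamp_s = t,
                 truth_cardiac_fraction = phase,
                 truth_resp_state = resp$state,
                 pixel_mm = config$pixel_mm),
            class = "thorax_image")
}

#' Ground-truth LV cavity area
#'
#' Analytic cavity area `pi * a * b * s(phase)^2` with `(a,b)` the
#' end-diastolic endocardial semi-axes; the reference for EF recovery.
#'
#' @inheritParams cardiac_phase_truth
#' @param phase cardiac-cycle fraction(s) in \[0,1)
#' @return area in mm^2
#' @export
lv_cavity_area_truth <- function(config, phase) {
  s <- 1 - (1 - config$contraction_factor) *
    contraction_waveform(phase, config$systole_phase)
  pi * prod(config$lv_endo_semiaxes_mm) * s^2
}
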