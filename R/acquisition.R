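# Continuous-rotation acquisition of the time-varying phantom into a
# time-stamped projection stream, plus the matched parallel-beam
# forward/back projector pair reused by iterative reconstruction.
#
# Projector model: ray-driven line integrals. For each detector bin centre
# t the ray t*(cos a, sin a) + s*(-sin a, cos a) is sampled every half
# pixel; the image is bilinearly interpolated at the sample points and the
# samples summed times the step length. The exact adjoint (scattering a
# projection value along its ray with the same bilinear weights) is what
# the iterative solver uses.

#' Scan geometry
#'
#' Acquisition settings for the continuous-rotation simulator: one
#' projection per frame, frame `i` at angle `(i * 360/n_angles) mod 360`.
#' Defaults (720 projections per rotation, 200 um detector pitch) mirror a
#' small-animal CT protocol; `photon_count_I0 = 0` disables Poisson noise.
#'
#' @param n_angles_per_rotation projections per full rotation (>= 2)
#' @param detector_pixels number of detector elements
#' @param detector_pitch_mm detector element pitch, mm
#' @param frame_rate_hz frames (= projections) per second
#' @param duration_s total scan time, s
#' @param photon_count_I0 expected photons per detector element for noise;
#'   0 disables noise
#' @param seed integer seed for the photon-noise stream
#' @return an object of class `scan_geometry`
#' @export
scan_geometry <- function(n_angles_per_rotation = 720L,
                          detector_pixels = 128L,
                          detector_pitch_mm = 0.2,
                          frame_rate_hz = 40,
                          duration_s = 60,
                          photon_count_I0 = 0,
                          seed = 1L) {
  stopifnot(n_angles_per_rotation >= 2L, detector_pixels >= 2L,
            detector_pitch_mm > 0, frame_rate_hz > 0, duration_s > 0,
            photon_count_I0 >= 0)
  structure(list(n_angles_per_rotation = as.integer(n_angles_per_rotation),
                 detector_pixels = as.integer(detector_pixels),
                 detector_pitch_mm = detector_pitch_mm,
                 frame_rate_hz = frame_rate_hz,
                 duration_s = duration_s,
                 photon_count_I0 = photon_count_I0,
                 seed = as.integer(seed)),
            class = "scan_geometry")
}

# Detector-bin coordinates (in bins, 1-based centre convention) of all
# pixel centres at one view angle; used by the pixel-driven FBP
# back-projection.
.detector_coords <- function(grid_n, pixel_mm, angle_deg, geometry) {
  ax <- (seq_len(grid_n) - (grid_n + 1) / 2) * pixel_mm
  th <- angle_deg * pi / 180
  tx <- outer(ax * sin(th), ax * cos(th), "+")  # rows y, cols x
  tx / geometry$detector_pitch_mm + (geometry$detector_pixels + 1) / 2
}

# Ray sample coordinates (grid row/col units) for one view angle:
# nsteps x ndet matrices plus the step length in mm.
.ray_coords <- function(grid_n, pixel_mm, angle_deg, geometry,
                        step_px = 0.5) {
  nd <- geometry$detector_pixels
  t_mm <- (seq_len(nd) - (nd + 1) / 2) * geometry$detector_pitch_mm
  half <- grid_n * pixel_mm / sqrt(2)
  s_mm <- seq(-half, half, by = step_px * pixel_mm)
  th <- angle_deg * pi / 180
  x <- outer(-s_mm * sin(th), t_mm * cos(th), "+")
  y <- outer(s_mm * cos(th), t_mm * sin(th), "+")
  list(r = y / pixel_mm + (grid_n + 1) / 2,
       c = x / pixel_mm + (grid_n + 1) / 2,
       ds_mm = step_px * pixel_mm)
}

# Forward: line integrals (mm^-1 * mm) by bilinear gather along each ray.
.project_ray <- function(values, rc) {
  cpp_project_ray(values, rc$r, rc$c, rc$ds_mm)
}

# Exact adjoint of .project_ray: scatter each detector value along its ray.
.backproject_ray <- function(p, rc, grid_n) {
  cpp_backproject_ray(p, rc$r, rc$c, rc$ds_mm, grid_n)
}

#' Forward-project an image at one angle
#'
#' Parallel-beam line integrals (mm^-1 * mm) about the grid centre, one
#' value per detector element: the image is bilinearly interpolated every
#' half pixel along each ray and the samples are summed times the step
#' length. Projected mass `sum(projection) * detector_pitch_mm` matches
#' `sum(image) * pixel_mm^2` to quadrature accuracy whenever the object's
#' shadow stays on the detector.
#'
#' @param image a `thorax_image` or a square numeric matrix
#' @param angle_deg view angle, degrees
#' @param geometry a [scan_geometry()]
#' @param pixel_mm pixel pitch; taken from `image` when it is a
#'   `thorax_image`
#' @return numeric vector of length `detector_pixels`
#' @export
forward_project <- function(image, angle_deg, geometry, pixel_mm = NULL) {
  if (inherits(image, "thorax_image")) {
    pixel_mm <- image$pixel_mm
    image <- image$values
  }
  if (is.null(pixel_mm)) stop("pixel_mm required for a plain matrix")
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix")
  if (!all(is.finite(image))) stop("image must be finite everywhere")
  rc <- .ray_coords(nrow(image), pixel_mm, angle_deg, geometry)
  .project_ray(image, rc)
}

# Adjoint of .splat: linear interpolation of a projection at the pixels'
# detector coordinates, scaled by pixel_mm^2 / pitch. `scale = FALSE` gives
# the plain interpolated smear used by filtered back-projection.
.smear <- function(p, u, geometry, pixel_mm, scale = TRUE) {
  nd <- geometry$detector_pixels
  i0 <- floor(u)
  w1 <- i0 + 1 - u
  g0 <- ifelse(i0 >= 1 & i0 <= nd, p[pmin(pmax(i0, 1L), nd)], 0)
  g1 <- ifelse(i0 + 1 >= 1 & i0 + 1 <= nd, p[pmin(pmax(i0 + 1L, 1L), nd)], 0)
  out <- g0 * w1 + g1 * (1 - w1)
  if (scale) out <- out * pixel_mm^2 / geometry$detector_pitch_mm
  matrix(out, nrow(u), ncol(u))
}

# Poisson photon noise in the count domain, log-converted back to line
# integrals. Zero counts are floored at 0.5 before the log (standard guard).
.add_poisson_noise <- function(p, I0, seed) {
  expected <- I0 * exp(-p)
  if (min(expected) < 1)
    warning("photon starvation: expected counts < 1 on some rays")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  counts <- stats::rpois(length(p), as.vector(expected))
  counts[counts < 0.5] <- 0.5
  matrix(log(I0) - log(counts), nrow(p), ncol(p))
}

#' Simulate a continuous-rotation scan
#'
#' Renders the phantom at `t_i = i / frame_rate_hz` and projects frame `i`
#' at angle `(i * 360 / n_angles_per_rotation) mod 360`. With
#' `photon_count_I0 > 0`, detector counts are drawn
#' `Poisson(I0 * exp(-p))` and log-converted back to noisy line integrals
#' (seeded from the geometry's noise seed). Per-projection ground truth
#' (cardiac fraction, respiratory state) is carried along for validation.
#'
#' @param config a [phantom_config()]
#' @param geometry a [scan_geometry()]
#' @return object of class `projection_stream`: `projections`
#'   (n_frames x detector_pixels), `angles_deg`, `timestamps_s`, `meta`
#'   (config + geometry), `truth` (data.frame)
#' @export
simulate_scan <- function(config, geometry) {
  fov_needed <- 2 * max(abs(.anatomy$body_center) + .anatomy$body_semiaxes)
  if (geometry$detector_pixels * geometry$detector_pitch_mm < fov_needed)
    warning("detector narrower than the phantom field of view; ",
            "projected mass will be clipped")
  # Nyquist guard against the default cardiac band's upper edge (12 Hz)
  if (geometry$frame_rate_hz <= 2 * 12)
    warning("frame rate at or below twice the cardiac band upper edge; ",
            "cardiac frequencies may alias")
  n <- floor(geometry$duration_s * geometry$frame_rate_hz)
  ts <- (seq_len(n) - 1) / geometry$frame_rate_hz
  angles <- ((seq_len(n) - 1) * 360 / geometry$n_angles_per_rotation) %% 360

  P <- matrix(0, n, geometry$detector_pixels)
  frac <- numeric(n)
  state <- character(n)
  for (i in seq_len(n)) {
    im <- render_thorax(config, ts[i])
    rc <- .ray_coords(config$grid_n, config$pixel_mm, angles[i], geometry)
    P[i, ] <- .project_ray(im$values, rc)
    frac[i] <- im$truth_cardiac_fraction
    state[i] <- im$truth_resp_state
  }
  if (geometry$photon_count_I0 > 0)
    P <- .add_poisson_noise(P, geometry$photon_count_I0, geometry$seed)
  structure(list(projections = P, angles_deg = angles, timestamps_s = ts,
                 meta = list(config = config, geometry = geometry),
                 truth = data.frame(truth_cardiac_fraction = frac,
                                    truth_resp_state = state,
                                    stringsAsFactors = FALSE)),
            class = "projection_stream")
}

#' @export
print.projection_stream <- function(x, ...) {
  cat("projection_stream:", nrow(x$projections), "projections x",
      ncol(x$projections), "detector px,",
      round(max(x$timestamps_s), 2), "s\n")
  invisible(x)
}

#' Write / read a projection stream
#'
#' The projection stack goes to a 32-bit float TIFF (projections as rows)
#' and the per-projection metadata (index, angle, timestamp, optional
#' ground truth) to a CSV sidecar, which round-trips bit-exactly.
#'
#' @param stream a `projection_stream`
#' @param dir output directory (created if needed)
#' @return `write_stream` returns `dir` invisibly; `read_stream` returns a
#'   `projection_stream` (without the phantom/geometry provenance beyond
#'   what the sidecar carries).
#' @export
write_stream <- function(stream, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(stream$projections, file.path(dir, "projections.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  side <- data.frame(index = seq_len(nrow(stream$projections)) - 1L,
                     angle_deg = stream$angles_deg,
                     timestamp_s = stream$timestamps_s)
  if (!is.null(stream$truth)) side <- cbind(side, stream$truth)
  utils::write.csv(side, file.path(dir, "sidecar.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_stream
#' @export
read_stream <- function(dir) {
  P <- tiff::readTIFF(file.path(dir, "projections.tif"))
  side <- utils::read.csv(file.path(dir, "sidecar.csv"),
                          stringsAsFactors = FALSE)
  truth <- NULL
  if ("truth_cardiac_fraction" %in% names(side))
    truth <- side[, c("truth_cardiac_fraction", "truth_resp_state")]
  structure(list(projections = P, angles_deg = side$angle_deg,
                 timestamps_s = side$timestamp_s, meta = list(),
                 truth = truth),
            class = "projection_stream")
}
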