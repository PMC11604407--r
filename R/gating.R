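# Intrinsic retrospective gating: recover respiratory and cardiac surrogate
# signals from the projection stream itself (no ECG leads or breathing
# cushion), reject inspiration-phase projections, assign every retained
# projection its fraction of the cardiac cycle, and group into 12 phases.

#' Thorax template with signal ROIs
#'
#' A reference projection of the thorax together with two ROI masks in the
#' template frame: a cardiac ROI over the heart shadow (left atrium / upper
#' thoracic cavity analogue) and a respiratory ROI over the lower thoracic
#' cavity and diaphragm. ROIs must be non-empty, match the reference shape
#' and (by default) not overlap.
#'
#' @param reference numeric vector (1D detector profile) or matrix
#' @param cardiac_roi,resp_roi logical masks, same shape as `reference`
#' @param allow_overlap permit overlapping ROIs (default FALSE)
#' @return an object of class `template_model`
#' @export
template_model <- function(reference, cardiac_roi, resp_roi,
                           allow_overlap = FALSE) {
  if (!identical(dim(as.array(reference)), dim(as.array(cardiac_roi))) ||
      !identical(dim(as.array(reference)), dim(as.array(resp_roi))) ||
      length(reference) != length(cardiac_roi) ||
      length(reference) != length(resp_roi))
    stop("ROI masks must have the same shape as the reference")
  if (!any(cardiac_roi) || !any(resp_roi)) stop("ROIs must be non-empty")
  if (!allow_overlap && any(cardiac_roi & resp_roi))
    stop("ROIs overlap; set allow_overlap = TRUE to permit this")
  structure(list(reference = reference,
                 cardiac_roi = as.logical(cardiac_roi) & TRUE,
                 resp_roi = as.logical(resp_roi) & TRUE),
            class = "template_model")
}

# Shannon mutual information (nats) from an equal-width joint histogram over
# each signal's observed range.
mutual_information <- function(x, y, n_bins = 32L) {
  x <- as.vector(x); y <- as.vector(y)
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("degenerate intensity histogram")
  bx <- pmin(floor((x - min(x)) / diff(range(x)) * n_bins), n_bins - 1L)
  by <- pmin(floor((y - min(y)) / diff(range(y)) * n_bins), n_bins - 1L)
  joint <- table(factor(bx, levels = 0:(n_bins - 1)),
                 factor(by, levels = 0:(n_bins - 1))) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

.circshift <- function(x, s) {
  if (is.matrix(x)) {
    n1 <- nrow(x); n2 <- ncol(x)
    x[((seq_len(n1) - 1 - s[1]) %% n1) + 1,
      ((seq_len(n2) - 1 - s[2]) %% n2) + 1, drop = FALSE]
  } else {
    n <- length(x)
    x[((seq_len(n) - 1 - s[1]) %% n) + 1]
  }
}

#' Register the thorax template onto a projection
#'
#' Exhaustive integer-translation search maximizing mutual information
#' between the template reference and the (circularly) shifted projection,
#' computed from an equal-width joint histogram. Ties are broken by the
#' smallest Euclidean norm, then lexicographically. Works on 1D detector
#' profiles and on 2D projections.
#'
#' @param projection numeric vector or matrix
#' @param template a [template_model()] (or a bare reference array)
#' @param search_radius_px search radius, in pixels, per dimension
#' @param n_hist_bins histogram bins per axis (default 32)
#' @return integer translation (length 1 for 1D, length 2 for 2D): the
#'   shift of the projection relative to the template
#' @export
register_template <- function(projection, template, search_radius_px = 10L,
                              n_hist_bins = 32L) {
  ref <- if (inherits(template, "template_model")) template$reference
         else template
  stopifnot(search_radius_px >= 0)
  two_d <- is.matrix(ref)
  shifts <- if (two_d)
    as.matrix(expand.grid(dy = -search_radius_px:search_radius_px,
                          dx = -search_radius_px:search_radius_px))
  else matrix(-search_radius_px:search_radius_px, ncol = 1)
  mi <- apply(shifts, 1, function(s)
    mutual_information(ref, .circshift(projection, -s), n_hist_bins))
  best <- which(mi == max(mi))
  if (length(best) > 1) {
    nrm <- rowSums(shifts[best, , drop = FALSE]^2)
    best <- best[nrm == min(nrm)]
    if (length(best) > 1)
      best <- best[order(shifts[best, 1],
                         if (two_d) shifts[best, 2] else shifts[best, 1])][1]
  }
  drop(shifts[best, ])
}

#' Map a template-frame ROI into the projection frame
#'
#' Translates the mask by the registered shift and crops at the frame
#' boundary (no wrap-around). Errors if less than half of the mask
#' survives cropping.
#'
#' @param roi_mask logical vector or matrix
#' @param translation integer shift as returned by [register_template()]
#' @return logical mask of the same shape
#' @export
map_roi <- function(roi_mask, translation) {
  out <- roi_mask & FALSE
  if (is.matrix(roi_mask)) {
    n1 <- nrow(roi_mask); n2 <- ncol(roi_mask)
    src_r <- seq_len(n1) - translation[1]
    src_c <- seq_len(n2) - translation[2]
    ok_r <- src_r >= 1 & src_r <= n1; ok_c <- src_c >= 1 & src_c <= n2
    out[ok_r, ok_c] <- roi_mask[src_r[ok_r], src_c[ok_c]]
  } else {
    n <- length(roi_mask)
    src <- seq_len(n) - translation[1]
    ok <- src >= 1 & src <= n
    out[ok] <- roi_mask[src[ok]]
  }
  if (sum(out) < 0.5 * sum(roi_mask))
    stop("ROI lost more than half of its pixels at the frame boundary")
  out
}

#' Extract a gating signal by ROI intensity sums
#'
#' One value per projection: the sum of line-integral intensities inside
#' the ROI.
#'
#' @param stream a `projection_stream`
#' @param roi_mask logical mask over detector pixels
#' @return numeric series, one value per projection
#' @export
extract_signal <- function(stream, roi_mask) {
  if (!any(roi_mask)) stop("empty ROI")
  rowSums(stream$projections[, as.logical(roi_mask), drop = FALSE])
}

#' Zero-phase Butterworth band-pass
#'
#' Mean-removed, forward-backward (zero-phase) 4th-order Butterworth
#' band-pass; attenuation at least 20 dB one octave outside the band.
#'
#' @param series numeric series
#' @param fs_hz sampling rate, Hz
#' @param band_hz length-2 pass band (low, high), Hz
#' @return filtered series, same length
#' @export
bandpass <- function(series, fs_hz, band_hz) {
  stopifnot(length(band_hz) == 2, band_hz[1] > 0, band_hz[2] > band_hz[1],
            band_hz[2] < fs_hz / 2)
  bf <- signal::butter(2, band_hz / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, series - mean(series)))
}

#' Spectral frequency estimate within a band
#'
#' Linear detrend, Hann window, zero-padding to at least 4x the series
#' length, magnitude spectrum; returns the parabolic-refined location of
#' the largest peak inside the band. Errors when the series is too short
#' (< ~8 cycles at the band's low edge) or when no in-band peak rises at
#' least 3x above the median in-band magnitude.
#'
#' @inheritParams bandpass
#' @return list with `hz` and `bpm`
#' @export
estimate_frequency <- function(series, fs_hz, band_hz) {
  n <- length(series)
  if (n < 8 * fs_hz / band_hz[1])
    stop("series too short for the requested band (need ~8 cycles)")
  if (fs_hz <= 2 * band_hz[2])
    stop("sampling rate below twice the band's upper edge")
  if (stats::sd(series) < 1e-12 * (abs(mean(series)) + 1))
    stop("no periodic component detected")
  tt <- seq_len(n)
  x <- unname(stats::residuals(stats::lm(series ~ tt)))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  nfft <- 2^ceiling(log2(4 * n))
  spec <- Mod(stats::fft(c(x * w, numeric(nfft - n))))[1:(nfft / 2)]
  freqs <- (seq_len(nfft / 2) - 1) * fs_hz / nfft
  inb <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (length(inb) < 3) stop("band too narrow for the spectral grid")
  pk <- inb[which.max(spec[inb])]
  if (spec[pk] <= 0 || spec[pk] < 3 * stats::median(spec[inb]))
    stop("no periodic component detected")
  # parabolic refinement on log magnitude
  f0 <- freqs[pk]
  if (pk > 1 && pk < length(spec)) {
    a <- log(spec[pk - 1] + 1e-300); b <- log(spec[pk] + 1e-300)
    cc <- log(spec[pk + 1] + 1e-300)
    d <- (a - cc) / (2 * (a - 2 * b + cc))
    if (is.finite(d) && abs(d) <= 0.5) f0 <- f0 + d * fs_hz / nfft
  }
  list(hz = f0, bpm = f0 * 60)
}

#' Detect inspiration-phase projections
#'
#' Per-cycle adaptive rule: inside a sliding window spanning three
#' respiratory cycles (centred on each sample), samples whose filtered
#' respiratory amplitude exceeds the window's `q`-quantile are labelled
#' inspiration. Flat windows (peak-to-peak below `eps_rel` of the overall
#' signal range, a breath-hold guard) reject nothing. The quantile rule is
#' invariant to rescaling of the signal.
#'
#' @param resp_filt band-passed respiratory series
#' @param fs_hz sampling rate, Hz
#' @param resp_rate_hz previously estimated respiratory rate, Hz
#' @param q rejection quantile (default 0.70, i.e. the top 30% of samples
#'   in each window are labelled inspiration)
#' @param eps_rel flat-signal guard, relative to the overall range
#' @return logical vector: TRUE where the projection is rejected
#'   (inspiration)
#' @export
detect_inspiration <- function(resp_filt, fs_hz, resp_rate_hz, q = 0.70,
                               eps_rel = 1e-9) {
  n <- length(resp_filt)
  half <- max(1L, round(1.5 * fs_hz / resp_rate_hz))
  scale <- diff(range(resp_filt))
  rejected <- logical(n)
  if (scale == 0) return(rejected)
  for (i in seq_len(n)) {
    win <- resp_filt[max(1, i - half):min(n, i + half)]
    if (diff(range(win)) < eps_rel * scale) next
    rejected[i] <- resp_filt[i] > stats::quantile(win, q, names = FALSE)
  }
  rejected
}

# Local maxima with topographic prominence >= prom and minimum separation
# min_dist (samples). Returns sub-sample peak times (s) by parabolic
# refinement.
.find_peaks <- function(x, min_dist, prom, fs_hz) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(numeric(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk out on each side until a higher sample; prominence is peak minus
    # the higher of the two minima encountered
    lmin <- x[i]; j <- i
    while (j > 1 && x[j - 1] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
    keep[k] <- (x[i] - max(lmin, rmin)) >= prom
  }
  cand <- cand[keep]
  if (!length(cand)) return(numeric(0))
  # enforce minimum distance, keeping higher peaks first
  ord <- cand[order(x[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord)
    if (!length(sel) || all(abs(sel - i) >= min_dist)) sel <- c(sel, i)
  sel <- sort(sel)
  # parabolic sub-sample refinement
  t_pk <- vapply(sel, function(i) {
    if (i > 1 && i < n) {
      d <- (x[i - 1] - x[i + 1]) / (2 * (x[i - 1] - 2 * x[i] + x[i + 1]))
      if (!is.finite(d) || abs(d) > 0.5) d <- 0
      (i - 1 + d) / fs_hz
    } else (i - 1) / fs_hz
  }, numeric(1))
  t_pk
}

# Zero-phase FFT comb-notch: remove narrow bands around the harmonics of
# f_notch_hz (respiratory leakage in the cardiac ROI signal), skipping any
# harmonic that falls within guard_hz of a harmonic of f_keep_hz so cardiac
# content is never notched.
.comb_notch <- function(series, fs_hz, f_notch_hz, f_keep_hz,
                        width_hz = 0.15, guard_hz = 0.5) {
  n <- length(series)
  X <- stats::fft(series)
  freqs <- (seq_len(n) - 1) * fs_hz / n
  freqs <- pmin(freqs, fs_hz - freqs)          # two-sided
  for (k in seq_len(floor(fs_hz / 2 / f_notch_hz))) {
    fk <- k * f_notch_hz
    keep_harm <- round(fk / f_keep_hz)
    if (keep_harm >= 1 && abs(fk - keep_harm * f_keep_hz) < guard_hz) next
    X[abs(freqs - fk) <= width_hz] <- 0
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Re-anchor the phase origin at the maximum of the folded beat waveform.
# Beat-length jitter makes the frame clock sample each beat at different
# phases, so folding the (respiration-notched, drift-removed) raw cardiac
# signal on the assigned phase super-resolves the beat waveform beyond the
# per-beat Nyquist limit; a low-order trigonometric fit then locates the
# waveform maximum (end-diastole, when the contrast-filled cavity is
# largest) more accurately than the band-limited per-beat peaks, whose
# position is biased early on asymmetric waveforms.
.refine_phase_origin <- function(fraction, y, h_max = 4L) {
  # phase diversity: commensurate frame/beat clocks (zero jitter) populate
  # only a few phase clusters, which bounds the resolvable harmonic order
  n_u <- sum(tabulate(floor(fraction * 24) + 1L, nbins = 24L) > 0)
  H <- max(1L, min(h_max, floor((n_u - 1) / 2)))
  Xd <- do.call(cbind, lapply(seq_len(H), function(k)
    cbind(cos(2 * pi * k * fraction), sin(2 * pi * k * fraction))))
  cf <- stats::coef(stats::lm(y ~ Xd))
  cf[is.na(cf)] <- 0
  grid <- seq(0, 1, length.out = 2000)[-2000]
  Gg <- do.call(cbind, lapply(seq_len(H), function(k)
    cbind(cos(2 * pi * k * grid), sin(2 * pi * k * grid))))
  fit <- as.vector(Gg %*% cf[-1])
  grid[which.max(fit)]
}

#' Assign each projection a cardiac-cycle fraction
#'
#' Peaks are detected on the filtered cardiac signal (minimum inter-peak
#' distance `0.6 * 60/est_bpm` s, prominence at least 0.3x the signal MAD,
#' sub-sample parabolic refinement). Each sample between consecutive peaks
#' gets `fraction = (t - t_prev) / (t_next - t_prev)`, so variable beat
#' lengths are handled exactly; samples before the first (after the last)
#' peak are extrapolated with the first (last) beat length, wrapped into
#' \[0,1). The assignment is invariant to affine rescaling of the signal.
#'
#' @param cardiac_filt band-passed cardiac series
#' @param fs_hz sampling rate, Hz
#' @param est_cardiac_bpm previously estimated heart rate, beats/min
#' @return list: `fraction` in \[0,1) per sample, `peak_times_s`,
#'   `extrapolated` (logical; outside the first/last detected beat)
#' @export
assign_cardiac_phase <- function(cardiac_filt, fs_hz, est_cardiac_bpm) {
  min_dist <- 0.6 * (60 / est_cardiac_bpm) * fs_hz
  prom <- 0.3 * stats::mad(cardiac_filt)
  pk <- .find_peaks(cardiac_filt, min_dist, prom, fs_hz)
  if (length(pk) < 2) stop("cardiac signal unusable: fewer than 2 beats detected")
  t <- (seq_along(cardiac_filt) - 1) / fs_hz
  i <- findInterval(t, pk)
  frac <- numeric(length(t))
  inside <- i >= 1 & i < length(pk)
  frac[inside] <- (t[inside] - pk[i[inside]]) /
    (pk[i[inside] + 1] - pk[i[inside]])
  b1 <- pk[2] - pk[1]
  bL <- pk[length(pk)] - pk[length(pk) - 1]
  before <- i < 1; after <- i >= length(pk)
  frac[before] <- ((t[before] - pk[1]) / b1) %% 1
  frac[after] <- ((t[after] - pk[length(pk)]) / bL) %% 1
  frac <- pmin(pmax(frac, 0), 1 - 1e-12)
  list(fraction = frac, peak_times_s = pk, extrapolated = before | after)
}

#' Group cardiac-cycle fractions into equal phase bins
#'
#' Half-open bins `[k/n, (k+1)/n)`: with the default 12 bins the first
#' phase collects fractions from 0 up to 8.33% of the cycle, the second
#' 8.33%-16.67%, and so on.
#'
#' @param fraction cardiac-cycle fractions in \[0,1)
#' @param n_bins number of phases (default 12)
#' @return integer bin ids in `0:(n_bins-1)`
#' @export
bin_phases <- function(fraction, n_bins = 12L) {
  if (any(fraction < 0 | fraction >= 1))
    stop("fractions must lie in [0,1)")
  pmin(as.integer(floor(fraction * n_bins)), n_bins - 1L)
}

#' Gating parameters
#'
#' @param n_bins cardiac phase bins
#' @param cardiac_band_hz band for cardiac rate estimation (default 5-12 Hz,
#'   i.e. 300-720 bpm)
#' @param resp_band_hz band for the respiratory signal (default 0.5-4 Hz)
#' @param phase_band_hz band used to re-filter the cardiac signal before
#'   phase assignment; `NULL` (default) selects a rate-adaptive band
#'   `(0.75 f0, min(2.5 f0, 0.45 fs))` that keeps the second harmonic, so
#'   the filtered waveform peaks near true end-diastole
#' @param insp_quantile inspiration rejection quantile
#' @param search_radius_px MI registration search radius
#' @param n_hist_bins MI histogram bins
#' @return list of class `gating_params`
#' @export
gating_params <- function(n_bins = 12L, cardiac_band_hz = c(5, 12),
                          resp_band_hz = c(0.5, 4), phase_band_hz = NULL,
                          insp_quantile = 0.70, search_radius_px = 10L,
                          n_hist_bins = 32L) {
  structure(list(n_bins = as.integer(n_bins),
                 cardiac_band_hz = cardiac_band_hz,
                 resp_band_hz = resp_band_hz,
                 phase_band_hz = phase_band_hz,
                 insp_quantile = insp_quantile,
                 search_radius_px = as.integer(search_radius_px),
                 n_hist_bins = as.integer(n_hist_bins)),
            class = "gating_params")
}

#' Run the full gating pipeline on a projection stream
#'
#' Composes template registration, ROI mapping, signal extraction,
#' band-pass filtering, rate estimation, inspiration rejection, per-beat
#' phase assignment and phase binning. Deterministic for fixed inputs.
#'
#' @param stream a `projection_stream`
#' @param template a [template_model()]
#' @param params a [gating_params()]
#' @return object of class `gating_result`: per-projection `retained`,
#'   `cardiac_fraction` and `bin_id` (NA where rejected), `extrapolated`
#'   flags, summary rates (`est_cardiac_bpm`, `est_resp_rate_per_min`,
#'   `retained_fraction`, `n_per_bin`), the registered `translation`, and
#'   the extracted `signals`
#' @export
gate <- function(stream, template, params = gating_params()) {
  fs <- stream$meta$geometry$frame_rate_hz
  if (is.null(fs))
    fs <- 1 / stats::median(diff(stream$timestamps_s))
  tr <- register_template(stream$projections[1, ], template,
                          params$search_radius_px, params$n_hist_bins)
  roi_c <- map_roi(template$cardiac_roi, tr)
  roi_r <- map_roi(template$resp_roi, tr)
  cardiac_raw <- extract_signal(stream, roi_c)
  resp_raw <- extract_signal(stream, roi_r)
  cardiac_filt <- bandpass(cardiac_raw, fs, params$cardiac_band_hz)
  resp_filt <- bandpass(resp_raw, fs, params$resp_band_hz)
  est_c <- estimate_frequency(cardiac_raw, fs, params$cardiac_band_hz)
  est_r <- estimate_frequency(resp_raw, fs, params$resp_band_hz)
  rejected <- detect_inspiration(resp_filt, fs, est_r$hz,
                                 q = params$insp_quantile)
  pb <- params$phase_band_hz
  if (is.null(pb))
    pb <- c(0.75 * est_c$hz, min(2.5 * est_c$hz, 0.45 * fs))
  phase_sig <- bandpass(cardiac_raw, fs, pb)
  phase_sig <- .comb_notch(phase_sig, fs, est_r$hz, est_c$hz)
  ph <- assign_cardiac_phase(phase_sig, fs, est_c$bpm)
  # anchor phase 0 at the folded-waveform maximum (end-diastole)
  y <- cardiac_raw - mean(cardiac_raw)
  Y <- stats::fft(y)
  fr2 <- (seq_along(y) - 1) * fs / length(y)
  Y[pmin(fr2, fs - fr2) < 1] <- 0                   # drop slow drift
  y <- Re(stats::fft(Y, inverse = TRUE)) / length(y)
  y <- .comb_notch(y, fs, est_r$hz, est_c$hz)
  # low beat-length variability means the frame clock samples each beat at
  # nearly the same phases, so the fold cannot resolve high harmonics
  cv_hat <- stats::sd(diff(ph$peak_times_s)) / mean(diff(ph$peak_times_s))
  shift <- .refine_phase_origin(ph$fraction, y,
                                h_max = if (cv_hat < 0.02) 2L else 4L)
  ph$fraction <- (ph$fraction - shift) %% 1
  retained <- !rejected
  frac <- ifelse(retained, ph$fraction, NA_real_)
  bins <- rep(NA_integer_, length(frac))
  bins[retained] <- bin_phases(ph$fraction[retained], params$n_bins)
  n_per_bin <- tabulate(bins[retained] + 1L, nbins = params$n_bins)
  structure(list(retained = retained,
                 cardiac_fraction = frac,
                 bin_id = bins,
                 extrapolated = ph$extrapolated,
                 est_cardiac_bpm = est_c$bpm,
                 est_resp_rate_per_min = est_r$bpm,
                 retained_fraction = mean(retained),
                 n_bins = params$n_bins,
                 n_per_bin = n_per_bin,
                 translation = tr,
                 phase_origin_shift = shift,
                 signals = list(cardiac_raw = cardiac_raw,
                                resp_raw = resp_raw,
                                cardiac_filt = cardiac_filt,
                                resp_filt = resp_filt,
                                phase_sig = phase_sig, fs_hz = fs)),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat("gating_result:", length(x$retained), "projections;",
      sprintf("%.1f%% retained", 100 * x$retained_fraction), "\n")
  cat("  est heart rate:", round(x$est_cardiac_bpm, 1), "bpm;",
      "est resp rate:", round(x$est_resp_rate_per_min, 1), "/min\n")
  cat("  per-bin counts:", paste(x$n_per_bin, collapse = " "), "\n")
  invisible(x)
}
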