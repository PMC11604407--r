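# Cardiac-function readouts from per-phase reconstructions: LV cavity
# segmentation, EDV/ESV, ejection fraction, fractional shortening,
# segmental myocardial strain (delta-L over L0), and the severity
# stratifications used for post-infarct hearts. In 2D slice mode, volumes
# are cavity area x 1 mm unit thickness, reported in microlitres.

#' Segment the contrast-filled LV cavity
#'
#' Otsu threshold restricted to a cardiac window (the cavity is the
#' brightest compartment inside it, mirroring i.v. contrast), then the
#' largest connected component. Invariant to global intensity scaling.
#'
#' @param image a `recon_image` (or plain matrix with `pixel_mm` given)
#' @param window logical matrix marking the cardiac search window; default
#'   is the central square of half-width `grid_n/4`
#' @param pixel_mm pixel pitch, required for a plain matrix
#' @return list: `mask` (full-size logical), `volume_ul`
#'   (area x 1 mm thickness), `threshold`
#' @export
segment_lv_cavity <- function(image, window = NULL, pixel_mm = NULL) {
  if (inherits(image, "recon_image")) {
    pixel_mm <- image$pixel_mm
    vals <- image$values
  } else vals <- image
  if (is.null(pixel_mm)) stop("pixel_mm required for a plain matrix")
  n <- nrow(vals)
  if (is.null(window)) {
    window <- matrix(FALSE, n, ncol(vals))
    h <- floor(n / 4)
    c0 <- round(n / 2)
    window[(c0 - h):(c0 + h), (c0 - h):(c0 + h)] <- TRUE
  }
  wv <- vals[window]
  # the window may clip adjacent lung, which is darker than soft tissue;
  # restricting the histogram to its upper half keeps the Otsu split
  # between myocardium and contrast rather than between lung and tissue
  wv <- wv[wv >= stats::median(wv)]
  rng <- range(wv)
  if (diff(rng) <= 0) stop("cavity not found: window has no contrast")
  thr <- EBImage::otsu(matrix((wv - rng[1]) / diff(rng), ncol = 1),
                       range = c(0, 1), levels = 256)
  thr <- rng[1] + thr * diff(rng)
  bw <- matrix(0, n, ncol(vals))
  bw[window] <- as.numeric(vals[window] > thr)
  if (!any(bw > 0)) stop("cavity not found: nothing above threshold")
  lab <- EBImage::bwlabel(bw)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  list(mask = mask, volume_ul = sum(mask) * pixel_mm^2 * 1, threshold = thr)
}

#' Cardiac analysis window for a phantom configuration
#'
#' Square window centred on the phantom's heart, spanning the epicardial
#' extent plus a margin; keeps lung fields and spine out of the cavity
#' segmentation.
#'
#' @param config a [phantom_config()]
#' @param margin_mm margin beyond the epicardial semi-axes
#' @return logical `grid_n` x `grid_n` matrix
#' @export
cardiac_window <- function(config, margin_mm = 1) {
  n <- config$grid_n
  ctr <- .anatomy$heart_center
  half <- max(config$lv_epi_semiaxes_mm) + margin_mm
  px <- function(mm) mm / config$pixel_mm + (n + 1) / 2
  rows <- pmax(1, floor(px(ctr[2] - half))):pmin(n, ceiling(px(ctr[2] + half)))
  cols <- pmax(1, floor(px(ctr[1] - half))):pmin(n, ceiling(px(ctr[1] + half)))
  w <- matrix(FALSE, n, n)
  w[rows, cols] <- TRUE
  w
}

#' Ejection fraction
#'
#' `(EDV - ESV) / EDV * 100`. A negative value (ESV above EDV, as can
#' happen on noisy segmentations) is returned with a warning rather than
#' an error.
#'
#' @param edv_ul,esv_ul end-diastolic / end-systolic volumes
#' @return percent
#' @export
ejection_fraction <- function(edv_ul, esv_ul) {
  if (edv_ul <= 0) stop("EDV must be positive")
  ef <- (edv_ul - esv_ul) / edv_ul * 100
  if (ef < 0) warning("ESV exceeds EDV; negative EF returned")
  ef
}

#' Fractional shortening
#'
#' `(LVIDd - LVIDs) / LVIDd * 100` from the internal diameters.
#'
#' @param lvidd_mm,lvids_mm diastolic / systolic LV internal diameters
#' @return percent
#' @export
fractional_shortening <- function(lvidd_mm, lvids_mm) {
  if (lvidd_mm <= 0) stop("LVIDd must be positive")
  (lvidd_mm - lvids_mm) / lvidd_mm * 100
}

#' LV internal diameter from a cavity mask
#'
#' Echo-style LVID analogue: the maximum chord through the cavity centroid
#' along the minor-axis direction (the eigenvector of the smaller
#' principal-component eigenvalue of the mask).
#'
#' @param mask logical cavity mask
#' @param pixel_mm pixel pitch
#' @return diameter in mm
#' @export
lv_internal_diameter <- function(mask, pixel_mm) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty cavity mask")
  ctr <- colMeans(idx)
  if (nrow(idx) < 3) return(pixel_mm * 0)
  ev <- eigen(stats::cov(idx), symmetric = TRUE)
  v <- ev$vectors[, 2]                 # minor-axis direction
  L <- max(dim(mask))
  tt <- seq(-L, L, by = 1)
  pr <- round(ctr[1] + tt * v[1]); pc <- round(ctr[2] + tt * v[2])
  ok <- pr >= 1 & pr <= nrow(mask) & pc >= 1 & pc <= ncol(mask)
  inside <- logical(length(tt))
  inside[ok] <- mask[cbind(pr[ok], pc[ok])]
  # contiguous run through the centroid (t = 0)
  i0 <- which.min(abs(tt))
  if (!inside[i0]) stop("cavity centroid falls outside the mask")
  lo <- i0; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(tt) && inside[hi + 1]) hi <- hi + 1
  (tt[hi] - tt[lo]) * pixel_mm
}

#' Strain
#'
#' Fractional length change `(l - l0) / l0`; negative while a segment
#' shortens in systole.
#'
#' @param l0 reference (end-diastolic) length
#' @param l deformed (end-systolic) length
#' @return dimensionless strain
#' @export
strain <- function(l0, l) {
  if (any(l0 <= 0)) stop("reference length must be positive")
  (l - l0) / l0
}

# Sub-pixel closed endocardial contour of a mask via the 0.5 level set.
# Returns the longest closed loop as an (n x 2) matrix of (row, col)
# coordinates, counterclockwise, closed (first point repeated at the end).
.endo_contour <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  cl <- grDevices::contourLines(x = seq_len(n1), y = seq_len(n2),
                                z = mask * 1, levels = 0.5)
  if (!length(cl)) stop("non-closed contour: no boundary found")
  closed <- Filter(function(s) {
    abs(s$x[1] - s$x[length(s$x)]) < 1e-9 &&
      abs(s$y[1] - s$y[length(s$y)]) < 1e-9
  }, cl)
  if (!length(closed)) stop("non-closed contour: cavity touches the frame")
  lens <- vapply(closed, function(s)
    sum(sqrt(diff(s$x)^2 + diff(s$y)^2)), numeric(1))
  s <- closed[[which.max(lens)]]
  pts <- cbind(s$x, s$y)
  # ensure counterclockwise orientation (positive shoelace area)
  a <- sum(pts[-nrow(pts), 1] * pts[-1, 2] - pts[-1, 1] * pts[-nrow(pts), 2])
  if (a < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
  pts
}

# Arc-length and centroid-angle parameterization of a closed contour,
# rotated to start at the anchor (the point of maximum y = "posterior
# base"). Angles are unwrapped monotonically over one turn.
.param_contour <- function(pts) {
  pts <- pts[-nrow(pts), , drop = FALSE]       # drop duplicated closing point
  k0 <- which.max(pts[, 2])
  pts <- pts[c(k0:nrow(pts), seq_len(k0 - 1)), , drop = FALSE]
  pts <- rbind(pts, pts[1, ])
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  arc <- c(0, cumsum(seg))
  ctr <- colMeans(pts[-nrow(pts), , drop = FALSE])
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  ang <- ang - ang[1]
  dd <- diff(ang)
  dd <- (dd + pi) %% (2 * pi) - pi
  ang <- cumsum(c(0, dd))
  if (ang[length(ang)] < 0) ang <- -ang        # traverse angles increasing
  ang <- cummax(ang)   # rasterization jitter must not break monotonicity
  list(pts = pts, arc = arc, total = arc[length(arc)], angle = ang)
}

#' Segmental endocardial strain
#'
#' The end-diastolic endocardial contour is arc-length parameterized from
#' the posterior-base anchor and split into `n_segments` equal-arc
#' segments; the segment boundaries are carried onto the end-systolic
#' contour by their centroid angle, and each segment's strain is
#' `(L_es - L_ed) / L_ed`. Global strain `gls` is the mean over segments.
#' Segment names follow base-to-apex order on the posterior then anterior
#' wall.
#'
#' @param ed_mask,es_mask cavity masks at end-diastole / end-systole
#' @param n_segments number of segments (default 6)
#' @return list: `segment_strain` (named numeric), `gls`
#' @export
segmental_strain <- function(ed_mask, es_mask, n_segments = 6L) {
  ed <- .param_contour(.endo_contour(ed_mask))
  es <- .param_contour(.endo_contour(es_mask))
  bounds <- seq(0, ed$total, length.out = n_segments + 1)
  led <- diff(bounds)
  # angles at the ED segment boundaries; map onto the ES contour's
  # arc-length through its (monotone) angle parameterization
  ang_b <- stats::approx(ed$arc, ed$angle, xout = bounds, ties = "ordered")$y
  arc_es <- stats::approx(es$angle, es$arc, xout = pmin(pmax(ang_b, 0),
                                                        max(es$angle)),
                          ties = "ordered")$y
  les <- diff(arc_es)
  st <- (les - led) / led
  names(st) <- if (n_segments == 6L)
    c("posterior base", "posterior mid", "posterior apex",
      "anterior apex", "anterior mid", "anterior base")
  else paste0("segment_", seq_len(n_segments))
  list(segment_strain = st, gls = mean(st))
}

#' Heart-failure severity from ejection fraction
#'
#' Severe below 20%, moderate from 20% to 40% (boundaries inclusive),
#' mild above 40%.
#'
#' @param ef_pct ejection fraction, percent
#' @return "severe", "moderate" or "mild"
#' @export
classify_heart_failure <- function(ef_pct) {
  ifelse(ef_pct < 20, "severe", ifelse(ef_pct <= 40, "moderate", "mild"))
}

#' Fibrosis severity from scar fraction
#'
#' Severe above 40%, moderate from 20% to 40% (boundaries inclusive),
#' mild below 20%.
#'
#' @param fraction_pct fibrotic fraction of the LV surface, percent
#' @return "severe", "moderate" or "mild"
#' @export
classify_fibrosis <- function(fraction_pct) {
  ifelse(fraction_pct > 40, "severe",
         ifelse(fraction_pct >= 20, "moderate", "mild"))
}

#' Cardiac cycle and phase durations
#'
#' `cycle_length_ms(bpm) = 60000 / bpm`; a phase is `1/n_bins` of the
#' average cycle: at 400 bpm the cycle is 150 ms and each of 12 phases
#' lasts 12.5 ms.
#'
#' @param bpm heart rate, beats/min (> 0)
#' @param n_bins number of phase bins (>= 1)
#' @return duration in ms
#' @export
cycle_length_ms <- function(bpm) {
  if (any(bpm <= 0)) stop("bpm must be positive")
  60000 / bpm
}

#' @rdname cycle_length_ms
#' @export
phase_duration_ms <- function(bpm, n_bins = 12L) {
  if (any(n_bins < 1)) stop("n_bins must be >= 1")
  cycle_length_ms(bpm) / n_bins
}

#' Cardiac metrics from a per-phase reconstruction series
#'
#' Segments the LV cavity in every phase bin, takes EDV/ESV as the
#' maximum/minimum cavity volume over bins, and derives EF, LVIDd/LVIDs,
#' FS, segmental strain between the ED and ES masks, severity classes and
#' phase timing.
#'
#' @param series list with `images` (recon images per bin, in bin order),
#'   `pixel_mm`, and optionally `phase_centers`
#' @param est_bpm estimated heart rate, for the timing readouts
#' @param window optional cardiac search window passed to
#'   [segment_lv_cavity()]
#' @param fibrosis_pct optional fibrotic fraction (percent) to stratify;
#'   NA leaves the class NA
#' @return object of class `cardiac_metrics`
#' @export
compute_metrics <- function(series, est_bpm, window = NULL,
                            fibrosis_pct = NA_real_) {
  n_bins <- length(series$images)
  segs <- lapply(series$images, segment_lv_cavity, window = window)
  vols <- vapply(segs, `[[`, numeric(1), "volume_ul")
  ed <- which.max(vols); es <- which.min(vols)
  ef <- ejection_fraction(vols[ed], vols[es])
  lvidd <- lv_internal_diameter(segs[[ed]]$mask, series$pixel_mm)
  lvids <- lv_internal_diameter(segs[[es]]$mask, series$pixel_mm)
  fs <- fractional_shortening(lvidd, lvids)
  st <- segmental_strain(segs[[ed]]$mask, segs[[es]]$mask)
  structure(list(volumes_ul = vols,
                 ed_bin = ed - 1L, es_bin = es - 1L,
                 edv_ul = vols[ed], esv_ul = vols[es], ef_pct = ef,
                 lvidd_mm = lvidd, lvids_mm = lvids, fs_pct = fs,
                 segment_strain = st$segment_strain, gls = st$gls,
                 hf_class = classify_heart_failure(ef),
                 fibrosis_class = if (is.na(fibrosis_pct)) NA_character_
                                  else classify_fibrosis(fibrosis_pct),
                 cycle_ms = cycle_length_ms(est_bpm),
                 phase_duration_ms = phase_duration_ms(est_bpm, n_bins),
                 est_bpm = est_bpm, n_bins = n_bins),
            class = "cardiac_metrics")
}

#' @export
print.cardiac_metrics <- function(x, ...) {
  cat("cardiac_metrics:\n")
  cat(sprintf("  EDV %.2f uL (bin %d), ESV %.2f uL (bin %d)\n",
              x$edv_ul, x$ed_bin, x$esv_ul, x$es_bin))
  cat(sprintf("  EF %.1f%% (%s heart failure class), FS %.1f%% (LVIDd %.2f / LVIDs %.2f mm)\n",
              x$ef_pct, x$hf_class, x$fs_pct, x$lvidd_mm, x$lvids_mm))
  cat(sprintf("  GLS %.3f; cycle %.1f ms, phase %.2f ms at %.0f bpm\n",
              x$gls, x$cycle_ms, x$phase_duration_ms, x$est_bpm))
  invisible(x)
}
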