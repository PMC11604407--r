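# Shared fixtures: a coarse phantom for fast end-to-end runs, simple
# geometric test images, and small numeric utilities.

quick_phantom <- function(...) {
  phantom_config(grid_n = 64L, pixel_mm = 0.4, ...)
}

quick_geom <- function(duration_s = 2, ...) {
  scan_geometry(duration_s = duration_s, ...)
}

disk_image <- function(n, pixel_mm, radius_mm, mu = 0.02,
                       center_mm = c(0, 0)) {
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  X <- matrix(ax, n, n, byrow = TRUE)
  Y <- matrix(ax, n, n)
  ((X - center_mm[1])^2 + (Y - center_mm[2])^2 <= radius_mm^2) * mu
}

nrmse <- function(x, truth, mask = TRUE) {
  sqrt(mean((x[mask] - truth[mask])^2)) / sqrt(mean(truth[mask]^2))
}

circ_mae <- function(a, b) {
  d <- abs(a - b)
  mean(pmin(d, 1 - d), na.rm = TRUE)
}

# Independent MI implementation for brute-force registration oracles.
oracle_mi <- function(x, y, n_bins = 32L) {
  bx <- pmin(floor((x - min(x)) / (diff(range(x))) * n_bins), n_bins - 1)
  by <- pmin(floor((y - min(y)) / (diff(range(y))) * n_bins), n_bins - 1)
  j <- table(bx, by) / length(x)
  px <- rowSums(j); py <- colSums(j)
  keep <- j > 0
  sum(j[keep] * log(j[keep] / outer(px, py)[keep]))
}
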