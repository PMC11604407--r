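#!/usr/bin/env Rscript
# Reconstruct each cardiac phase bin with both methods and compare their
# image-level behaviour. Back-projection image levels depend on how many
# projections a bin happens to hold; the ordered-subset iterative solver
# does not, which is why it is the default for gated data.

suppressMessages(library(cardiogate))

seed <- 1L
cfg <- run_config(seed = seed)
stream <- simulate_scan(cfg$phantom, cfg$geometry)
tpl <- make_template(cfg, stream)
g <- gate(stream, tpl, cfg$gating)

dir.create("results/phases", showWarnings = FALSE, recursive = TRUE)
# motion-free soft-tissue reference band (lateral body wall, right of the
# lung field): image levels there should not depend on the phase bin
n <- cfg$phantom$grid_n; pm <- cfg$phantom$pixel_mm
ax <- (seq_len(n) - (n + 1) / 2) * pm
X <- matrix(ax, n, n, byrow = TRUE); Y <- matrix(ax, n, n)
ref <- X >= 9 & X <= 10.5 & abs(Y) <= 2

rows <- lapply(0:(cfg$gating$n_bins - 1L), function(b) {
  ss <- phase_subset(stream, g, b)
  os <- os_iterative_reconstruct(ss, cfg$geometry, n, pm)
  fb <- suppressWarnings(fbp_reconstruct(ss, cfg$geometry, n, pm))
  tiff::writeTIFF(os$values / max(os$values),
                  sprintf("results/phases/phase_%02d.tif", b),
                  bits.per.sample = 32L)
  data.frame(bin = b, n_projections = ss$n_projections,
             ref_os = mean(os$values[ref]), ref_fbp = mean(fb$values[ref]))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/phase_levels.csv", row.names = FALSE)
print(tab, digits = 4)
message(sprintf(
  "soft-tissue level spread across unequal-count bins: OS-SIRT %.2f%%, FBP %.2f%%",
  100 * diff(range(tab$ref_os)) / mean(tab$ref_os),
  100 * diff(range(tab$ref_fbp)) / mean(tab$ref_fbp)))
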