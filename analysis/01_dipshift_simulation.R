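#!/usr/bin/env Rscript
# Simulate DIPSHIFT dipolar dephasing curves at 5 kHz MAS across the range of
# molecular order parameters seen in the receptor, and check the
# mobile-lipid-headgroup worked example: a site with S < 0.04 barely dephases
# at all, so headgroup signals cannot bias the backbone analysis.

suppressPackageStartupMessages(library(dipshiftr))
dir.create("results", showWarnings = FALSE)

pair <- spin_pair()
scale <- decoupling_scale()
powder <- powder_scheme()
mas <- mas_condition(5000, 33)   # dense grid for smooth curve shapes

S_grid <- c(0.04, 0.17, 0.34, 0.50, 0.67, 0.85, 0.91)
curves <- lapply(S_grid, function(S) {
  dephasing_curve(effective_coupling(S, pair, scale), mas, powder,
                  label = sprintf("S=%.2f", S))
})

tab <- do.call(rbind, lapply(seq_along(S_grid), function(i) {
  data.frame(S_true = S_grid[i], t1_us = curves[[i]]$t1 * 1e6,
             intensity = curves[[i]]$intensity)
}))
write.csv(tab, "results/dephasing_curves.csv", row.names = FALSE)

depth <- data.frame(
  S_true = S_grid,
  d_eff_hz = effective_coupling(S_grid, pair, scale),
  depth_pct = vapply(curves, function(cv) 100 * dephasing_depth(cv),
                     numeric(1))
)
write.csv(depth, "results/dephasing_depth.csv", row.names = FALSE)

cat(sprintf("rigid-limit coupling: %.0f Hz (r_eff = %.3f A), kappa = %.4f\n",
            pair$d_rigid, pair$r_eff, scale$kappa))
cat(sprintf("S = 0.04 (mobile headgroup regime): max dephasing %.3f%% (< 1%%)\n",
            depth$depth_pct[1]))
cat(sprintf("S = 0.85 (rigid helix): max dephasing %.1f%%\n",
            depth$depth_pct[depth$S_true == 0.85]))
cat("wrote results/dephasing_curves.csv, results/dephasing_depth.csv\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(tab, aes(t1_us, intensity, colour = factor(S_true))) +
    geom_line() +
    labs(x = expression(t[1] ~ "(µs)"), y = "normalized intensity",
         colour = "S") +
    theme_minimal()
  ggsave("results/dephasing_curves.pdf", p, width = 6, height = 4)
}
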