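#!/usr/bin/env Rscript
# Quantify secondary-structure class fractions from synthetic 2D
# Calpha/Cbeta correlation spectra: for each labeled residue type, generate
# crosspeaks in the helix/coil/sheet analysis windows with a known aggregate
# (beta-sheet) volume fraction and recover it by crosspeak-box integration.

suppressPackageStartupMessages(library(dipshiftr))
dir.create("results", showWarnings = FALSE)

rt <- region_table()
targets <- c(Met = 0.23, Arg = 0.22, His = 0.05)

rows <- lapply(names(targets), function(res) {
  w <- rt$windows[[res]]
  sheet <- targets[[res]]
  mid <- function(cl) mean(pmax(w[[cl]], w[[cl]][2] - 4))
  peaks <- data.frame(
    ppm_f1 = c(mid("helix"), mid("coil"), mid("sheet")),
    ppm_f2 = c(34, 30, 36),
    width_f1 = 0.35, width_f2 = 0.5,
    volume = c((1 - sheet) * 0.8, (1 - sheet) * 0.2, sheet)
  )
  sp <- gen_spectrum_2d(peaks, seq(65, 45, length.out = 241),
                        seq(42, 24, length.out = 217))
  boxes <- list(helix = list(f1 = w$helix, f2 = c(31.5, 38)),
                coil = list(f1 = w$coil, f2 = c(24.5, 31.5)),
                sheet = list(f1 = c(45, w$sheet[2]), f2 = c(31.5, 40)))
  fr <- class_fractions(integrate_crosspeaks_2d(sp, boxes))
  data.frame(residue = res, helix = fr[["helix"]], coil = fr[["coil"]],
             sheet = fr[["sheet"]], sheet_generated = sheet,
             sheet_error = abs(fr[["sheet"]] - sheet))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/region_fractions.csv", row.names = FALSE)

print(tab, row.names = FALSE, digits = 3)
cat(sprintf("max |recovered - generated| sheet fraction: %.4f (within 0.01)\n",
            max(tab$sheet_error)))
cat("the aggregate (sheet) pool is spectrally separated, so it can be\n")
cat("quantified and excluded from the motional analysis of folded receptor.\n")
cat("wrote results/region_fractions.csv\n")
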