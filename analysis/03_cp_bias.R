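#!/usr/bin/env Rscript
# Demonstrate the cross-polarization dynamic bias: a heterogeneous ensemble
# of rigid helical sites and mobile termini yields an apparent ensemble order
# parameter that decreases from short CP contact time through long contact
# time to direct excitation, because short CP preferentially polarizes the
# rigid sub-population.

suppressPackageStartupMessages(library(dipshiftr))
dir.create("results", showWarnings = FALSE)

pair <- spin_pair()
scale <- decoupling_scale()
powder <- powder_scheme()
mas9 <- mas_condition(5000, 9)
sim9 <- dipshift_simulator(mas9, powder)

pops <- list(site_population(0.85, 0.5, "rigid-helix"),
             site_population(0.34, 0.5, "mobile-terminus"))
cpk <- cp_model()

conditions <- list(list(excitation = "cp", t_cp = 20e-6),
                   list(excitation = "cp", t_cp = 700e-6),
                   list(excitation = "cp", t_cp = 2000e-6),
                   list(excitation = "direct", t_cp = NULL))

fits <- lapply(conditions, function(cn) {
  cv <- gen_dephasing(pops, cn$excitation, t_cp = cn$t_cp, mas = mas9,
                      pair = pair, scale = scale, powder = powder, cp = cpk,
                      noise_sd = 0)[[1]]
  fit_dephasing(cv, pair, scale, sim = sim9, uncertainty = "curvature")
})
tab <- fit_report(fits, labels = rep("rigid+mobile ensemble", 4),
                  conditions = lapply(conditions, function(cn) {
                    list(excitation = cn$excitation, contact_time = cn$t_cp)
                  }))
write.csv(tab, "results/cp_bias.csv", row.names = FALSE)

w20 <- cp_weight(20e-6, c(0.85, 0.34), cpk)
cat(sprintf("CP weight at 20 us: rigid %.4f vs mobile %.4f (ratio %.1f)\n",
            w20[1], w20[2], w20[1] / w20[2]))
print(tab[, c("excitation", "contact_time_us", "S_fit", "sigma_S")],
      row.names = FALSE)
cat("apparent S decreases monotonically from 20 us CP to direct excitation,\n")
cat("so contact-time dependence itself reports dynamic heterogeneity.\n")
cat("wrote results/cp_bias.csv\n")
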