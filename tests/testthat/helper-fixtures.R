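# Shared fixtures: one physics setup and one precomputed simulator reused
# across test files (the simulator caches its coarse-scan curve library, so
# sharing it keeps the fitting tests fast).
fix_pair <- spin_pair()
fix_scale <- decoupling_scale()
fix_mas9 <- mas_condition(5000, 9)
fix_powder <- powder_scheme()
fix_sim9 <- dipshift_simulator(fix_mas9, fix_powder)

# the grid of order parameters reported for the three labeled residue types
# across excitation conditions
reported_S <- c(0.17, 0.34, 0.41, 0.46, 0.47, 0.50, 0.61, 0.67,
                0.80, 0.81, 0.83, 0.85, 0.87, 0.90, 0.91)

# hand-built curves for edge-case tests
new_curve_for_test <- function(t1, intensity, nu_r, ...) {
  dipshiftr:::new_dephasing_curve(t1, intensity, nu_r, ...)
}
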