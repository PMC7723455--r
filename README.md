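# dipshiftr

Solid-state NMR analysis of membrane-protein dynamics from DIPSHIFT
dipolar-dephasing experiments, for spectroscopists studying G protein-coupled
receptors and other membrane proteins reconstituted in lipid bilayers.

Magic-angle-spinning (MAS) separated-local-field experiments of the DIPSHIFT
family measure the motionally averaged ¹H–¹³C dipolar coupling of each
spectral region: the ¹³C signal is recorded as a function of a dipolar
evolution delay t₁ within one rotor period, and the depth of the resulting
dephasing curve encodes the coupling. The molecular order parameter is

  *S* = *D*exp / *D*rigid,  0 ≤ *S* ≤ 1,

the ratio of the measured coupling to its rigid-limit value — 0 for isotropic
mobility, 1 for complete rigidity. `dipshiftr` implements the full
quantitative chain around this statistic:

- **Physics** — rigid-limit point-dipole coupling
  *D* = (μ₀/8π²)·γ_I·γ_S·ħ/r³ (≈ 21.7 kHz for a one-bond C–H at
  r_eff = 1.117 Å), homonuclear-decoupling scale factor (FSLG default
  κ = 1/√3), and the order-parameter definition.
- **Simulation** — closed-form dipolar phase under MAS,
  ω(t) = 2π·d_eff·[c₁(β)cos(ω_r t + γ) + c₂(β)cos(2ω_r t + 2γ)], powder
  averaged on a deterministic sin β-weighted orientation grid; curves refocus
  exactly at the full rotor period.
- **Fitting** — least-squares comparison of observed curves against
  simulated ones over *S* ∈ [0, 1] (global scan + local refinement), with
  jackknife / Monte-Carlo / curvature uncertainties.
- **Secondary structure** — chemical-shift-region classification
  (helix / coil / β-sheet windows per residue type, Cα–Cβ secondary-shift
  classification) and 1D/2D trapezoid integration for class fractions.
- **³¹P lineshapes** — static axially symmetric CSA powder patterns and
  two-component (bilayer + isotropic) decomposition for the isotropic lipid
  fraction.
- **Synthetic data** — generators for dephasing curves of heterogeneous
  dynamic ensembles (with an explicit cross-polarization bias model),
  Gaussian-peak 1D/2D spectra and two-component ³¹P spectra, so every
  pipeline stage is testable without experimental spectra.

## Worked example

A rigid transmembrane site (S = 0.85) versus the mobile-lipid headgroup
regime (S = 0.04) at 5 kHz MAS:

```r
library(dipshiftr)

pair  <- spin_pair()          # one-bond C-H: D_rigid ~ 21677 Hz
scale <- decoupling_scale()   # FSLG: kappa = 0.5774
mas   <- mas_condition(5000, 9)

rigid <- dephasing_curve(effective_coupling(0.85, pair, scale), mas)
fit_dephasing(rigid, pair, scale)
#> <fit_result> S = 0.850 +/- 0.000 (jackknife), d_eff = 10638 Hz, rss = 8.71e-32

mobile <- dephasing_curve(effective_coupling(0.04, pair, scale),
                          mas_condition(5000, 129))
100 * dephasing_depth(mobile)
#> [1] 0.2670565
```

The rigid site dephases deeply and refits to its generating order parameter;
the S = 0.04 site loses less than 1 % of its intensity over the whole rotor
period, which is why highly mobile headgroup signals can be neglected in the
backbone analysis.

The `analysis/` directory holds the numbered workflow drivers
(`01_dipshift_simulation.R` … `05_p31_isotropic.R`): curve simulation,
order-parameter recovery, the cross-polarization contact-time bias of a
rigid + mobile ensemble, secondary-structure class fractions from synthetic
2D spectra, and ³¹P isotropic-fraction decomposition. Each writes its tables
under `results/`. `pipeline_run()` executes the same chain from a single
YAML configuration (`inst/extdata/demo_config.yaml`).

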