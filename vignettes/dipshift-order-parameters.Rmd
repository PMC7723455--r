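---
title: "Order parameters from DIPSHIFT dephasing curves: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order parameters from DIPSHIFT dephasing curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipshiftr)
```

This vignette is the package's own account of the science it implements: the
forward model of DIPSHIFT dipolar dephasing under magic-angle spinning
(MAS), the least-squares extraction of molecular order parameters, the
chemical-shift-region quantification of secondary structure, the ³¹P
powder-lineshape decomposition, and the synthetic-data model that stands in
for experimental spectra. It also records the numerical conventions and the
design choices made where the problem is genuinely open.

## The measurement model

A DIPSHIFT experiment records the integrated ¹³C intensity of a spectral
region as a function of a dipolar evolution delay $t_1$ within one rotor
period $\tau_r = 1/\nu_r$. During $t_1$ the heteronuclear ¹H–¹³C coupling
evolves while homonuclear ¹H–¹H couplings are removed by Lee–Goldburg-type
decoupling, which scales the heteronuclear coupling by a factor $\kappa$.
For a crystallite at Euler angles $(\beta, \gamma)$ relative to the rotor
axis, the instantaneous dipolar frequency under MAS is

$$\omega(t) = 2\pi d_\mathrm{eff}\left[\tfrac{\sqrt2}{2}\sin 2\beta
  \cos(\omega_r t + \gamma) - \tfrac12\sin^2\beta
  \cos(2\omega_r t + 2\gamma)\right],$$

with $\omega_r = 2\pi\nu_r$ and $d_\mathrm{eff} = \kappa\, S\,
D_\mathrm{rigid}$ the motionally and decoupling-scaled coupling. The
accumulated phase $\Phi(t_1) = \int_0^{t_1}\omega(t)\,dt$ has a closed form
(`dipolar_phase()`), and the observed curve is the powder average

$$I(t_1) = \left\langle \cos\Phi(t_1) \right\rangle_{\beta,\gamma},$$

which starts at 1 and refocuses exactly to 1 at $t_1 = \tau_r$ because
$\omega(t)$ contains only rotor harmonics. The molecular order parameter is
$S = D_\mathrm{exp}/D_\mathrm{rigid}$: 0 for isotropic mobility, 1 for
complete rigidity. The experiment is sensitive to the *amplitudes* of all
motions faster than roughly the inverse coupling (tens of microseconds); no
correlation times are extracted, and none are modeled.

Modeling assumptions worth stating explicitly:

- **Single effective I–S pair per region.** CH₂/CH₃ multiplicity and remote
  protons are folded into the effective coupling, matching a
  single-coupling fit per spectral region. Methyl three-site hopping is not
  modeled separately.
- **Ideal pulses.** Echo-based variants that suppress distortions at very
  short contact times are represented by the same ideal dephasing function.
- **No $T_2$ decay during $t_1$** and no chemical-shift evolution (refocused
  in the experiment). A multiplicative amplitude in the fit absorbs residual
  normalization error instead.

## Physics defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `r_eff` | 1.117 | Å | vibrationally averaged one-bond C–H distance; gives $D_\mathrm{rigid} \approx 21.68$ kHz |
| `d_rigid` | computed | Hz | direct override available; literature conventions span ~21.5–23.3 kHz |
| `kappa` | $1/\sqrt3 \approx 0.5774$ | — | theoretical Lee–Goldburg scale factor; experimentally calibrated values drift by a few percent |
| `nu_r` | 5000 | Hz | the MAS rate of the dephasing experiments modeled here |
| t₁ grid | 9 points, $[0, \tau_r]$ inclusive | s | 7-point variant selectable; endpoint inclusion makes refocusing an explicit sample |

The rigid-limit convention deserves emphasis: reported order parameters are
only defined relative to a chosen $D_\mathrm{rigid}$, and published studies
differ at the several-percent level. The package therefore computes the
default from `r_eff` and exposes both `r_eff` and a direct `d_rigid`
override in code and in the YAML config (`[physics]` block), rather than
hard-coding a number. All couplings are carried in Hz; the $2\pi$ enters
once, inside the phase computation.

## Powder averaging and numerical conventions

The powder average uses a deterministic $(\beta, \gamma)$ grid — default
128 β cell midpoints × 64 uniform γ values with $\sin\beta$ weights — chosen
over Monte-Carlo orientation sampling for bit-reproducibility. An optional
convergence check doubles the grid and warns when any curve point moves by
more than $10^{-4}$. At the default size, curves at experimentally relevant
couplings are converged to well below $10^{-6}$.

Two symmetry properties are worth distinguishing. The **rotor phase
origin** — a coherent shift $\gamma \to \gamma + \varphi_0$ in *both* rotor
harmonics — is an exact invariance of the γ-averaged curve, and the tests
hold it to $10^{-9}$. Replacing the cosine by a sine *independently in each
harmonic* is **not** an exact symmetry: it flips the relative phase of the
two harmonics, and a series expansion of $\langle\cos\Phi\rangle$ shows
agreement only through fourth order in the dephasing angle. The two
conventions agree to better than $10^{-4}$ for $d_\mathrm{eff} \lesssim
0.6\,\nu_r$, and the tests check exactly that regime; at stronger couplings
the difference is real (about 2 % of the intensity at
$d_\mathrm{eff}/\nu_r = 3$), so the package fixes the cosine convention and
treats the rotor-origin shift as the meaningful "convention independence".

## Fitting

`fit_dephasing()` minimizes
$\mathrm{RSS}(S) = \sum_{t_1}\left[I_\mathrm{obs}(t_1) -
A\,I_\mathrm{sim}(t_1; \kappa S D_\mathrm{rigid})\right]^2$ over
$S \in [0,1]$ by a coarse global scan (step 0.01) followed by golden-section
refinement. The global scan guards against local minima from oscillatory
curves at large $d_\mathrm{eff}/\nu_r$; because the objective compares
against the same simulation engine that generates synthetic curves,
noise-free recovery is limited only by the refinement tolerance
($\sim 10^{-6}$ in $S$). The amplitude $A$ is fitted by the closed-form
linear solution but clamped to $[0.9, 1.1]$ so it absorbs
integration/normalization error without trading against $S$; a pure shape
fit ($A \equiv 1$) is selectable. No baseline offset is fitted by default —
the experiment refocuses to full intensity — and a best fit pinned at the
$S = 1$ boundary raises a warning, since it usually indicates a
miscalibrated rigid limit rather than true rigidity.

Experimental error bars in this kind of analysis are often quoted as
standard errors without a stated resampling unit. The package refuses to
guess: `estimate_uncertainty()` implements a leave-one-out jackknife over
t₁ points (default), Monte-Carlo refitting of noise-perturbed curves, and a
curvature (quadratic-expansion) estimate, and the method label is carried
next to every reported $\sigma_S$. On synthetic data at noise sd 0.02 the
three agree within a factor of about 1.5.

## Chemical-shift regions

Secondary structure is quantified from Cα (and Cα–Cβ) chemical shifts using
per-residue analysis windows (`region_table()`): helix/coil windows and an
open-ended β-sheet cutoff for Met, Arg and His. Two conventions are fixed
deliberately:

- A shift exactly on a boundary shared by two windows belongs to the
  **higher-ppm** window (windows are matched in descending-ppm order with
  closed bounds).
- Gaps between windows — notably 53.3–54.0 ppm for Arg, whose class the
  analysis windows leave undefined — classify as `unassigned` and are never
  silently merged into a neighbor. (For Met, the operative helix window is
  55.0–59.2 ppm; the broader 53.0–59 ppm range sometimes quoted for the
  full Cα envelope is descriptive, not an analysis window.)

The Cα–Cβ route (`classify_dca_dcb()`) computes
$\Delta = \Delta\delta_{C\alpha} - \Delta\delta_{C\beta}$ against shipped
random-coil reference shifts (editable CSV, since compilations differ by a
few tenths of a ppm) with explicit thresholds of ±1.4 ppm. Integration is
plain trapezoid (1D) and double trapezoid (2D) with window endpoints added
by linear interpolation; crosspeak boxes must be pairwise disjoint to
prevent double counting.

## ³¹P lineshapes

Fluid-bilayer ³¹P spectra are modeled as axially symmetric CSA powder
patterns: $\delta(\theta) = \delta_\mathrm{iso} +
\tfrac{\Delta\sigma}{2}(3\cos^2\theta - 1)$ with $\sin\theta$ weighting,
where $\Delta\sigma = \sigma_\parallel - \sigma_\perp$ of the motionally
averaged tensor. The sign convention puts the intense perpendicular edge at
the high-field side for positive $\Delta\sigma$; the sign is a config
parameter, not a hidden constant. The lineshape is evaluated through the
exact orientation CDF on the axis bins — the $\theta = 90°$ edge singularity
is integrated analytically, not sampled — then convolved with a Lorentzian
(default, matching exponential apodization) or Gaussian kernel and
normalized to unit area.

The isotropic fraction of a two-component spectrum is estimated by a
least-squares decomposition into unit-area powder and isotropic components
(Nelder–Mead over fraction, anisotropy and widths, with the overall
amplitude solved linearly). A window-integration mode is provided as a
cross-check; it systematically overestimates small fractions because powder
intensity leaks into the isotropic window, which is why the pipeline reports
both values side by side.

## The synthetic-data model

Because no deposited experimental spectra exist for this analysis, the
generators define the study conditions explicitly:

- **Ensembles.** Sites are grouped into populations with true order
  parameters and weights; mixtures like {S = 0.85, w = 0.5 (rigid helix);
  S = 0.34, w = 0.5 (mobile)} emulate the dynamic heterogeneity of a
  receptor ensemble.
- **Cross-polarization bias.** CP efficiency is modeled as
  $w(t_{cp}, S) = e^{-t_{cp}/T_{1\rho}}\,(1 - e^{-t_{cp}S^2/T^0_{IS}})$
  with defaults $T^0_{IS} = 100$ µs and $T_{1\rho} = 5$ ms. The quadratic
  coupling dependence makes a 20 µs contact time polarize an S = 0.85 site
  about 23× (and never less than $(S_1/S_2)^2$×) more efficiently than an
  S = 0.17 site, while $T_{1\rho}$ decay penalizes long contact times. This
  is a declared phenomenological model — the experimental argument is
  qualitative — and its constants are part of the study conditions, not
  tuning knobs. Direct excitation sets $w \equiv 1$ for every site.
- **Noise.** Additive i.i.d. Gaussian noise on normalized intensities,
  default sd 0.02, the integral signal-to-noise regime of milligram
  quantities of labeled membrane protein; curves and spectra are
  deterministic under a fixed seed.
- **Spectra.** 1D/2D spectra are sums of (separable) Gaussians with
  analytically known areas/volumes, so integration round trips have exact
  targets.

What passing tests on these data do *not* show: robustness to baseline
roll, t₁-noise ridges, overlapped lipid background peaks, or lineshape
distortions from finite pulses — real-data effects deliberately outside the
generator. Synthetic results validate the estimators, not the spectrometer.

## Problem sizes and runtimes

The default test and analysis configuration uses the 128 × 64 powder grid,
9-point curves, 100 noisy replicates per order parameter for recovery
statistics, $10^3$ random draws for the phase-oracle comparison, a 96 × 48
independent orientation grid with 2001-point time integration for the
brute-force curve oracle, and $10^6$ orientation draws for the ³¹P
histogram oracle. These sizes give oracle agreements two or more orders of
magnitude below the assertion thresholds while keeping the full suite
around half a minute on one core.

## Configuration format

Run configuration, region tables and ensemble definitions are YAML
(`run_config()`, `read_region_table()`); interchange data are plain-text
TSV/CSV with `#` metadata headers (`write_curve()`, `write_spectrum_2d()`).
Exit-status conventions and vendor raw-data parsing are intentionally out of
scope: the analysis consumes region integrals, not FIDs.

## Known limitations

- One effective coupling per region: no multi-spin simulation, no explicit
  methyl dynamics, no ¹⁵N channels.
- Order parameters inherit the rigid-limit convention; comparisons across
  studies require harmonizing $D_\mathrm{rigid}$ and $\kappa$.
- The η = 0 restriction of the ³¹P simulator covers bilayer-averaged
  tensors only; rigid-lattice (η ≠ 0) patterns are not fitted.
- The CP-bias generator is phenomenological; it reproduces the direction
  and rough magnitude of contact-time bias, not spin-dynamics detail.
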