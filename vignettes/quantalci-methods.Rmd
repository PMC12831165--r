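---
title: "Models and methods in quantalci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in quantalci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalci)
```

# Scope

quantalci models how the affinity of an IL-1 family ligand for its receptor
shapes cell-level dose responses while leaving the behavior of individual
signaling complexes untouched. It provides two simulation engines — a
stochastic model of bulk complex assembly and a hybrid model of
single-complex NEMO recruitment — together with the quantification layer
used to analyze them (trajectory descriptors, sigmoid dose-response fits,
Fano-factor noise statistics, melt-curve Tm calling, bootstrap comparison,
and minimal structure utilities). Synthetic-data generators emulate the
statistical structure of live-cell imaging readouts so that every stage is
testable without external data.

# Bulk assembly model

Mature complex-I-like (CI-like) assemblies form through a three-step
reversible cascade in a well-mixed cell:

$$L + R_1 \rightleftharpoons LR_1 \rightleftharpoons LR_1R_3
  \rightleftharpoons C \rightarrow \varnothing$$

Ligand $L$ (held at a constant extracellular concentration, an excess bath)
binds receptor $R_1$; the accessory chain $R_3$ joins; the cytoplasmic
adaptor MyD88 completes the mature complex $C$; and $C$ is lost by
degradation or internalization, which removes receptor, co-receptor and
adaptor from the signaling pool. The loss step is what produces the
adaptive rise-and-return of the complex count $N(t)$: with a finite
receptor pool and no recycling, every receptor eventually transits to the
lost sink.

The simulator (`simulate_assembly()`) draws exact sample paths with the
Gillespie direct method (compiled, R RNG, so `set.seed()` governs runs).
Relative ligand affinity acts only on the primary step: the on-rate is
multiplied by `aff` and the off-rate divided by `aff`
(`effective_primary_rates()`). Everything else is held constant across
affinities.

## Parameter defaults and calibration

No published rate table exists for this cascade, so the packaged defaults
were calibrated once against the stated phenomenology and then frozen:

| parameter | default | units | role |
|---|---|---|---|
| `k1_on` | 0.05 | (ng/mL)^-1 min^-1 | primary binding (affinity-scaled) |
| `k1_off` | 0.1 | min^-1 | primary unbinding (affinity-scaled) |
| `k2_on`, `k3_on` | 0.1 | molecule^-1 min^-1 | co-receptor / adaptor capture |
| `k2_off`, `k3_off` | 0.1 | min^-1 | reverse steps |
| `k_loss` | 0.05 | min^-1 | mature-complex loss |
| `r1_total` | 500 | molecules | limiting receptor pool |
| `r3_total`, `myd88_total` | 2000 | molecules | non-limiting pools |

At `aff = 1` and a saturating dose these defaults give a peak of roughly
390 mature complexes about 6 minutes after stimulation, decaying to a
handful by 120 minutes — several hundred complexes peaking within half an
hour and adapting within one to two hours, as observed for NEMO puncta
counts. The downstream capture rates are fast relative to primary
unbinding across the affinity range of interest
(`k2_on * r3_total = 200 >> k1_off / aff` even at `aff = 0.01`), which
puts the cascade in the step-1-limited "capture" regime. In that regime a
bound receptor is almost always captured before it releases ligand, so the
dose response is governed by the primary on-flux `k1_on * aff * L` and the
EC50 scales as `1 / aff`: a 100-fold affinity change moves the EC50 by two
log decades. The acceptance suite measures 2.05 decades with five
replicates per dose.

Doses are expressed in ng/mL throughout; no molar conversion is applied.

# Single-complex (HyDeS) model

Each NEMO spot $i$ carries two ODEs — an intensity $I_i$ (a continuous
proxy for ubiquitin chain size and local NEMO activity) and a
deubiquitinase feedback $X_i$ recruited in proportion to intensity:

$$\frac{dI}{dt} = P_\mathrm{form} P_\mathrm{bound}
   \frac{K_\mathrm{growth}}{K_\mathrm{limit} + I}
   - K_\mathrm{dbasal}\, X I,
  \qquad
  \frac{dX}{dt} = K_\mathrm{xbasal} I - K_\mathrm{xdbasal} X$$

75 spots form at regular intervals (defaults: every 0.5 min over a 60 min
horizon), approximating one stimulated cell. Affinity couples to the
dynamics through one of three mechanisms:

* **bound_toggle** — $P_\mathrm{bound}$ is a two-state telegraph process.
  The unbinding rate is `k_unbind_ref / affinity`, so ligand-receptor
  contact duration is proportional to affinity. Switch times are sampled
  exactly from exponential dwell distributions; between switches the ODEs
  are integrated with fixed-step RK4 (`dt = 0.01` min), and integration
  steps never straddle a switch, so the gate is exact and the state is
  continuous. The binary-switch reading is the natural realization of
  "toggling formation on and off with binding state"; a mean-field option
  (`use_telegraph = FALSE`) replaces the gate by its stationary occupancy
  `k_bind / (k_bind + k_unbind)` for comparison.
* **growth_scale** — the gate is held at 1 and growth is scaled by the
  bounded factor `affinity / (affinity + growth_k_half)`
  (`growth_k_half = 0.1`), a monotone coupling that saturates at high
  affinity rather than growing without bound.
* **dub_suppression** — the gate is held at 1 and high affinity suppresses
  DUB activity:
  `kdbasal' = 500 * kdbasal / (500 * affinity + 1)`
  (`dub_effective_rate()`), strictly decreasing in affinity; the factor
  500 steepens the affinity dependence.

## Defaults

`k_bind = 0.5` and `k_unbind_ref = 0.05` min^-1 give bound-state
occupancies of about 0.91 at affinity 1 and 0.09 at affinity 0.01.
`kgrowth = 100`, `klimit = 50` keep growth sub-saturated (typical peak
intensities near 27, below `klimit`) while letting a spot approach its
balance intensity well inside the one-hour imaging window.
`kxbasal = kxdbasal = 0.5` min^-1 make the feedback equilibrate within a
couple of minutes, so intensity reflects the growth/degradation balance
rather than the initial transient. `kdbasal = 2e-3` sits in the window
where all three couplings express a two-decade affinity drop as a 4-fold
or larger reduction in mean per-spot AUC (the packaged-default behavior
the acceptance suite checks; measured folds are about 5.2, 5.6 and 5.6
for the three variants at 200 spots per condition). These magnitudes were
chosen once, by a coarse scan of `kdbasal` at fixed ratios of the other
rates, and frozen.

With the gate held at 1 the system has a unique positive fixed point, the
root of $K_g/(K_l+I) = (K_d K_{xb}/K_{xd}) I^2$
(`steady_state_intensity()`); the integrator reproduces it to better than
1e-4 relative error, which is the standing check on the hybrid scheme.
Spots are not removed once formed: single-spot intensity in this framework
does not fully adapt, and tracks simply run to `t_end`.

# Trajectory descriptors

`compute_descriptors()` reduces any nonnegative time course to nine
scalars: trapezoidal AUC; maximum and its time (earliest sample on ties);
maximal 3-point OLS slopes before and after the peak (rise and decay
rates; 2-point fallback when a phase has fewer than three samples);
half-maximum crossing times up and down with linear interpolation between
samples (sub-frame resolution, deterministic); their difference (FWHM);
and an adaptation time. The sliding 3-point windows overlap — the choice
between overlapping and disjoint triples is not observable from the
published descriptor definitions, and overlapping windows dominate in
practice.

"Lower plateau" has no standard definition, so adaptation time is
operationalized as: baseline = mean of the final 10% of samples; the
trajectory has adapted at the first post-peak time it drops below
baseline + 5% of (max − baseline) and stays there for 3 consecutive
samples. All three thresholds are arguments.

# Dose-response fitting and noise

Mean descriptor values per dose are fitted with two sigmoid forms:

* `fit_hill()`: $y = y_\mathrm{max} / (1 + (K_A/x)^n)$ on dose $x$; the
  experimental convention, EC50 $= K_A$. The Hill exponent is free by
  default (`fix_n = TRUE` for the one-site variant): published
  descriptions of the experimental fits are ambiguous about whether the
  exponent was fixed, and the free-exponent Hill equation is the standard
  dose-response convention; EC50 is $K_A$ either way.
* `fit_logistic()`: $y = y_\mathrm{max}/(1 + e^{-K_A (x - x_0)})$ on
  $x = \log_{10}$ dose, the form used for simulation-derived dose
  responses; EC50 $= 10^{x_0}$.

Both use bounded Levenberg-Marquardt least squares with data-driven
multi-starts (`y_max` from the response maximum, midpoint from the dose
nearest half-max, several slope starts). Non-convergence is flagged, never
silent. $R^2$ is computed on the fitted mean responses. On noiseless
forward-generated data both forms recover their generating parameters to
1e-6 relative error.

`group_fano()` computes variance/mean per group with the sample-variance
(n − 1) convention — the convention is stated here because the source
procedures do not pin it down — and excludes groups whose mean is zero or
undefined.

# Melt curves

`melt_temperature()` follows the standard thermal-shift order: min-max
normalization, quadratic Savitzky-Golay smoothing over a 15-point rolling
window, then Tm at the maximum of dF/dT. Numerical choices:

* Endpoints use the filter's own least-squares transients, which
  reproduce polynomials up to the filter order exactly at the edges
  (reflection padding does not).
* On uniform grids the derivative is estimated with a Savitzky-Golay
  first-derivative filter whose bandwidth (default 8 °C) is matched to
  the width of a typical unfolding transition. A protein unfolding step
  spreads over several degrees; slopes estimated over a comparable span
  average measurement noise without blurring the transition, whereas
  two-point differences at fine temperature resolution are
  noise-dominated. The called Tm is refined below grid resolution by the
  vertex of a quadratic fit to the derivative around its maximum.
* The derivative search is restricted to temperatures up to the global
  fluorescence maximum, so the post-transition decline of dye curves
  (dye release after full unfolding) cannot be called as a transition;
  secondary derivative peaks above a prominence threshold are reported
  for bi-phasic curves.

Against synthetic two-state curves on a 0.1 °C grid (emulating continuous
fluorescence collection during a 0.05 °C/s ramp) the pipeline recovers
generator midpoints across 40-90 °C within 0.2 °C at noise up to 3% of
the transition span.

# Resampling statistics

`bootstrap_descriptor_means()` resamples a descriptor set with replacement
(defaults: 100,000 iterations, sample size 5) — the stabilization used
when very few tracks are recovered in a condition.
`left_tailed_t_test()` tests H1: mean(a) < mean(b); Welch's
unequal-variance form is the default because group sizes are routinely
unequal and small (a pooled-variance option exists). Whether published
comparisons were run on raw descriptor sets or bootstrap distributions is
ambiguous; both pathways are exposed, with raw-set testing as the default
and the bootstrap reserved for visualization and stabilization. The
one-sided test holds its nominal 5% size on Gaussian nulls within Monte
Carlo error (1,000 repetitions). P-values are reported raw; a
Benjamini-Hochberg column is available but off by default.

# Structure utilities

`read_pdb()` (backed by bio3d) keeps the first model and blank/'A'
altlocs. `contact_residues()` marks a ligand residue as contacting a
receptor chain when any atom lies within 4.5 Å (inclusive boundary; all
deposited atoms by default, heavy-atom-only as an option — the atom
subset used by the published rule is unstated). `c_terminal_distance()`
returns the Cα-Cα distance between the highest-numbered Cα-bearing
residues of two chains and reports the residue numbers used, since
deposited structures often truncate true termini.

# Synthetic data: what it does and does not emulate

`gen_spot_count_timecourses()` produces per-cell spot-count pulses: a
gamma-like shape $(t/t_p)^a e^{-a(t/t_p - 1)}$ that peaks at exactly
`peak_time_mean` (default 30 min) and decays to 5% of peak by
`adaptation_time_mean` (default 90 min, inside the observed 60-120 min
window), with amplitude following a Hill function of dose whose midpoint
is `reference_ec50 / relative_affinity`. Cell-to-cell variability is a
unit-mean lognormal amplitude factor (CV `noise_cv`) with Poisson frame
counts; no distributional model of this variability has been published,
so this is a stand-in chosen for integer counts and tunable
variance-to-mean behavior, not inferred fact. With `noise_cv = 0` the
generator returns the deterministic mean curve itself (real-valued), the
limit used for exact EC50-recovery checks; integer-count emulation
applies to the noisy regime.

The generators do not emulate raw microscope images, photobleaching,
detection/tracking errors, or receptor heterogeneity between cells.
Passing tests therefore demonstrate correctness of the analysis chain on
data with the assumed statistical structure — not robustness to imaging
artifacts.

`gen_melt_curve()` is a two-state logistic with linear baselines,
optional post-transition decline and Gaussian noise, so Tm recovery is
analytic. `gen_toy_structure()` writes a three-chain CA-only fixture
with exactly known inter-chain gaps and terminal separations (labelled
synthetic; it stands in for deposited coordinates, which the package does
not download).

# Problem sizes

The test and acceptance workloads are sized for interactive use: 200-500
stochastic replicates for equilibrium checks, 5 replicates per dose for
EC50 scaling scans, 200 spots per condition for affinity fold-changes,
1,000 Monte Carlo repetitions for test-size calibration, and 100-300
spots for occupancy checks. At these sizes the full suite runs in well
under a minute.

# Known limitations

* The decoy receptor IL-1R2, spatial diffusion, and downstream IKK /
  NF-κB dynamics are out of scope.
* Single-spot tracks do not adapt; only the cell-level count adapts (via
  receptor-pool depletion).
* Dissociated intermediates recycle receptor (steps 1-3 are reversible)
  but lost mature complexes do not; recycling after loss is not modeled.
* Rate magnitudes are package calibrations, not measured constants;
  conclusions should rest on the scalings they implement (EC50 ∝ 1/aff in
  the capture regime; affinity-fold-changes of per-spot AUC), not on
  absolute values.
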