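# quantalci

Stochastic and hybrid models of IL-1 receptor complex assembly and
quantized NEMO recruitment.

## The problem

When IL-1β binds its receptor IL-1R1, the accessory chain IL-1R3 and the
adaptor MyD88 are recruited to form a complex-I-like (CI-like) signaling
assembly at the membrane, visible in live cells as EGFP-NEMO puncta. Ligand
orthologs from different species bind the human receptor with very
different affinities. The question this package's models address is *where*
that affinity acts: it shifts the cell-level dose response (how many
complexes form at a given dose), while the behavior of each individual
complex — its NEMO recruitment amplitude and timing — can remain
essentially affinity-invariant ("quantized" signaling). quantalci is for
systems biologists who want to simulate both layers and run the full
quantification chain on the results or on their own tabular imaging data.

## What is inside

* **Bulk assembly** (`simulate_assembly`, `scan_dose_affinity`): exact
  Gillespie (direct method, compiled) simulation of
  `L + R1 ⇌ LR1; LR1 + R3 ⇌ LR1R3; LR1R3 + MyD88 ⇌ C; C → lost`,
  with relative affinity `Aff` scaling only the primary step
  (`k1_on · Aff`, `k1_off / Aff`). In the capture regime this makes
  EC50 ∝ 1/Aff — a 100-fold affinity change shifts the EC50 by two log
  decades.
* **Single-complex HyDeS model** (`simulate_single_complexes`): per spot,
  `dI/dt = Pform·Pbound·Kgrowth/(Klimit + I) − Kdbasal·X·I` and
  `dX/dt = Kxbasal·I − Kxdbasal·X`, with affinity coupled through a
  telegraph binding gate (`bound_toggle`), a growth-rate scaling
  (`growth_scale`), or DUB suppression
  `Kdbasal′ = 500·Kdbasal/(500·affinity + 1)` (`dub_suppression`).
* **Trajectory descriptors** (`compute_descriptors`): AUC, Max, rise/decay
  rates (max 3-point OLS slope), t_max, half-max crossing times, FWHM,
  adaptation time.
* **Dose-response and noise** (`fit_hill`, `fit_logistic`, `ec50`,
  `group_fano`): Hill fits `y = yMAX/(1+(KA/x)^n)`, logistic fits in
  log10 dose `y = yMAX/(1+e^{−KA(x−x0)})`, Fano factor variance/mean.
* **Thermal shift** (`melt_temperature`): normalize, quadratic
  Savitzky-Golay (15-point window), Tm at the maximum derivative.
* **Resampling** (`bootstrap_descriptor_means`, `left_tailed_t_test`):
  100,000× bootstrap at sample size 5; Welch left-tailed t-tests.
* **Structure utilities** (`read_pdb`, `contact_residues`,
  `c_terminal_distance`): 4.5 Å residue contacts; Cα-Cα distance between
  chain C-termini.
* **Synthetic data** (`gen_spot_count_timecourses`, `gen_melt_curve`,
  `gen_toy_structure`, …): generators with known ground truth so the whole
  pipeline is testable offline.
* **Pipelines** (`run_pipeline`): seeded end-to-end recipes writing CSVs
  plus a checksummed manifest.

## Worked example

Simulate one stochastic assembly response, reduce it to descriptors, then
scan dose × affinity and fit the dose response:

```r
library(quantalci)

p <- assembly_params(ligand_conc = 3, aff = 1, seed = 1)
traj <- simulate_assembly(p)
round(unlist(compute_descriptors(trajectory(traj$time, traj$c_mature))), 2)
#>             auc             max         rate_up       rate_down
#>         9208.50          279.00           58.50           14.00
#>           t_max          t50_up        t50_down            fwhm
#>           10.00            2.52           28.90           26.38
#> adaptation_time
#>           79.00

scan <- scan_dose_affinity(assembly_params(seed = 11),
                           doses = 10^seq(-4, 3, 0.5),
                           affs = c(1, 0.01), n_reps = 5)
for (a in c(1, 0.01)) {
  sub <- scan[scan$aff == a, ]
  m <- vapply(split(sub$auc, sub$dose), mean, numeric(1))
  fit <- fit_logistic(log10(as.numeric(names(m))), unname(m))
  cat(sprintf("aff %-5g EC50 = %.4f ng/mL (r2 = %.3f)\n", a, ec50(fit), fit$r2))
}
#> aff 1     EC50 = 0.1285 ng/mL (r2 = 0.997)
#> aff 0.01  EC50 = 14.5571 ng/mL (r2 = 0.999)
```

The single cell mounts ~280 mature complexes, peaking 10 minutes after
stimulation and adapting back toward baseline by ~80 minutes. Dropping the
relative affinity 100-fold moves the fitted EC50 from 0.13 to 14.6 ng/mL —
2.05 log decades, the affinity-to-sensitivity mapping the assembly model
encodes.

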