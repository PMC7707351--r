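# igrtmine

Image-based data-mining of the dose differences that residual setup errors
leave behind after image-guided radiotherapy (IGRT), and of their relation
to survival.

## The problem

IGRT protocols for lung cancer correct patient setup only when the measured
shift exceeds an action threshold (typically 5 mm), and image only at some
fractions (daily for the first three, then weekly). The residual errors this
leaves are small and look clinically innocent — yet they rigidly displace
the delivered dose distribution relative to the anatomy. For tumours near
the heart, a residual shift towards the heart silently raises heart dose
above plan. This package implements, as reusable and tested components, the
analysis chain for detecting where such unplanned dose matters:

1. **IGRT simulation** (`igrt_protocol()`, `apply_igrt_protocol()`) —
   systematic + random per-fraction setup errors filtered by an
   action-threshold protocol with a realistic imaging schedule.
2. **Dose accumulation under shift invariance** (`accumulate_dose()`,
   `delta_dose()`) — the delivered dose is estimated as
   `D_acc(x) = (1/n) Σ_f D(x + r_f)` (trilinear interpolation), and
   `Δdose = D_acc − D_plan`, positive where more dose arrived than planned.
3. **Voxel-wise data-mining** (`permutation_test()`, `extract_region()`) —
   patients are grouped by one-year survival; at each voxel
   `t = (mean Δdose_dead − mean Δdose_alive) / SD_perm`, with the SD taken
   over label permutations; global inference by the maxT permutation
   distribution (family-wise error controlled); the reported region is the
   connected component at 80% of the peak t.
4. **Survival modelling** (`elastic_net_select()`, `fit_cox()`,
   `octile_analysis()`, `km_validation()`) — elastic-net Cox variable
   selection (mixing 0.5), unpenalized multivariable Cox fit of regional
   Δdose, octile-based dose-threshold estimation, and Kaplan–Meier
   validation of the threshold.
5. **Synthetic cohort generator** (`sim_config()`, `generate_cohort()`) —
   parametric thorax phantoms, flat-top beams with clinical penumbra,
   known patient-to-reference affine transforms, clinical covariates, and
   proportional-hazards survival driven by the accumulated dose inside a
   planted "sensitive" heart-base subregion — a known ground truth against
   which the whole chain is validated.

`run_pipeline()` chains everything from one YAML-able configuration and one
master seed; `inst/cli/igrtmine` exposes the stages as shell subcommands.

## Worked example

A 300-patient synthetic cohort with a planted Δdose effect of ln(1.25) per
Gy (active at all planned doses), mined with 300 permutations:

```r
library(igrtmine)
cfg <- pipeline_config(
  seed = 7,
  cohort = list(n_patients = 300L, grid_shape = c(48L, 48L, 36L),
                spacing = c(4, 4, 4), effect_beta_delta = log(1.25),
                dose_threshold_window = c(0, Inf)),
  ibdm = list(n_perm = 300L))
res <- run_pipeline(cfg)
print(res$mined$tstat)
#> <tstat_map> 48x48x36 lattice, 170 dead vs 127 alive, 300 permutations
#>   max t = 4.410, global p = 0.0033
print(res$mined$region)
#> <dose_region> 174 voxels at t >= 3.528 (26-connected)
dice(res$mined$region$mask, res$cohort$reference$sensitive_mask)
#> [1] 0.415
```

The t-map peaks at 4.41 with a family-wise permutation p of 0.0033; the
80%-of-peak isocontour region (174 voxels) overlaps the planted sensitive
mask with Dice 0.42 — the miner found the planted heart-base region. The
multivariable Cox model on the mined region's dose summaries recovers the
planted effect size:

```r
res$model$cox$table[res$model$cox$table$term == "delta_region", ]
#> HR per Gy delta-dose: 1.270 (1.194-1.350), p = 2.5e-14
```

(true value 1.25/Gy). With the effect active everywhere, the octile analysis
correctly finds Δdose significant across the dose range and returns the
bottom of the range as its "threshold"; gating the effect to a 16–24 Gy
window (`dose_threshold_window = c(16, 24)`, the generator default) moves
the estimate to that window — that experiment is run by the acceptance
script below.

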