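# plaquet2

Quantification of the lipid-rich necrotic core (LRNC) in carotid
atherosclerotic plaque from quantitative T2 mapping — an R implementation
of the full analysis chain used to validate T2-based lipid quantification
against endarterectomy histology, plus a synthetic phantom/cohort
generator that makes every stage verifiable without patient data.

The package is for imaging scientists and methodologists working on
plaque characterization: it provides the voxel-wise relaxometry, the
dual-threshold segmentation, the histology calibration machinery, and the
clinical statistics battery as reusable, tested functions.

## The method

A multi-echo spin-echo acquisition yields images at echo times
$\mathrm{TE}_1 < \dots < \mathrm{TE}_{14}$ (9–127 ms). Each voxel is fitted
with the monoexponential decay

$$S(\mathrm{TE}) = S_0\,e^{-\mathrm{TE}/T_2},$$

by nonlinear least squares (log-linear initialization, vectorized
Levenberg–Marquardt refinement), giving a T2 map of the vessel wall inside
a lumen/outer-wall ROI. Wall voxels are then classified with two
thresholds: $T_2 < T_{2L}$ is lipid core, $T_2 > T_{2H}$ is recent
intraplaque haemorrhage (IPH, which occurs inside the core and has the
longest T2 of all components); their union is the LRNC. The pair
$(T_{2L}, T_{2H})$ is calibrated by exhaustive grid search
($T_{2L} \in [30,50]$, $T_{2H} \in [70,120]$ ms, 1-ms steps) maximizing the
Pearson correlation of per-slice lipid area (%) with histology, with
leave-one-out cross-validation reported alongside the in-sample maximum.
Downstream statistics: Bland–Altman agreement, group t tests and relative
differences, the ≥25% large-core chi-square, ROC with Youden-optimal
cutoff, scan-rescan ICC (two-way random, absolute agreement) and
within-subject CoV, and modified AHA plaque typing scored by Cohen's
kappa.

## Worked example

Run the complete synthetic study at its default conditions (64×64 phantom
slices; 15 symptomatic and 11 asymptomatic plaques; ~60 matched slices):

```r
library(plaquet2)
study <- run_synthetic_study(study_config(), seed = 1)
print(study)
```

```
Synthetic carotid T2-mapping study
  26 plaques retained (quality >= 3; 0 excluded), 61 slices
  calibrated thresholds: T2L = 43 ms, T2H = 89 ms
  slice R = 0.989 (LOOCV 0.988), RMSE = 2.3%; plaque R = 0.994
  groups: 35.4% vs 17.4% lipid (p = 1.49e-06), AUC = 0.96
  scan-rescan: ICC = 0.89 (0.10-0.98), CoV = 8.0%
  AHA agreement: 100.0%, kappa = 1.00
```

Reading the output: the calibration recovered thresholds within one grid
step of the generating pair (42, 90 ms); the slice-level correlation with
the emulated histology and its leave-one-out estimate agree closely; the
symptomatic group carries roughly twice the lipid fraction of the
asymptomatic group (the relative difference is reported in
`study$stats$groups`); and nine scan-rescan replicate pairs give an
intraclass correlation of 0.89. Synthetic agreement numbers run higher
than those achievable against real histology — the methods vignette
(`vignettes/t2-mapping-methods.Rmd`) explains the generator's noise model
and that trade-off, along with every tunable parameter.

Individual stages are ordinary functions returning classed objects:

```r
cfg    <- phantom_config()
tissue <- make_tissue_map(cfg, lipid_fraction = 25, iph_fraction = 5, seed = 7)
series <- simulate_echo_series(tissue, cfg, seed = 7)
map    <- fit_slice(series, wall_roi_from_tissue(tissue))   # "t2map" object
print(map); plot(map)

cls <- classify_voxels(map, wall_roi_from_tissue(tissue), threshold_pair(42, 90))
measure_slice(cls, wall_roi_from_tissue(tissue))
```

A thin command-line front end with `simulate`, `fit`, `segment`,
`calibrate`, `stats`, `aha` and `run-all` subcommands lives at
`inst/cli/plaquet2.R`; it reads/writes NIfTI volumes with JSON sidecars
and CSV tables.

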