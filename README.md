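# halfield

Simulation and analysis of **half-field irradiation migration experiments**:
time-lapse single-cell tracking on a 60 mm dish that was half-shielded with
lead during X-ray exposure, so that directly irradiated (*In-field*) and
shielded bystander (*Out-of-field*) cells share one dish, alongside
sham-irradiated (*Control*) and fully irradiated (*Uniform*) dishes. The
package targets researchers studying radiation-induced non-targeted
(bystander) effects on cell motility, and anyone who needs a calibrated,
fully reproducible synthetic testbed for single-cell tracking statistics.

## What it computes

* **Synthetic cohorts** — per-cell speeds $s_i$ drawn from a lognormal law
  with cohort median $m$ and log-scale
  $\sigma = \log(q_3/q_1) / (2\,\Phi^{-1}(0.75))$ fitted to a published
  interquartile range; 2-D walks at 15-min frames over 24 h (97 frames)
  with uniform step directions, optional directional persistence, and
  either fixed ($s_i\,\Delta t$) or Rayleigh step lengths. Shipped presets
  calibrate all four groups of both experiment series (with and without
  cisplatin pre-treatment), plus FUCCI cell-cycle state distributions
  including the 70.3% G2-arrest preset.
* **Dish geometry** — half-field classification (`IN_FIELD`,
  `OUT_OF_FIELD`, the 20 mm `EXCLUDED` band over the penumbra,
  `OUTSIDE_DISH`), a sigmoidal penumbral dose profile, and the closed-form
  analyzable area fraction.
* **Tracking** — label-movie rendering (16-bit multi-page TIFF), centroid
  detection, greedy nearest-neighbour linking with a hard distance gate,
  and the published trajectory-inclusion filters with machine-readable
  rejection reasons.
* **Migration metrics** — per-cell velocity (µm/h), total path length, net
  displacement, and the ensemble mean squared displacement
  $\mathrm{MSD}(t) = N^{-1}\sum_i \lVert x_i(t)-x_i(0)\rVert^2$ with an
  OLS linear fit and $R^2$ as the random-walk linearity measure.
* **Group statistics** — Steel's many-to-one rank test (standardized
  pairwise rank statistics, product-correlation multivariate-normal
  familywise adjustment evaluated by exact 1-D quadrature, plus an
  exhaustive/sampled permutation mode), Pearson chi-square for FUCCI state
  distributions, and median (IQR) summaries.

See `vignettes/half-field-migration.Rmd` for the models, assumptions and
numerical choices.

## Worked example

```r
library(halfield)

cfg <- experiment_preset("xray", n_cells_per_group = 300, seed = 11)
rec <- run_experiment(cfg, out_dir = "demo_out")

rec$results$summaries$velocity_umph
#> # A tibble: 4 × 5
#>   group            n median    q1    q3
#> 1 Control        300   6.17  3.72 11.5
#> 2 Uniform        300   5.25  3.16  8.39
#> 3 In-field       300   5.56  3.30  9.18
#> 4 Out-of-field   300   4.87  2.43  8.50

for (cmp in rec$results$steel$velocity_umph)
  cat(sprintf("%-13s z = %6.2f  p_adj = %.4g\n", cmp$group, cmp$z, cmp$p_adjusted))
#> Uniform       z =  -2.97  p_adj = 0.008395
#> In-field      z =  -1.97  p_adj = 0.1225
#> Out-of-field  z =  -4.10  p_adj = 0.0001204
```

The cohort medians track each group's calibrated speed law, and the
familywise-adjusted comparisons show the bystander-suppression pattern of
the X-ray-only series: Uniform and Out-of-field cells migrate
significantly slower than Control while the In-field difference is not
significant. `demo_out/` receives the full stage outputs: kept/rejected
track CSVs, per-cell `metrics.csv`, `msd.csv` with per-group fit
summaries, `stats.json`, `qc.json` (region counts, analyzable fraction
0.584 at the default geometry) and a `run_record.json` whose digests are
identical across reruns with the same config and seed.

A thin CLI wraps the same functions:

```sh
exec/halfield run --config inst/extdata/presets/xray.yaml --out-dir out
exec/halfield track --labels movie.tif --pixel-size 1.3 --max-step 30 --out tracks.csv
```

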