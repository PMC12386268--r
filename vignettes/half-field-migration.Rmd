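---
title: "Models and methods: half-field irradiation migration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: half-field irradiation migration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfield)
```

## The experiment this package models

In a half-field irradiation experiment, cells are seeded across a 60 mm
culture dish and one half of the dish is covered with a lead block during
X-ray exposure (2 Gy here). Cells under the block receive essentially no
primary dose but share medium — and therefore secreted signals — with the
directly irradiated half. Comparing four populations (sham-irradiated
*Control* dishes, fully irradiated *Uniform* dishes, and the *In-field* and
*Out-of-field* halves of half-shielded dishes) separates direct radiation
effects on cell motility from bystander effects transmitted to unirradiated
neighbours. A second series adds a cisplatin pre-treatment (5 µM for 1 h,
then 14 h of drug-free incubation before exposure), which arrests roughly
70% of the FUCCI-reporter cells in G2 (green nuclear fluorescence).

Each dish is imaged by time-lapse microscopy every 15 minutes for 24 hours;
single cells are segmented and tracked, and per-cell migration statistics
are compared across groups. The raw movies behind the published cohort
statistics are not deposited anywhere, so this package rebuilds the entire
analysis chain on *synthetic* data whose distributional structure is
calibrated to the published per-group summaries. That supports two uses:
validating every stage of the analysis against known ground truth, and
asking whether the published group differences are recoverable by the
published analysis under a fully specified generative model.

## The generative model

### Per-cell speed heterogeneity

Migration speed varies far more between cells than within one cell's
track, and published cohort velocity distributions are strongly
right-skewed (the upper quartile sits much further from the median than the
lower). We therefore model the per-cell speed $s_i$ (µm/h) as lognormal,
the simplest positive, right-skewed two-parameter family:

$$\log s_i \sim \mathcal{N}(\log m,\ \sigma^2),$$

where $m$ is the cohort median. The log-scale $\sigma$ is fitted from the
published interquartile range: a lognormal's quartiles are
$m\,e^{\mp z_{75}\sigma}$ with $z_{75} = \Phi^{-1}(0.75) \approx 0.6745$,
and least squares over the two log-ratios $\log(q_1/m)$, $\log(q_3/m)$
gives the closed form

$$\hat\sigma = \frac{\log(q_3/q_1)}{2\,z_{75}}.$$

`lognormal_sigma_from_iqr()` implements this; `speed_preset()` exposes the
eight calibrated group presets (four groups × two series). The fit is
exact when the printed quartiles are log-symmetric about the median; for
the shipped presets the implied quartiles land within a few percent of the
printed ones (checked in the test suite).

### The walk

Each cell takes one step per frame. Step **direction** is uniform on the
circle, optionally blended with the previous direction:
$d_t \propto p\,d_{t-1} + (1-p)\,u_t$ with persistence $p \in [0,1)$ and
$u_t$ a fresh uniform unit vector; $p = 0$ is a pure random walk, which is
what the calibrated presets use (the published ensemble MSD curves are
linear, and net displacement shows no directional bias). Step **length**
follows one of two laws:

* `fixed` (default): length exactly $s_i \Delta t$. This makes the
  path-length velocity estimator recover $s_i$ without bias or noise, so
  calibration recovery is exact in expectation — the cohort median of
  estimated velocities converges to the preset median.
* `gaussian`: Rayleigh-distributed length with mean $s_i \Delta t$, which
  at $p = 0$ is exactly an isotropic bivariate Gaussian step. This is the
  textbook diffusive walk; with per-axis step SD $\sigma_a$ the ensemble
  MSD is $2\sigma_a^2 k$ at lag $k$ frames and the fitted slope estimates
  $4D$ with $D = \sigma_a^2 / (2\Delta t)$.

Frames: "15-minute intervals for 24 h" is realised as 97 frames — 96
intervals with both endpoints included. Start positions are uniform over
the group's analyzable sub-region (whole dish for Control/Uniform; the
respective half outside the exclusion band for In-field/Out-of-field), at
least one cell radius from region edges so that no trajectory is lost to
an immediate boundary exit.

Reproducibility: one master seed; every replicate of every group draws
from its own stream whose seed is derived deterministically from the
master seed and the (group, replicate) key (`derive_seed()`), so identical
configurations reproduce byte-identical trajectory tables regardless of
evaluation order.

### What the generator does not emulate

Cell division, death, and contact interactions are not simulated; there is
no explicit diffusing bystander-signal field (group speed effects are
imposed directly through the calibrated speed laws); rendered label movies
are flat disks, not realistic brightfield or fluorescence textures; and
within-cell speed fluctuations beyond the step law are absent. Passing
tests therefore demonstrate that the *analysis chain* is correct and that
the published group differences are *consistent* with a heterogeneous
random-walk model — they do not validate segmentation performance on real
images, nor any mechanistic account of how bystander signals alter speed.

## Dish geometry and dose model

Coordinates are in mm with the origin at the dish centre; the shield edge
is the vertical line $x = b$ (default $b = 0$) and the irradiated half is
$x < b$. The published "20 mm exclusion region" around the boundary is
read as a band of total width 20 mm (half-width 10 mm); the caption
wording does not rule out 20 mm per side, so the half-width is a
configuration parameter. Cells are classified at their first frame —
24-hour path lengths are of order 100 µm, two orders of magnitude below
the 10 mm band half-width, so later boundary crossings by analyzable cells
are negligible.

The dose falloff at the field edge (penumbra) is modelled as a normal-CDF
sigmoid, $\mathrm{dose}(x) = D_0\,\Phi\!\big((b - x)/\varsigma\big)$: full
dose deep in the open half, $D_0/2$ exactly at the shield edge, monotone
non-increasing in $x$. No numeric penumbra profile is published, so the
width $\varsigma$ defaults to 1 mm and is freely configurable; dose is
carried as metadata and does not influence the generator. Dose from
scattered secondary electrons is deliberately out of scope.
`analyzable_fraction()` gives the closed-form fraction of dish area
outside the band (0.584 at the defaults) for QC reporting.

## Tracking

Real pipelines use learned segmentation plus sophisticated linkers; both
are out of scope here. The package's tracking stage is deliberately
minimal and auditable:

* `detect_centroids()`: one centroid per nonzero label, the unweighted
  mean of member pixel centres (0-based indices), scaled to µm.
* `link_trajectories()`: greedy nearest-neighbour linking per frame pair
  in ascending distance order, with a hard gate `max_step` (default 30 µm
  per 15-min frame ≈ 120 µm/h, roughly ten times the calibrated median
  speed). No gap closing and no division handling: a label that vanishes
  ends its track, and any successor starts a new track that the
  completeness filter removes. Greedy linking is exact on well-separated
  fixtures; the test suite bounds its failure modes against a brute-force
  minimum-cost matching oracle on small instances.

Trajectory inclusion mirrors the published rules: only complete tracks
(all frames, no gaps) that never leave the dish are analysed, and on
half-field dishes cells starting inside the exclusion band are dropped.
Rejections carry machine-readable reasons (`INCOMPLETE`, `EXITED_FIELD`,
`EXCLUDED_REGION`, plus `NONVIABLE` for tracks whose total motion is below
a floor of 0.1 µm — a proxy for dead cells; set the floor to zero to
disable it).

## Migration statistics

For a track $x_i(t)$ sampled at uniform $\Delta t$:

* **total distance** — sum of Euclidean step lengths (µm);
* **net displacement** — $\lVert x_i(T) - x_i(0)\rVert$ (µm), always
  $\le$ total distance;
* **velocity** — total distance / elapsed time (µm/h). A per-step-speed
  average is also exposed; the two are algebraically identical at uniform
  $\Delta t$, and both are provided because published velocity definitions
  rarely state the estimator.

The **ensemble MSD** at lag $t = k\Delta t$ is the ensemble mean of the
squared displacement from the initial position,

$$\mathrm{MSD}(t) = \frac{1}{N}\sum_{i=1}^{N}\lVert x_i(t) - x_i(0)\rVert^2,$$

computed over complete tracks only (every lag averages the same $N$
cells). This is the ensemble form, not the time-averaged form — the two
coincide in expectation for increment-stationary processes but differ as
estimators; the time-averaged variant is deliberately not implemented. An
ordinary least-squares line over all $K$ lags with a **free intercept**
summarises the curve; the intercept is left free because localisation
noise adds a positive offset at short lags, and $R^2$ of this fit is the
linearity measure. All lags enter with equal weight (the published fits
show no truncation), even though neighbouring MSD ordinates are strongly
correlated — $R^2$ here is a descriptive index, not a formal test.
`classify_motion()` labels a curve `RANDOM_WALK_CONSISTENT` when
$R^2 \ge 0.99$ (configurable), and always reports the underlying $R^2$
alongside the label.

## Steel's many-to-one test

Each treatment $g$ is compared with the shared control by a Wilcoxon
rank-sum statistic $W_g$ over the *pairwise* joint ranking (mid-ranks for
ties), standardized as

$$z_g = \frac{W_g - n_g(N_g+1)/2}{\sqrt{\tfrac{n_0 n_g}{12}\big(N_g + 1 - T\big)}},
\qquad N_g = n_0 + n_g,$$

with the usual tie correction $T = \sum(t^3 - t)/\{N_g(N_g-1)\}$ and a 0.5
continuity correction on the rank-sum scale. Under the global null the
$z_g$ are asymptotically jointly normal with correlation
$\rho_{gh} = \gamma_g\gamma_h$, $\gamma_g = \sqrt{n_g/(n_g+n_0)}$ (the
classic 1/2 at equal sizes), because all statistics share the control
ranks. The familywise-adjusted two-sided p-value is

$$p_g = P\!\big(\max_j |Z_j| \ge |z_g|\big).$$

Because the correlation has the product form, the max-|Z| tail reduces
exactly to a one-dimensional integral over the shared control factor
($Z_j = \gamma_j X_0 + \sqrt{1-\gamma_j^2}\,\varepsilon_j$), which the
package evaluates by deterministic adaptive quadrature (relative tolerance
1e-10; the `mc_error` field reports the integration error bound, which is
orders of magnitude below any decision threshold). The test suite verifies
this quadrature against an independent multivariate-normal integrator.

A **permutation mode** replaces the normal limit entirely: pooled group
labels are relabelled — exhaustively when the number of distinct
arrangements is manageable (34,650 at 4+4+4), otherwise by sampled
permutations (capped at $10^6$) — and $p_g$ is the fraction of
arrangements whose max-|z| reaches $|z_g|$, hence an exact multiple of one
over the number of arrangements.

Numerical choices worth recording:

* **Sidedness** — two-sided, because the two experiment series show
  effects in opposite directions (suppression without cisplatin,
  enhancement with it).
* **Continuity correction** — at 4 cells per group the exact permutation
  distribution of max-|z| is coarsely discrete; the 0.5 correction reduces
  the mean |p-discrepancy| between the normal approximation and exhaustive
  permutation from ≈0.08 to ≈0.015, and is negligible ($z$ shift < 0.01)
  at the study's ≥31 cells per group. Even so, no continuous approximation
  can track the discrete null *uniformly* at n = 4: its central atoms
  carry probability ≈0.2, so mid-distribution discrepancies up to a few
  hundredths are intrinsic. In the decision-relevant tail (exact
  p ≤ 0.3) agreement is within 0.02, which is what the test suite asserts.
* **Pooling** — replicates are pooled into one sample per group before
  testing, mirroring how published per-group cohorts (>30 cells over ≥3
  replicates) are formed; the replicate id is retained in all outputs for
  sensitivity analyses.
* **Ties** — mid-ranks with the tie-corrected variance; a completely tied
  pair returns $z = 0$, $p = 1$ rather than an error.
* $\alpha = 0.05$ throughout, as in the source analysis.

FUCCI state distributions are compared across conditions with the plain
Pearson chi-square test of homogeneity (no continuity correction),
cross-checked in the tests against `stats::chisq.test(correct = FALSE)`.
Group summaries report median and quartiles by the inclusive
linear-interpolation convention (`quantile` type 7).

## FUCCI state model

States are i.i.d. draws over (red = G1, yellow = early S, green = S/G2/M).
The cisplatin preset uses the published arrest fraction, green = 0.703.
The published figure gives no numeric values for the untreated
distribution or for the non-green split after cisplatin, so the package
chooses once: untreated (0.55, 0.12, 0.33), a typical asynchronous
profile for this reporter line, and cisplatin (0.197, 0.100, 0.703). These
choices affect only the chi-square demonstration, not the migration
analysis.

## Cohort sizes used by the shipped checks

The test suite states each check's problem size explicitly; the main ones,
chosen as the package's own trade-off between resolution and determinism:

* Calibration recovery: n = 1000 cells per preset, tolerance three
  standard errors of a lognormal sample median
  ($\mathrm{SE} = 1/\{2 f(m)\sqrt{n}\}$ with $f$ the known preset
  density).
* Diffusive-MSD law: 10,000 cells × 24 lags, 2% per lag.
* Familywise error: 2000 null replicates of four groups × 31 cells.
* End-to-end pattern reproduction: the calibrated effect sizes are small —
  the largest, Control vs Out-of-field without cisplatin, corresponds to
  $P(X_{\text{trt}} < X_{\text{ctl}}) \approx 0.574$, and the smallest
  that must reach significance (cisplatin In-field vs Control) to ≈0.514.
  A prospective power calculation from these AUCs
  ($z \approx (\mathrm{AUC}-0.5)\sqrt{6n}$ at equal sizes) sets cohort
  sizes with >95% familywise power for the expected pattern: 1500
  cells/group for the X-ray-only series (large enough to flag Uniform and
  Out-of-field, small enough that the slight In-field difference stays
  non-significant, as published) and 16,000 cells/group for the cisplatin
  series. At the published scale of ~10²–10³ cells per group the
  cisplatin In-field effect is too small for reliable familywise
  significance under this generative model — worth knowing when comparing
  against the published p = 0.002.

## Known limitations

* The lognormal speed law is calibrated to three quantiles; real cohorts
  may have heavier tails, which would widen rank-test power but not change
  medians.
* Greedy linking is only exact on well-separated cells; it is a validation
  fixture, not a competitor to production trackers.
* The MSD $R^2$ criterion is descriptive; with correlated lag estimates it
  is not a calibrated hypothesis test of diffusivity.
* First-frame region classification ignores the (negligible at defaults,
  but configurable) possibility of exclusion-band crossings during the
  movie.
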