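---
title: "Methods: Bliss synergy screening, dose-response, foci imaging, and in-vivo endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bliss synergy screening, dose-response, foci imaging, and in-vivo endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synletscreen)
```

This vignette is the package's account of its models and the choices behind
them: what is computed, under which assumptions, with which defaults, and
what the synthetic-data generators do and do not emulate.

## 1. Screen data model and normalization

A combination screen arrives as a long table of wells: one row per
(cell line, compound A dose, compound B dose, replicate). The canonical
design is a 6×6 grid per condition — a vehicle corner, five single-agent
doses along each edge, and 25 combination cells.

Raw luminescence is normalized per (cell line, compound pair, replicate)
group by the **arithmetic mean of that group's vehicle wells**, so vehicle
averages to 1. Two deliberate choices:

- values above 1 (apparent growth stimulation) are *retained* at the
  normalization stage; whether they influence synergy is decided later by
  the effect clipping flag;
- the grouping is per condition and replicate rather than per physical
  plate, because plate identity is usually not exported with the well
  table. If plate-level controls are available, normalize upstream and load
  the table as `value_kind = "normalized"`.

Inhibition effects are `effect = 1 - viability`. With `clip = TRUE`
(default) effects are bounded to [0, 1]: the Bliss rule composes effects as
probabilities, and negative or super-unity "probabilities" would leak
through every downstream formula. The unclipped variant
(`effect + viability = 1` exactly) remains available for diagnostics.

## 2. Bliss independence and the synergy score

For single-agent effects $a$ and $b$, Bliss independence expects
$a + b - ab$ from a non-interacting combination. Per cell,

$$\Delta\alpha_{ij} = \alpha_{ij}^{obs} - \bigl(\alpha_i^A + \alpha_j^B - \alpha_i^A \alpha_j^B\bigr),$$

with $\alpha_i^A$, $\alpha_j^B$ taken from the matrix's **own edge row and
column** — not from refitted single-agent curves — so each matrix is
self-contained and the edge cells vanish identically when the vehicle
effect is 0.

The scalar score is $100 \times \text{mean}(\Delta\alpha)$ over an
aggregation domain:

- `combinations_only` (default): the 25 cells with both doses positive.
  Edge deltas are identically zero by construction, so including them only
  shrinks every score by the constant factor 25/36 and blurs the >15
  threshold's meaning. This default is the package's reading of "over the
  full dose-response matrix" phrasing common in screen reports; the
  `full_matrix` flag exposes the literal alternative.
- classification is **strictly** greater than 15 points.

Replicates are scored individually and then summarized as mean ± sample SD
(n−1); a single replicate reports an absent SD. Scoring replicates first
(rather than averaging viabilities and scoring once) matches how replicate
synergy values are quoted as mean ± SD, and keeps the SD interpretable as
between-replicate spread of the actual statistic.

## 3. Genotype-differential ranking

Each library compound is summarized per cell line, averaged (unweighted)
within genotype, and ranked by

$$\text{difference} = \overline{\text{score}}_{deficient} - \overline{\text{score}}_{proficient},$$

descending; ties break by the deficient mean, then compound name. The
unweighted mean reflects the symmetric two-lines-per-genotype design; no
weighting scheme is implied by such a panel. A **hit** is a top-difference
compound whose deficient mean exceeds 15 — the ranking and the synergy
threshold applied jointly. No significance test is attached: with two cell
lines per genotype the difference is a ranking statistic, not an inferential
one. Incomplete conditions are skipped with a warning and surfaced in a QC
table, never silently dropped.

## 4. Dose-response fitting and the IC50 estimand

Single-agent curves use the four-parameter logistic on log-concentration,

$$v(c) = \text{bottom} + \frac{\text{top} - \text{bottom}}{1 + (c/m)^{h}},$$

fitted by bounded least squares (Levenberg–Marquardt via minpack.lm, with a
bounded BFGS pass as a safety net for the occasional singular Jacobian on
near-perfect data), from three starts bracketing the concentration range.
Defaults: top free in [0.8, 1.2], bottom free in [0, 1]; both can be pinned
(`fix_top = 1`, `fix_bottom = 0`) since instrument-software conventions for
"logistic interpolation" vary. Replicates are averaged per concentration
before fitting by default.

One identifiability caveat matters in practice. When the lower asymptote is
free and the ladder does not reach it, the midpoint parameter $m$ trades
off against `bottom` along a flat residual ridge: on noisy 10-point curves
the SSE-optimal $m$ can sit 20–30% from the truth while the fitted *curve*
is essentially correct. The stable estimand is the **absolute
half-viability concentration** — `ic50(fit, level = 0.5)` inverts the
fitted curve at viability 0.5 — which is also what "concentration producing
a 50% reduction in viability" means operationally. Recovery statistics in
the tests and acceptance script therefore measure that quantity; with
top = 1, bottom = 0 it coincides with $m$.

The default ladder is 10 points spanning 0.02–20 µM geometrically
(step ≈ 2.15×). A strict two-fold series cannot span a 1000-fold range in
10 points, so the endpoints are held fixed and the step follows; this is
the package's resolution of the "two-fold, 20 nM to 20 µM" convention.

## 5. High-content foci quantification

The imaging module mirrors a vendor high-content pipeline while keeping
every step explicit:

1. **Background correction**: least-squares fit of a degree-2 polynomial
   intensity surface (with one robustness pass dropping the brightest 20%
   of fit pixels so nuclei do not drag the surface up), subtracted and
   floored at 0. Morphological opening with a large box is available as an
   alternative estimator.
2. **Nucleus segmentation**: optional Gaussian pre-smoothing (σ = 1 px),
   Otsu threshold, hole filling, connected components. Per object: area
   (µm²), shape ratio perimeter²/(4π·area), length-to-width ratio from
   principal second moments, average and total intensity — measured on the
   *unsmoothed* corrected channel. Default filters: area 100–1500 µm²,
   both ratios 1–5, average intensity 500–8000, total 2×10⁵–5×10⁷.
   Excluded objects are tallied with the first filter they fail.
3. **Spot detection ("box method", value 3)**: the vendor operation is
   proprietary; it is implemented as top-hat enhancement — local background
   by morphological opening with a (2·3+1)² box, positive residual
   thresholded at the maximum of an absolute floor, `threshold_k` (4)
   robust noise SDs (MAD about 0), and `rel_threshold` (0.3) of the peak
   residual. The relative term keeps spot supports compact so adjacent
   foci resolve as separate components; it assumes roughly comparable
   focus amplitudes within a field, which holds for the generator and for
   typical immunofluorescence puncta but is listed as a limitation for
   strongly heterogeneous staining. Spots must lie entirely within a
   retained nucleus mask and pass focus filters (area 1–30 µm², ratios
   1–5, avg 500–16000, total 3×10²–10⁶).
4. **Statistics**: mean foci per nucleus ± SEM per condition, plus cells
   per field.

Perimeter uses a Crofton-style estimate (exposed unit edges × π/4), exact
in expectation for isotropic smooth contours: a rasterized disc measures a
shape ratio within ~5% of 1. The pixel scale defaults to 0.65 µm/px and is
explicit everywhere, since all filters are in physical units.

## 6. Tumor growth endpoints and survival comparison

Caliper volume is $0.5 \times L \times W^2$ (mm³), with reversed axes
swapped under a warning. RTV normalizes each series to its day-0 volume.
**Progression** is the first *measured* day with RTV ≥ 10 — no
between-visit interpolation, matching a twice-weekly measurement cadence —
and trajectories that never cross are censored at the last measurement;
animals removed early (death, open tumor) are censored at removal day.
Arms are compared by Kaplan–Meier curves and the unweighted (Mantel–Cox)
log-rank test via the survival package.

Small cohorts need care with the log-rank p-value: for 3 vs 3 animals the
permutation null has only $\binom{6}{3} = 20$ support points, and the
chi-square approximation can be off by ~0.08 in absolute p. The package
therefore offers `p_method = "permutation"` (Monte-Carlo label permutation
of the same statistic) and the test suite validates it against an
independently hand-rolled risk-set implementation; the asymptotic p remains
the default for conventional reporting.

## 7. What the generators emulate — and what they do not

Every generator is a pure function of its spec and a mandatory seed.

- **Screens** (`gen_screen`): multiplicative Bliss-null surfaces
  $v_{ij} = v_i^A v_j^B$ from logistic potencies, an injected synergy
  $\Delta$ subtracted from combination cells, additive Gaussian viability
  noise truncated at 0 (default σ = 0.05, on the scale of reported
  replicate SDs of ~10 score points), vehicle at 1 + noise. Default panel:
  4 cell lines (2 per genotype) × 27 compounds × 6×6 — the bookkeeping
  scale of a real screen. Default potencies place the single-agent IC50 at
  twice the top ladder dose so the null surface stays far enough from the
  viability floor that an injected Δ ≤ ~0.4 passes through arithmetically
  intact; with σ = 0 the recovered score is exactly 100·Δ. Not emulated:
  plate-position effects, edge evaporation, luminescence heteroscedasticity.
- **Curves** (`gen_dose_response_curve`): 4PL plus Gaussian noise on the
  default ladder.
- **Images** (`gen_foci_image`): non-overlapping disc nuclei (default
  radius 11.3 µm ⇒ area ≈ 400 µm²) with point-like foci planted at
  separated sites inside each nucleus, optional planar illumination
  gradient and Gaussian noise at a chosen SNR; ground truth lists every
  object, including deliberately out-of-filter plants (a ~50 µm² nucleus,
  a ~40 µm² focus) flagged `filtered`. Real nuclei are neither discs nor
  uniform; texture, overlaps and chromatin structure are not emulated, so
  passing imaging tests demonstrates correctness of the measurement
  machinery, not segmentation performance on real stains.
- **Trajectories** (`gen_growth_trajectories`): exponential volume growth
  from 100 mm³ with per-arm rates (defaults place the 10× crossing near
  day 21 for vehicle and day 40 for the treated arm), lognormal
  measurement noise (sdlog 0.1), twice-weekly schedule, rendered as
  (length, width) with a per-animal aspect ratio in [1, 1.4]. Not
  emulated: treatment-phase kinetics changes, regressions, toxicity
  dropouts beyond explicit censoring.

## 8. Numerical choices, problem sizes, and degenerate inputs

- Normalization is idempotent to 1e-12; zero-vehicle groups and missing
  vehicle wells are hard errors naming the group.
- Delta matrices agree with a cell-by-cell loop to 1e-12 (tested on random
  grids); scores are exact arithmetic on the delta grid.
- Flat dose-response data (zero variance) raise a degenerate-fit error
  rather than returning an arbitrary curve; optimizer failures return a
  non-converged fit, never a silent NaN.
- All-zero images pass through background correction unchanged with a
  warning; `ic50()` refuses levels outside the open (bottom, top) interval.
- Test and acceptance problem sizes were chosen as the smallest that pin
  the statistics: 1,000 null matrices for calibration (mean within ±1
  point of 0; |score| < 15 in ≥ 99%), 100 screens for ranking recovery,
  200 curves for IC50 recovery, 6 noisy fields for detection F1, 10,000
  permutations for the log-rank comparison.

## 9. Known limitations

- The aggregation-domain default (`combinations_only`) is a convention
  choice; scores under `full_matrix` are smaller by exactly 25/36 for
  constant deltas, and published scalar scores from external tools may use
  smoothing or alternative aggregation, so cross-tool comparisons should
  be made at matching settings.
- The box-method spot detector approximates a proprietary vendor
  operation; parameters are matched to the printed filter windows, but
  transfer to real instrument images is not claimed.
- Intensity filter windows are instrument-calibration specific (arbitrary
  units); apply them to other instruments only after recalibration.
- Free-asymptote 4PL midpoints are weakly identified on ladders that do
  not reach the lower plateau (Section 4); report the absolute
  half-viability concentration, or pin the asymptotes, when comparing
  potencies across conditions.
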