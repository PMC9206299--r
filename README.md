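# synletscreen

Analysis toolkit for plate-based drug **combination screens** in isogenic
cell-line panels, built around Bliss-independence synergy scoring of 6×6
dose matrices — the design used to find synthetic-lethal drug pairs that
selectively kill DNA-repair-deficient (e.g. BRCA1-mutant) tumor cells while
sparing repair-proficient controls. The package covers the full arc of such
a study:

- **Screen model** — long-format plate tables, normalization of raw
  luminescence to vehicle control wells, assembly of complete 6×6
  viability/inhibition grids.
- **Bliss synergy** — delta-score matrices and scalar synergy scores with
  the conventional "> 15 ⇒ synergistic" classification, replicate
  mean ± SD summaries, inhibition heatmaps.
- **Differential ranking** — compound ranking by the difference in mean
  synergy score between genotype groups (deficient − proficient), the
  computation behind a screen's hit list.
- **Dose–response** — four-parameter logistic (4PL) fits of 10-point
  single-agent curves and IC50 extraction.
- **Foci imaging** — high-content quantification of nuclear γH2AX foci:
  surface-fit background correction, nucleus segmentation with area/shape/
  intensity filters, box-method spot detection, per-condition statistics.
- **In-vivo endpoints** — caliper tumor volumes (0.5·L·W²), relative tumor
  volume (RTV), progression-free survival at a 10× RTV threshold,
  Kaplan–Meier curves and log-rank comparison.
- **Synthetic data** — seeded generators for every input type (screens,
  curves, images, growth trajectories) with ground truth, so the entire
  pipeline is testable without raw instrument data.

## The model

For fractional inhibition effects $\alpha^A$ and $\alpha^B$ of two agents at
doses $C_x^A$, $C_y^B$, Bliss independence predicts the combined effect of
non-interacting drugs as

$$\alpha_{exp} = \alpha^A + \alpha^B - \alpha^A\,\alpha^B ,$$

the composition rule for independent probabilities. The **delta score** at a
dose pair is the observed excess over this expectation,
$\Delta\alpha = \alpha_{obs} - \alpha_{exp}$, with the single-agent effects
read from the matrix's own edge row and column (vehicle at the corner). The
scalar **synergy score** is $100\times$ the mean $\Delta\alpha$ over the 25
cells where both doses are positive; a score strictly above 15 is called
synergistic. Effects are inhibition fractions $1-\text{viability}$, clipped
to $[0,1]$ by default so the Bliss composition stays probabilistic.

## Worked example

A synthetic 27-compound, 4-cell-line screen (two BRCA1-deficient and two
proficient lines, 3 replicates, viability noise σ = 0.05) with synergy
Δ = 0.25 injected for one compound in the deficient lines only:

```r
library(synletscreen)

inj  <- data.frame(compound = "compound13", genotype = "deficient", delta = 0.25)
spec <- screen_spec(injected = inj, sigma = 0.05, replicates = 3, seed = 42)
records <- gen_screen(spec)

screen  <- score_screen(records)                 # 108 condition summaries
ranking <- genotype_difference_ranking(screen)
head(ranking, 3)
#>     compound mean_deficient mean_proficient difference rank   hit
#> 1 compound13         24.580           0.467      24.11    1  TRUE
#> 2 compound14          1.991          -2.515       4.51    2 FALSE
#> 3 compound24          0.779          -1.143       1.92    3 FALSE
```

The injected compound is recovered at the top of the ranking with a
deficient-line mean score near the injected 25 points (the genotype
difference, 24.1, is the screen's hit statistic), and its per-matrix result
reads:

```r
m <- assemble_matrix(records, "KB1P-G3", "compound13", "GSK126", replicate = 1)
synergy_score(delta_matrix(effect_matrix(m)))
#> synergy_result: KB1P-G3, compound13 x GSK126 (replicate 1)
#>   score 24.26 (combinations_only), synergistic (> 15)
```

Single-agent potency, from a noisy 10-point curve generated with a true
midpoint of 13.4 µM:

```r
crv <- gen_dose_response_curve(ic50 = 13.4, sigma = 0.02, seed = 7)
fit <- fit_logistic(crv$concentrations, crv$viability)
fit
#> 4PL concentration-effect fit
#>   top 1.001  bottom 0.05314  hill 0.9184  ic50 13.37 uM
#>   SSE 0.00383  converged TRUE
ic50(fit, 0.5)   # concentration at absolute 50% viability: 15.1 uM
```

A command-line front end (`exec/synletscreen`) exposes `run`, `ic50`,
`synergy`, `rank` and `simulate` subcommands over the same functions, and
`run_full_screen()` writes scores, ranking, QC and a JSON manifest in one
call.

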