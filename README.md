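# privetspread

Spatially explicit forecasting of invasive shrub range expansion and the
associated crown fire risk in southeastern US forestlands.

Chinese and European privet (*Ligustrum sinense*, *L. vulgare*) are among the
most aggressive invasive shrubs of southern forests. They thicketize the
understorey, adding ladder fuels and coarse woody fuels that raise the odds of
stand-replacing crown fires during drought. `privetspread` implements a
cell-based invasion forecasting pipeline for this system, exercised end-to-end
on synthetic landscapes: it is aimed at quantitative ecologists and forest
biometricians who want a reproducible, testable implementation of the
forecasting machinery without access to the proprietary inventory plot data.

## The model

The landscape is a lattice of 2428-ha cells (width 4927 m), each assigned one
of seven land types; invasion is confined to forest cells. Per-cell occupancy
percent `P_i,t` evolves annually by logistic local spread plus immigration:

    P_{i,t+1} = P_{i,t} + r_i P_{i,t} (1 - P_{i,t}/K_i) + q * sum_{j != i} k_ji P_{j,t}

clamped to `[0, K_i]` with `K_i = 100`. The components are estimated in
stages:

- **Habitat quality** `HQ_i = logistic(alpha + X_i' beta)`: logistic
  regression of invasion presence on landscape, forest, climate and ownership
  covariates, selected by bidirectional stepwise AIC and validated by the
  Hosmer–Lemeshow test and classification accuracy.
- **Intrinsic spread rate** `r_i = ln(P_i,t2 / P_i,t1) / (t2 - t1)` from
  paired occupancy surveys (cells with treatments, declines, or zero
  occupancy are flagged and excluded); seven candidate functional forms
  relate `r` to `HQ` (best published fit: `r = 0.3815 exp(0.8611 HQ)`, giving
  `r = 0.86`/yr in the best habitat, HQ = 0.95) and impute rates for
  unsurveyed cells.
- **Dispersal kernel** `k_ji`: the radially symmetric lognormal kernel with
  shape `S = 1` and scale `L` (the dispersal velocity in grid-widths per
  year, equal to the median dispersal distance). The scale is calibrated by
  simulating 8-year invasion patterns for the candidate ladder
  `L = 1, 1/2, ..., 1/7` (4927 down to 703.86 m/yr) and comparing each to the
  observed pattern with Mantel's permutation test (999 randomizations).
- **Crown fire risk**: a zero-inflated negative binomial model of 5-year
  crown-fire counts — structural zeros driven by temperature and
  precipitation, counts driven by slope, physiographic class and privet
  occupancy (xeric and mesic sites burn ~2.14 and ~2.04 times more often
  than hydric; each occupancy percent multiplies expected frequency by
  ~1.05). Simulated occupancy converts to expected annual frequencies,
  binned into 0.125-wide risk categories.

Monte Carlo ensembles perturb `r_i` with a median-1 lognormal multiplier each
cell-year and report yearly means ± SE of landscape totals.

## Worked example

The `analysis/` scripts run the pipeline as a six-stage workflow
(`Rscript analysis/01_generate_landscape.R`, then `02` … `06`), writing
tables under `results/`. On the default seeds, stage 4 prints the
calibration table for an observed pattern generated at the true scale
`L = 1/5`:

      velocity     L mantel_r p_value pseudo_loglik
    1     4927 1.000    0.657   0.001        -20856
    2     2464 0.500    0.866   0.001         -5845
    3     1642 0.333    0.951   0.001         -2029
    4     1232 0.250    0.987   0.001          -760
    5      985 0.200    0.995   0.001          -537
    6      821 0.167    0.991   0.001          -709
    7      704 0.143    0.978   0.001         -1073
    Selected L = 0.2 (velocity 985.40 m/yr)

i.e. the true dispersal velocity (985.4 m/yr) attains the largest Mantel
correlation with the observed pattern and is selected. Stage 2 reports the
habitat-quality refit ("Hosmer-Lemeshow: chi2 = 8.40 (df 8), p = 0.3957;
correctly classified 76% of forest cells"), stage 5 the 60-run, 20-year
projection ("forest occupancy 0.11% (year 0) -> 32.12% +/- 0.02 SE
(year 20)"), and stage 6 the fitted crown-fire model and the count of forest
cells per annual-frequency category at year 0 versus year 20.

The same pipeline is available programmatically:

```r
library(privetspread)
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "results"))
res$calibration$table
res$ensemble$summary
```

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch at desk scale —
landscape generation, habitat-quality fit, rate estimation, dispersal
calibration over the whole candidate ladder, a 40-run 20-year ensemble and
the crown-fire model — against the installed package, and writes its JSON
report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
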