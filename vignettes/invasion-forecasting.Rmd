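---
title: "Forecasting invasive shrub spread and crown fire risk: methods and design choices"
author: "privetspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting invasive shrub spread and crown fire risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privetspread)
```

## The model and its assumptions

`privetspread` forecasts the range expansion of understorey shrub invasions
(exotic privets in southeastern US forestlands are the motivating system) on
a lattice of 2428-ha cells, and converts projected occupancy into expected
crown fire frequencies. The annual update for forest cell $i$ is

$$P_{i,t+1} = P_{i,t} + r_i P_{i,t}\left(1 - \frac{P_{i,t}}{K_i}\right) + q \sum_{j \ne i} k_{ji} P_{j,t},$$

where $P_{i,t}$ is the percentage of the cell occupied by the invader,
$K_i = 100$ is the carrying capacity (heavily invaded plots reach essentially
full occupancy), $r_i$ is the intrinsic local spread rate, $k_{ji}$ is the
dispersal-kernel weight from cell $j$ to $i$, and $q$ scales immigration.
The model assumes: (i) invasion is confined to forest land and land types do
not change over the horizon; (ii) within-cell spread is logistic; (iii)
between-cell propagule pressure is linear in source occupancy and depends on
the pair only through centroid distance; (iv) updates are annual and
synchronous (all increments are computed from the year-$t$ state and applied
at once, so cell ordering cannot matter). The state is clamped to
$[0, K_i]$ after every step, which absorbs any overshoot from the sum of
growth and immigration.

The printed update equations are deterministic. Monte Carlo ensembles arise
from a declared stochasticity: each cell-year, $r_i$ is multiplied by a
lognormal deviate with median 1 and log-sd `noise_sd`. This preserves the
expectation structure of the logistic term (in the median sense), produces
ensemble spread that grows with the projection horizon, and collapses exactly
to the deterministic recursion at `noise_sd = 0` — which the tests exploit.
An alternative literal reading of the component equations, in which local
spread and immigration accumulate as running totals that are re-added every
year, diverges (occupancy increments would compound without bound) and was
rejected.

$q$ is exposed as a parameter with default 1, i.e. the kernel mass arriving
in a cell converts one-to-one into occupancy percentage; it is a free scaling
constant with no independent estimate, and the calibration stage absorbs
mis-scaling into the selected velocity.

## Stage models

**Habitat quality.** $HQ_i = \mathrm{logistic}(\alpha + X_i'\beta)$ is the
probability that a forest cell is invaded, fitted by maximum likelihood and
selected by bidirectional stepwise AIC from the full candidate set. The
covariates are slope (degrees), adjacency to water within 300 m (0/1), mean
daily maximum temperature (°C), stand age (years), site productivity class,
artificial regeneration (0/1), distance-to-road class, fire disturbance
(0/1) and private ownership (0/1). `reference_hq_model()` carries the
published regional estimates; the odds ratio of any covariate is
$e^{\beta_j}$ exactly, which the tests verify through the prediction
function. Model validity is checked by the Hosmer–Lemeshow test (equal-count
deciles of predicted risk, ties broken by a stable sort; groups with zero
expected counts are merged with their neighbour and the merge is logged;
$\chi^2$ on $G-2$ df) and by classification accuracy at a fixed threshold of
0.5 (no threshold is standard for this statistic; 0.5 mirrors the "correctly
classified" convention).

**Spread rates.** Paired surveys give
$r_i = \ln(P_{i,t_2}/P_{i,t_1})/(t_2 - t_1)$. Cells are flagged — never
errored — when treated (site preparation or control), when occupancy
declined, or when either survey is zero (the estimator is undefined at 0);
flagged cells later receive rates imputed from habitat quality, mirroring the
handling of plots without second-cycle surveys. Seven candidate curves
relate $r$ to $HQ$: linear, logarithmic, inverse power, quadratic power, and
exponentials in $\sqrt{HQ}$, $HQ$ and $HQ^2$. The $\sqrt{HQ}$ exponential
appears in the candidate list but not in the canonical comparison table; it
is implemented and fitted by default, and can be dropped via the `families`
argument. Every family is linear in its parameters after transforming the
predictor (and, for exponentials, taking $\log r$), so all fits are ordinary
least squares — deliberately, to avoid nonlinear-optimizer nondeterminism.
$R^2$ is reported on the natural scale for all families (and additionally on
the log scale for exponentials, since which scale the canonical table uses
is not stated). Selection takes the highest natural-scale $R^2$ among
families whose coefficients are all significant at $p < 0.01$ (the gate the
canonical comparison states). On noiseless data a family fits its own data
exactly, residual variance is numerically zero and least-squares p-values
are NaN; such perfect fits are assigned $p = 0$ so that the generating
family wins selection, as it should.

**Dispersal.** The radially symmetric lognormal kernel integrand reduces
algebraically to the lognormal density with log-median $\ln L$ and log-sd
$S$, so band masses are differences of lognormal CDFs; the tests verify this
closed form against adaptive quadrature of the raw integrand to $10^{-9}$.
$S = 1$ follows the convention for woody, animal-dispersed species. $L$ is
the dispersal velocity in grid-widths per year and equals the median
dispersal distance. On the lattice, the centroid distance of each ordered
pair is assigned to the unit-width annulus $[D-\tfrac12, D+\tfrac12]$ and the
band's mass is **shared equally among the source cell's recipient cells in
that band**. The discretization of the continuous kernel onto a lattice is
underdetermined (how many neighbours share an annulus is a modelling
choice); equal sharing is declared because it conserves probability — row
mass never exceeds 1, and mass in empty bands, in $[0, \tfrac12)$, or beyond
the truncation radius represents propagules that leave the landscape (or
stay home, which the logistic term already covers; self-weights are 0). One
consequence: for boundary cells the weight at a given distance can differ
between rows, so "depends only on distance" holds exactly for interior cells
of a uniform lattice and within every row always. The kernel is truncated
where the cumulative lognormal mass passes 0.999, bounding cost with
negligible loss; rows are not renormalized after truncation.

**Calibration.** Candidate scales $L = 1, 1/2, \dots, 1/7$ (4927 to 703.86
m/yr at the 4927-m cell width) each drive an ensemble over the 8-year
survey-to-survey span; the ensemble-mean final pattern is compared to the
observed pattern with Mantel's permutation test. The pattern statistic is
the matrix of pairwise absolute occupancy differences over forest cells (the
comparison requires some dissimilarity summary; occupancy differences are the
default and a presence/absence mismatch matrix is a drop-in alternative).
Mantel's $r$ is the Pearson correlation of lower triangles; the p-value is
one-sided ($p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(n_{perm}+1)$ under
simultaneous row/column permutation), consistent with selecting the most
positively correlated candidate: the selected $L$ is the significant
($p \le 0.05$, 999 randomizations) candidate with the largest $r$. A
Gaussian pseudo-log-likelihood of the observed occupancies around ensemble
means is reported alongside but never drives selection.

**Crown fire.** Expected 5-year counts follow a zero-inflated negative
binomial: $E_i = [1 - p_i]\,\mu_i$ with
$p_i = \mathrm{logistic}(\gamma + \delta' w_i)$ driven by climate (structural
zeros: conditions under which crown fires are unlikely regardless of fuels)
and $\mu_i = \exp(\epsilon + \zeta' z_i)$ driven by slope, physiographic
class (hydric is the reference; xeric and mesic enter as indicators) and
privet occupancy. The fit is joint maximum likelihood via BFGS on the exact
ZINB log-likelihood (the zero class mixes structural zeros with negative
binomial zeros via log-sum-exp), with standard errors from the inverse
observed Hessian and backward elimination by AIC honouring the partition —
climate candidates in the zero part, landscape/forest/occupancy candidates
in the count part. No installed package provides this estimator, so it is
implemented here and cross-checked against `MASS::glm.nb` on the
zero-inflation-free special case. Annual expected frequencies are the 5-year
expectation divided by 5 (the window is 5 years; reporting is annual), and
risk categories are half-open bins of width 0.125, lower-exclusive and
upper-inclusive, so 0.125 falls in the lowest positive bin.

## The synthetic world

The generator emulates the statistical structure the analysis assumes, not
any real geography: a near-square lattice (the field sampling design uses
hexagons of the same 2428-ha area; squares of equal area are
distance-equivalent at this resolution), seven land types with configurable
proportions (default 55% forest, matching heavily forested Gulf states),
Gaussian climate and terrain covariates truncated to valid ranges (mean
daily maximum 24 ± 1.5 °C, precipitation 0.38 ± 0.08 cm/day — a humid
subtropical climate of roughly 1400 mm/yr — slope 4 ± 3°, stand age
40 ± 20 yr), ordinal productivity and road-distance classes, mostly private
ownership (85%), and a physiographic mix of 25% xeric / 60% mesic / 15%
hydric. Initial invasion is restricted to a handful of forest foci with
occupancy drawn below the 25% low-occupancy ceiling.

Three generator contracts make the downstream estimators testable:

- presence is drawn from a known logistic truth (`synthetic_hq_truth()` uses
  the published slopes with the intercept set to hit a target prevalence of
  0.3 on this landscape's covariate scales, since the published intercept
  belongs to the original survey's codings);
- the second survey is the exponential-growth image of the first,
  $P_{t_2} = \min(K, P_{t_1} e^{r \Delta t + \varepsilon})$, so the rate
  estimator recovers the generating rate exactly at zero noise;
- fire counts are structural zeros with probability $p_i$, otherwise
  negative binomial draws, so the empirical mean approaches $(1-p_i)\mu_i$.

Two stated-world choices deserve explanation. First, the rate survey draws
leading-edge occupancies of 0.1–0.8%: at spread rates of 0.38–0.86/yr, five
years of exponential growth multiplies occupancy 7–74-fold, and any start
above ~1.3% saturates at $K$, censoring the log-ratio estimator; the
invasion front the estimator is meant to capture is exactly these
low-occupancy plots. Second, the crown-fire intercepts and dispersion — not
part of the published coefficient table — are declared as
`zero_intercept = 2.6` (≈40% structural zeros at the regional climate
means), `count_intercept = -3.6` and `dispersion = 1.5`, anchored to the
observed rarity of crown fires (about 3% of inventory plots burned in a
5-year window) and keeping annual expected frequencies within the reported
0–0.5 category range; every published fire-model quantity is a ratio or
per-unit change and is independent of these values. Because crown fires are
that rare, the pipeline fits the fire model on an auxiliary plot sample
(default 4000 cells, ~30% invaded) standing in for the full regional
inventory rather than on the small simulated landscape, where a few dozen
forest cells would contain only a handful of fires.

A green test suite on this world establishes that the estimators recover
known truths under the model's own assumptions — it does not establish
spatial autocorrelation robustness, covariate measurement error, observer
effects, or any fidelity to real Alabama/Mississippi geography, none of
which the generator emulates.

## Numerical choices

- Kernel band masses use `plnorm` differences; quadrature only appears in
  tests as the independent oracle.
- Exponential rate curves are estimated by log-linear least squares; the
  natural-scale $R^2$ of the back-transformed fit is what selection uses.
- The ZINB likelihood evaluates the zero class by log-sum-exp to avoid
  underflow; the dispersion is optimized as $\log\theta$; starting values
  are a Poisson regression for the count part and a flat zero part.
- Hosmer–Lemeshow groups are equal-count by construction
  (`ceiling(rank * G / n)` after a stable sort), so ties in predicted risk
  cannot reorder records between runs.
- Ensemble and calibration seeds derive from one master seed via
  `sample.int(.Machine$integer.max, ...)`, keeping every derived seed a
  valid 32-bit integer and reruns bit-identical.
- Monte Carlo sizes are scaled down from the full design (240 runs) to 20–60
  runs in the shipped workflow and tests; standard-error columns make the
  cost of that visible.

## Known limitations

- No spatial autocorrelation correction in the habitat-quality fit, no
  mixed-effects or spatially varying rates, no anisotropic kernels.
- Climate covariates are constant over the projection horizon; there is no
  fire-spread physics, fuel-moisture modelling or management intervention.
- The calibration experiment's power depends on contrast in the observed
  pattern; with very few foci or very low noise contrast, neighbouring
  velocities are near-indistinguishable and selection can return a
  non-significant table (reported as "none selected", never an error).
- The literal hexagonal tessellation, real inventory data ingestion and
  GIS-based mapping of the original analysis are out of scope.
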