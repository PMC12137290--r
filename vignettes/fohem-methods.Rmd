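---
title: "Methods: hybrid fuzzy-ensemble yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid fuzzy-ensemble yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fohem)
```

This vignette is the package's own account of its model, its tunable
parameters, the synthetic data it is validated on, and the numerical and
design choices behind the implementation.

## The prediction problem

One record is a plot-season observation from a maize–soybean intercropping
trial: numeric soil covariates (organic carbon, pH, iron, clay content,
plant-available moisture, ...), crop covariates (total biomass,
transpiration, leaf area index, ...), management covariates (maize residue
biomass, management scores), a treatment code (`SS` sole soybean, `SM` sole
maize, `2M2S` two maize rows alternating with two soybean rows, `2M3S` two
maize with three soybean rows), a location, and the observed yield in t/ha.
The goal is a per-record yield prediction that is both accurate and
agronomically interpretable.

## Model structure

The predictor is a convex blend of two components,

$$\hat Y \;=\; w_{\mathrm{fis}}\, Y_{\mathrm{FIS}}
        \;+\; (1 - w_{\mathrm{fis}})\, Y_{\mathrm{ens}},
        \qquad 0 \le w_{\mathrm{fis}} \le 1,$$

with the weight fitted on a validation split, either globally or per
treatment-by-location group (a global fallback weight always exists and
serves unseen groups).

### Fuzzy inference system

Each input variable carries triangular membership functions
$\mu_{a,b,c}(x)$ rising linearly on $[a,b)$ and falling on $[b,c]$, with
the boundary sets *shouldered* (membership saturates at 1 beyond the peak)
so extreme observations keep full membership. Rule antecedents are
AND-combined with the `min` t-norm by default; `product` is selectable
because the two readings coexist in common practice. Inference is standard
Mamdani: consequent sets clipped at the rule strength, aggregated by
pointwise maximum over the output universe discretized at `resolution`
grid points (default 1000), defuzzified by centroid
$\sum_i x_i \mu_i / \sum_i \mu_i$.

The default yield rule base (`build_yield_fis()`) takes 2–4 selected
features. Breakpoints follow the expert ranges where they are known —
total biomass: low 0–10, medium 5–20, high 15–20 t; maize residue biomass:
low 0–4000, high 6000–10000 kg/ha — and an overlapping tertile partition of
the feature's range otherwise. Overlapping printed ranges are realised as
peak-at-midpoint triangles. The output variable spans 0–10 t/ha with low
yield below 7.5 (left-shouldered, peak 0), medium 7.5–9 (peak 8.25), and
high 9–10 (right-shouldered). The rule grid enumerates all label
combinations and maps them monotonically (scores low = 0, medium = 1,
high = 2; consequent low when the mean score $\le 0.5$, high when
$\ge 1.5$, else medium), so all-low maps to low, all-high to high, and
mixtures to medium. Records where no rule fires receive the output-universe
midpoint with a warning rather than an error, keeping batch pipelines
total; `fis_infer()` on a single record still raises a typed error so
callers can implement their own fallback.

### Stacked ensemble

Three base learners: a random forest (`ranger`, 300 trees), a gradient
booster (`xgboost`, 300 rounds, learning rate 0.1, depth 4, native factor
handling for treatment/location), and an in-package extreme learning
machine. The ELM draws hidden weights and biases once from a seeded
Uniform(−1, 1) on standardized inputs (default 100 sigmoid units) and fits
only the read-out, as the ridge solution
$\hat\beta = \arg\min \lVert H\beta - y\rVert^2 + \lambda\lVert\beta\rVert^2$
with $\lambda = 10^{-3}$, intercept unpenalized, computed stably by SVD of
the centered activation matrix. The meta-combiner is non-negative least
squares of the response on out-of-fold base predictions plus an intercept
(5 folds by default): the simplest leak-free stacker, and one whose
in-meta-sample error can never exceed that of its best base learner.

### Genetic algorithm

One engine serves all three searches: binary or bounded-real chromosomes,
tournament selection (size 3, sampled **with replacement**, ties to the
lowest index — with-replacement sampling is what makes the size-2
tournament probabilities over fitnesses $(1,2,3)$ exactly $(1/9, 3/9,
5/9)$), one-point crossover for binary and arithmetic blend for real
chromosomes at rate 0.8, per-gene mutation at rate 0.02 (bit flip, or
Gaussian perturbation with sd $0.1(hi - lo)$ clamped to bounds), elitism
(1 by default, guaranteeing a monotone best-fitness history), a
50-generation budget, and early stopping after 10 stagnant generations.
Fitness is always maximized; error-minimizing callers pass the negation.

**Feature selection** evolves an inclusion mask scored by
$\mathrm{CV}\text{-}R^2 - \lambda_{\mathrm{par}} \cdot k/p$ with parsimony
weight $\lambda_{\mathrm{par}} = 0.05$; all-zero masks are repaired by
activating one random gene. **Feature engineering** then selects from a
finite candidate pool — squares, `log1p` (only for non-negative ranges),
and pairwise products of the top-8 yield-correlated features — and a
transformation set is retained only if its penalty-free score is at least
the base mask's.

**Evaluator choice.** The selection stage scores candidates with a small
cross-validated random forest (3 folds, 50 trees): cheap, seedable, and
able to detect any form of dependence. The engineering stage instead uses
a cross-validated ridge-stabilized linear fit on standardized columns.
This split is deliberate: tree ensembles are invariant to monotone feature
maps, so a forest scores `x^2` and `log1p(x)` identically and cannot tell
*which* functional form a target actually contains — under a forest
evaluator a monotone surrogate ties with the true square term and recovery
of a planted quadratic becomes unreliable. A linear evaluator credits
exactly the transformation that linearizes the relationship; the test
suite asserts recovery in at least 8 of 10 seeded runs.

**Weight optimization** runs a real-chromosome GA (one gene per group,
bounds $[0,1]$) minimizing validation MSE of the blend. Because the
objective is separable and quadratic in each gene, every gene is then
polished by a bounded Brent line search with the endpoints kept as
candidates. The polish guarantees the returned blend never does worse than
either component on the validation data — a pure GA can land within its
mutation scale of the optimum but cannot make that guarantee when the
optimum sits near an endpoint. The closed-form projection optimum
$w^\* = \mathrm{clamp}\!\left(\langle y - y_{\mathrm{ens}},\,
y_{\mathrm{fis}} - y_{\mathrm{ens}}\rangle / \lVert y_{\mathrm{fis}} -
y_{\mathrm{ens}}\rVert^2,\, 0, 1\right)$ is used only in tests, as an
independent oracle. Per-group weights are used when every group has at
least 10 validation records (8 free weights on a ~45-record validation
split overfit otherwise); groups with fewer than 2 records merge into the
global weight with a warning.

### Orchestration

`fohem_fit()` chains the stages: a seeded 80/20 fit/validation split
stratified by treatment-by-location; feature selection and engineering on
the fit part; FIS construction on the top (by absolute yield correlation)
2–4 selected features; stack fitting on the engineered design; weight
optimization on the validation part; finally an ensemble refit on all
data. One global seed fans out to fixed per-stage offsets, so a single
integer reproduces the entire fit, byte for byte. Inside `fohem_fit()` the
feature-stage GAs default to population 30 and 15 generations (each
fitness call refits a cross-validated model; the search space is small),
while the weight GA keeps the full population-100 / 50-generation
protocol, whose fitness is arithmetic. Standalone `ga_config()` defaults
remain population 100 / 50 generations.

## The synthetic generator

Real records of this kind are institutional and not publicly distributable,
so validation runs on `simulate_yield_data()`. Defaults emulate the study
conditions: 225 records; 26 numeric features (uniform within expert ranges)
plus treatment and location, 28 input parameters in all; near-balanced
group assignment; yield built additively as

$$Y = 6.0 + \beta_{\mathrm{treat}} + \beta_{\mathrm{loc}}
      + \textstyle\sum_j e_j z_j + \varepsilon,\qquad
      \varepsilon \sim \mathcal N(0, 0.3^2),$$

clipped at zero, where $z_j$ standardizes feature $j$ to $[-1, 1]$ within
its range. Treatment effects ($\mathrm{SS} = -2.2$, $\mathrm{SM} = +1.2$,
$\mathrm{2M2S} = +0.8$, $\mathrm{2M3S} = +0.4$ t/ha) make maize-dominant
treatments out-yield sole soybean; location effects ($\pm 0.5$ t/ha) put
Khairpur above Bahawalpur; both orderings and the 0–10 t/ha yield scale
mirror the reported field behaviour. Feature effect signs encode the
planted interpretability ground truth (total biomass, residue biomass,
moisture, pH positive; iron, clay, bulk density negative), and eight
features are pure noise so selection has a planted negative answer.

What the generator does **not** emulate: correlated features (all
covariates are independent uniforms), treatment-dependent feature
distributions, interactions or non-additive yield structure (unless a test
plants one), multi-year panel dependence, and weather series. Passing
tests therefore demonstrate that each algorithm recovers structure it is
designed to recover — not that the pipeline attains any particular accuracy
on real intercropping data, whose headline numbers are not reproducible
without the private records.

## Numerical choices and degenerate inputs

- Defuzzification grid: 1000 points; doubling it moves crisp outputs by
  well under 0.5% of the universe span, and a 10^4-point re-implementation
  agrees to 10^-3 of span.
- Degenerate membership segments ($a = b$ or $b = c$) evaluate to 1 at the
  shared point; membership is clamped to $[0,1]$ everywhere.
- ELM: constant columns get sd 1 before standardization; the SVD solve
  handles the over-parameterized (interpolation) regime where normal
  equations would be singular.
- The linear evaluator standardizes encoded columns and adds a $10^{-6}$
  ridge so near-collinear engineered designs (e.g. a feature and its
  square on a large scale) remain solvable.
- Tie-breaks are deterministic throughout (tournament ties to the lowest
  index; candidate pools ordered by schema position on equal correlation),
  which is what makes seed-reproducibility exact.
- Zero-variance targets make $R^2$ undefined; metrics report `NA` with a
  warning instead of failing.

## Problem sizes used in the checks

The test suite and the acceptance script run at desk scale, chosen once:
the full study conditions ($n = 225$) for end-to-end fits, stacking, and
cross-validation; $n = 100$–$120$ with reduced GA budgets (population
10–20, 4–10 generations) for repeated-recovery properties that need 10
seeded replicates; $10^4$ draws for the tournament distribution check; 100
random rule bases for the inference oracle. The five-fold cross-validation
of the whole pipeline in `scripts/acceptance.R` refits the hybrid model per
fold.

## Known limitations

- The FIS is a coarse expert prior (3 sets per variable, monotone rule
  grid); on the synthetic conditions it explains far less variance than the
  ensemble, and the optimized blend weight correctly stays small. Its value
  is interpretability and robustness, not standalone accuracy.
- Rule bases are not induced from data beyond the monotone grid, and
  membership parameters are not themselves optimized.
- Blend weights are convex by construction; a negative or >1 weight (one
  component anti-correlated with the target) is clamped.
- The gradient-boosting learner is delegated to `xgboost`; no
  hyperparameter search is performed for any base learner.
- Shapley values use Monte-Carlo sampling with background imputation;
  contributions carry sampling error reported as per-feature standard
  errors, and assume feature independence in the background draws.
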