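---
title: "Ensemble habitat models and the change importance product"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble habitat models and the change importance product}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icehab)
```

## The problem

Ice-obligate Antarctic seals breed on sea ice whose extent and stability are
expected to change under climate warming. Surveys of breeding distribution
from very-high-resolution satellite imagery yield presence–absence records
(one row per surveyed location) together with remotely sensed environmental
covariates — bathymetry, distance to the ice edge, ice-concentration
variability, sea-surface temperature, distances to penguin colonies, and so
on. Two questions follow: which covariates explain breeding habitat, and
which of those influential covariates are themselves likely to change? A
covariate can matter a great deal to the seals yet be irrelevant to climate
projections (bathymetry), or be volatile under warming yet unimportant to
habitat choice. The analysis implemented here answers both questions at once
with the *change importance product*: the product of a model-derived
proportional variable importance and an expert-elicited climate change
score, ranked across covariates.

`icehab` implements that pipeline end to end and pairs it with a synthetic
presence–absence generator, so every stage can be exercised and tested
without the original survey data, which are not public.

## The pipeline

### 1. Collinearity screening

Oceanographic and ice covariates are inherently collinear. For each
covariate $j$, the variance inflation factor is
$\mathrm{VIF}_j = 1/(1 - R^2_j)$, with $R^2_j$ the coefficient of
determination of an OLS regression of covariate $j$ on all the others.
`filter_by_vif()` removes covariates *stepwise*: the single worst offender
is dropped (ties broken alphabetically), VIFs are recomputed, and the loop
repeats until every remaining covariate has VIF at or below the threshold
(default 10, the conventional cut for strong collinearity). Stepwise
removal, rather than one-shot exclusion of everything above threshold, is
deliberate: under shared collinearity a one-shot rule discards covariates
that become acceptable once their partners are gone. Every removal is
logged with the VIF at removal, so the one-shot alternative can be
reconstructed from the report. Perfect linear dependence is reported as an
unbounded flag rather than a floating-point overflow.

### 2. Balanced hold-out

Survey data are severely unbalanced: presences are far rarer than absences.
`make_holdout()` holds out `floor(0.2 × presences)` presence records plus
an *equal* number of absences, both sampled uniformly, so goodness of fit
is judged on a balanced test set while the training remainder keeps its
imbalance. The fraction is interpreted relative to presences, not all
records — that is the arithmetic under which a survey of 4,911 presences
yields a 982 + 982 test set and 3,929 training presences. An explicit count
override (`n_test_presence`) covers designs whose hold-out was not an exact
fraction.

### 3. Balanced bootstraps

Rather than reweighting, the analysis resamples: each bootstrap replicate
contains *every* training presence exactly once plus an equal-sized random
sample of absences (without replacement while the pool allows, with
replacement otherwise). Models trained on unbalanced data optimise absence
prediction at the expense of presence error; the 1:1 bootstrap removes that
incentive, and replicate-to-replicate variation in the absence sample
propagates sampling uncertainty into every downstream summary. The default
is 500 replicates per learner family.

### 4. The three-member ensemble

Each bootstrap is fitted by three model families:

* **RF** — a probability random forest (`ranger`).
* **BRT** — gradient-boosted regression trees (`xgboost`), whose per-split
  gain records drive its importance measure.
* **Maxent** — an L1-regularised maximum-entropy presence/background model,
  implemented in this package (see below).

Per bootstrap, each family is tuned by grid search with 10-fold
cross-validation: records are randomly partitioned into folds whose sizes
differ by at most one, out-of-fold predictions are pooled, and candidates
are scored by $R^2 = 1 - SS_{res}/SS_{tot}$ against the 0/1 labels (a
squared-correlation variant is available by flag). Ties go to the simpler
candidate — fewer trees, or larger regularisation — then declaration order.
Default grids are conventional SDM choices: RF tries
$m_{try} \in \{\lceil\sqrt p\rceil, \lceil p/3\rceil, p\}$ at 500 trees;
BRT crosses learning rate $\{0.01, 0.1\}$, depth $\{1, 3\}$ and
$\{100, 500\}$ trees; Maxent tries regularisation multipliers
$\{0.5, 1, 2\}$. All grids are configurable, and the test suite and
acceptance script use deliberately small single-candidate grids so that
500-bootstrap runs complete in minutes; the grids affect member quality,
never the pipeline's counting arithmetic.

### The maximum-entropy learner

Maxent is the one member the R ecosystem does not supply as a uniform,
self-contained fitting routine, so it is implemented here from its
objective. Given presence rows and background rows, covariates are expanded
into features (linear and quadratic by default; hinge and pairwise products
available), standardised against the background, and the weights solve

$$\max_w \; \overline{F_p w} \;-\; \log \overline{\exp(F_b w)}
\;-\; \sum_j \lambda_j |w_j|, \qquad
\lambda_j = \text{reg} \cdot s_j / \sqrt{n_{pres}},$$

where $s_j$ is the feature's standard deviation over the presences. The
problem is concave and solved by accelerated proximal gradient (FISTA) with
backtracking and adaptive restart, to a prox-gradient residual below 1e-6.
At zero regularisation the solution satisfies the maximum-entropy moment
constraints — model-weighted background feature means equal presence
feature means — which the tests verify, together with a closed-form
one-binary-feature oracle, $w = \log\!\big(p(1-q)/(q(1-p))\big)$.

Predictions transform the fitted relative log-density through a logistic
link anchored at the training prevalence.

One choice deserves emphasis: in the pipeline the normalisation sample (the
"background") is the *whole* balanced bootstrap — presences and absences —
not the absences alone. With only ~10² absence rows and a quadratic
expansion, the presence feature means can lie outside the convex hull of
the absence features, in which case the maximum-entropy objective is
unbounded below and no finite weights exist; including the presence sites
in the background (as canonical Maxent software does — sample locations are
part of the landscape) guarantees boundedness. `fit_maxent()` itself uses
exactly the background it is given, so callers can make either choice.

### 5. Variable importance, made comparable

Importance is computed per member with the measure native to each family:
permutation importance (baseline AUC minus mean AUC over 5 independent
shuffles of a covariate, on the member's own bootstrap records) for RF and
Maxent, and percentage split-gain contribution for BRT. Raw measures are
then made comparable by *proportional* normalisation: negatives are clipped
to zero and each is divided by the sum, so per member the importances are a
point on the simplex. Means and SDs across bootstraps are reported per
family. The record set, metric and shuffle count are configurable; in-bag
evaluation with AUC is the default because it matches the packaged
behaviour ecologists commonly rely on.

A member whose raw importances are all zero after clipping — possible for a
fully shrunk Maxent fit on noise — carries no signal to allocate and is
excluded from aggregation; the run manifest counts such exclusions.

### 6. The change importance product

Experts independently score each covariate 0–3 for expected change under
climate warming (0 none … 3 high); rater means give the *climate change
score*. The anchor cases from the elicitation design are pinned in the
generator's fixtures: an ice-edge-distance covariate scores 3 (ice is
already receding), a bathymetry covariate scores 0 (depth will not change).
The change importance product is then

$$\mathrm{CIP}_{v,m} = \text{score}_v \times
\overline{\text{prop.\ importance}}_{v,m} \in [0, 3],$$

per covariate $v$ and model family $m$, with a single ranking taken on the
unweighted mean across the three families (no weighting is justified, so
none is applied). Ties are broken alphabetically and flagged. Because
scores enter multiplicatively, the ranking is invariant to any uniform
positive rescaling of the score scale, and zero-scored covariates rank last
regardless of importance — both tested properties.

### 7. Evaluation and partial dependence

Every member is scored on the balanced hold-out with both AUC (the
Mann–Whitney pair statistic) and $R^2$; means ± SD are reported per family,
deliberately as a superset so either reporting convention can be read off.
Partial dependence sweeps one covariate over 50 evenly spaced points
between its 1st and 99th percentiles (avoiding extrapolated tails), sets
every record's value to each grid point, averages predictions within each
member, and reports the mean and SD of those member-level curves pooled
across *all* members of all families — the ribbon therefore mixes
bootstrap-sampling and between-model uncertainty. Per-family curves are
also attached.

## The synthetic generator

`sim_config()` + `simulate_dataset()` generate data with the statistical
structure the analysis assumes and nothing more:

* covariates drawn multivariate normal with a requested correlation matrix
  (validated positive semi-definite); positive, right-skewed
  distance-to-feature covariates obtained by exponentiating a Gaussian —
  a monotone transform that adds realism without new machinery;
* manufactured near-duplicate columns (`collinear_pairs`) whose VIF exceeds
  any reasonable threshold, to exercise the screen;
* presence labels drawn Bernoulli through a logistic link on a known sparse
  set of driver coefficients, with rows resampled and relabelled until the
  presence and absence counts match the configuration *exactly* — survey
  class totals are observed constants, not random variables, and the
  pipeline's counting arithmetic is tested against exact values;
* severe, configurable class imbalance. The real absence:presence ratio of
  the surveys is not published, so it is a free parameter; the fixtures use
  ratios between 5:1 and 30:1.

A single root seed spawns per-stage child seeds (`child_seed()`), so each
stage is reproducible independently of how many random draws other stages
consume.

What the generator does *not* emulate: spatial autocorrelation, rasters,
observation error in the covariates, and any real ice or ocean physics.
Passing tests therefore demonstrate that the pipeline's statistics behave
as designed under its own assumptions — not that the ecological conclusions
drawn from the real surveys are correct.

## Numerical choices and edge cases

* VIF: perfect dependence → unbounded flag; constant columns rejected;
  fewer than two remaining covariates stops the filter with a warning.
* Degenerate hold-out fraction 0 → empty test set; evaluation is skipped
  when the test set lacks a class.
* Cross-validation folds with a single training class predict the class
  mean for that fold.
* A zero-boosting-rounds BRT candidate is an explicit constant-0.5 model,
  whose pooled CV $R^2$ is exactly 0 on balanced labels — it can only win a
  tie.
* Maxent: convergence is declared at prox-gradient residual < 1e-6;
  non-convergence warns and names the likely cause (unbounded objective).
  Regularisation → ∞ drives all weights to zero and predictions to the
  constant prevalence.
* All-zero importance members are excluded (and counted) rather than
  force-normalised.

## Known limitations

* **Maxent under a null.** L1 selection on pure-noise data is sparse by
  design: the few surviving features are whatever chance correlations the
  dataset contains, and their proportional importance is near 1 in each
  surviving member. Per-family mean importances for the Maxent member are
  therefore *not* near-uniform under a null generator, even though the raw
  importances are tiny; the tree ensembles, and the cross-model mean the
  CIP ranks on, are near-uniform. Interpret per-family Maxent importance
  with this in mind.
* Hold-out AUC/R² summaries average per-member metrics; they do not
  evaluate a pooled ensemble prediction.
* In-bag permutation importance reflects what the fitted member uses, not
  out-of-sample predictive loss; switch the evaluation table if the latter
  is wanted.
* The expert score sheet is an input. The package validates and averages
  it; it cannot audit the elicitation itself.

## Problem sizes used in the checks

The bundled tests run the full pipeline at reduced scale (tens of
bootstraps, single-candidate grids) and verify the counting arithmetic at
the study's printed sizes: a 4,911-presence table yields a 982 + 982
hold-out and 3,929-presence bootstraps of 7,858 records; a 172-presence
table with a 38-presence hold-out yields 76 test records and 134-presence
bootstraps; 500 bootstraps × 3 families give 1,500 members. The acceptance
script (`scripts/acceptance.R`) reruns the fast-ice-scale analysis in full
— 500 bootstraps, 1,500 members — plus the pack-ice-scale preprocessing, in
a few minutes on one CPU.

## A worked example

```{r example, eval = FALSE}
library(icehab)

cfg <- sim_config(
  n_presence = 300, n_absence = 1500,
  covariate_names = c("ice_edge_dist", "bathy", "ice_sd", "sst", "x5", "x6"),
  driver_coefficients = c(ice_edge_dist = -2, ice_sd = 1.5),
  collinear_pairs = list(list(source = "sst", copy = "sst_copy",
                              noise_sd = 0.05)),
  seed = 1)
ds <- simulate_dataset(cfg)

sheet <- generate_score_sheet(
  c(cfg$covariate_names, "sst_copy"), n_raters = 4, seed = 2,
  forced = c(ice_edge_dist = 3, bathy = 0))

run <- run_species_analysis(
  species_config("demo", ds$table, sheet,
                 n_bootstrap = 50,
                 grids = list(rf = data.frame(mtry = 2, num_trees = 100),
                              brt = data.frame(eta = 0.1, max_depth = 2,
                                               nrounds = 60),
                              maxent = data.frame(reg_mult = 1)),
                 cv_folds = 5, seed = 3))
run$ranking          # covariates by descending change importance product
run$evaluation       # hold-out AUC and R^2 per model family
```
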