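---
title: "Methods: one-step media optimization across donors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-step media optimization across donors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mediaforge)
```

This vignette records the models, assumptions and design choices behind
`mediaforge`. The package implements a one-time optimization pipeline for
cell culture media: a three-level screening design run once on several
donors, per-donor predictive models, a constrained in-silico grid search,
and consensus formulations derived by clustering the pooled top candidates.

## The screening design

For `k` components the definitive screening design (DSD) stacks a conference
matrix `C` (square, zero diagonal, off-diagonal entries ±1, with
`CᵀC = (k−1)I`), its negation `−C` interleaved as fold-over pairs, and one
overall centre run — `2k + 1` runs in total. Two algebraic facts drive its
use here: each factor is at its mid level in exactly three runs (its two
diagonal zeros plus the centre), and the fold-over symmetry makes every
main-effect column exactly orthogonal, in integer arithmetic, to every
quadratic and two-factor-interaction column. Main effects can therefore be
estimated free of aliasing with second-order terms, which is what lets a
single 25-run screen support second-order response-surface models at all.

`build_conference_matrix()` uses the Paley construction for orders
`k = q + 1` with `q` an odd prime — the bordered Jacobsthal matrix of
quadratic-residue characters, with a `−1` border on the column side so the
Gram identity holds in both `q mod 4` classes. Order 10 requires GF(9)
arithmetic and is stored as a verified table; order 16 is built by
skew-Hadamard doubling of the order-8 matrix. Every supported order is
checked against the Gram identity in the tests; unsupported orders raise an
error rather than falling back silently. Any valid DSD is accepted as
equivalent up to column permutation and sign switching; no attempt is made
to reproduce one specific published design instance.

The reference medium is a control of known performance outside the coded
component space. Its rows carry `NA` coded levels, are excluded from all
model features, and receive a scenario-level constant performance in the
simulator. Run order is randomized per donor block under a recorded seed.

## The donor simulator

The study's real measurements are proprietary, so the simulator is a
first-class module, not a test fixture. A *scenario* defines a population of
donor response surfaces: for each response, a second-order polynomial in
coded units

\[ y(x) = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
   \sum_{i<j} \beta_{ij} x_i x_j \]

whose coefficients are population means plus independent Gaussian
donor-specific deviations (per coefficient class), plus Gaussian replicate
noise, with responses clamped to their physical bounds (viability to
[0, 100] %, expansion to non-negative values).

The default scenario (`default_scenario()`) encodes the study regime the
pipeline assumes:

* **Expansion (day 6, abstract "expansion units")**: intercept 25, a few
  strong main effects (2.8, 2.2, −1.8, 1.4, 0.9 on five components),
  negative curvature on the dominant components and two weak interactions.
  Over the design this spans roughly 15–32 units, with the reference medium
  (mean 30) near the top — the regime a well-performing base formulation
  plus a screening range produces.
* **Viability (day 3, %)**: intercept 82 with one designated
  toxic-at-high-level component (`c06`: main −10, curvature −3). Runs with
  that component at its high level fall below 75 % viability and the rest
  sit above it, reproducing the bimodal low/high split around the 75 %
  threshold without leaving the second-order surface family.
* **Replicate noise**: SD 1 (one unit / one percentage point). This anchors
  the attainable model error: a well-specified model's training RMSE sits
  near 1 and R² above 0.9, the regime reported for final screening models
  of this kind.
* **Donor variability**: SDs 1.5–2 on intercepts, 0.6 on mains, 0.2 on
  quadratics, and 0.03–0.05 on interactions. Donor differences are carried
  by terms identifiable from a 25-run DSD (levels, mains, curvature). Large
  deviations on the 66 mutually aliased interaction columns would inject
  variance no model could learn from 25 distinct design points and would
  contradict the stated noise regime, so interaction scatter is kept small.

`planted_scenario()` is the recovery testbed: both responses are concave
quadratics with their vertex at a known `x*` (via
`main = −2 · quad · x*`, curvature 2 on six active components). Its donor
deviations (0.1 on mains, 0.05 on quadratics) keep every donor's true
optimum within a few hundredths of `x*`, because the property being tested
is recovery of a *shared* optimum. A much stronger curvature was considered
and rejected: larger true coefficients weaken the relative penalty in the
elastic net, admit more spurious interaction terms, and tilt model argmaxes
toward the corners of the space.

What the simulator does *not* emulate: mechanistic T-cell biology,
time-course dynamics between the two snapshot responses, correlated donor
deviations, non-Gaussian or heteroscedastic replicate noise, and batch or
plate effects. Passing tests therefore demonstrate that the pipeline's
statistics behave as designed under a faithful second-order world, not that
any particular laboratory medium is optimal.

## Competitive per-donor modelling

Each donor block and response is modelled independently — nine candidates
from three algorithms × three nested equations (`eq1` mains; `eq2` mains +
quadratics; `eq3` full second order, 90 columns at k = 12). Features are
centred and scaled; zero-variance columns are centred only and recorded.

* `fit_ols_stepwise()`: bidirectional stepwise selection from the
  intercept-only model over the equation's term set, minimising
  `AIC = n log(RSS/n) + 2p` with `p` counting coefficients including the
  intercept. Rank-deficient moves are rejected, and the RSS is floored at
  machine scale so an exactly interpolating model stops growing. With a
  penalty of 2 this criterion is deliberately liberal: under a pure-noise
  response it admits the strongest of five spurious predictors roughly half
  the time, which is a property of AIC itself and is tested as such.
* `fit_elastic_net()`: grid search over mixing `alpha ∈ {0, .25, .5, .75, 1}`
  and 50 log-spaced penalties derived from the data, tuned by cross-validated
  RMSE with ties broken toward the larger penalty then larger `alpha` (the
  sparser model); refit on all data at the winner. The `lambda = 0` limit is
  computed by exact least squares rather than coordinate descent.
* `fit_random_forest()`: 500 trees, the per-split candidate-feature fraction
  tuned over {1/3, 1/2, 2/3, 1}. Forest predictions are bounded by the
  training response range by construction.

**Cross-validation.** Metrics come from a seeded 10-fold split with the
scaler re-fit inside every training fold; hyperparameters are tuned on the
same folds and the reported `cv_rmse`/`cv_r2` belong to the selected tune.
By default folds are drawn over *observations*, treating technical
replicates as separate data points — the standard tenfold protocol on a
training table, and the one under which well-specified models reach the
CV-RMSE ≈ 1–1.5 regime the final-model selection assumes. A stricter
run-level protocol (`zoo_config(fold_by = "run")`), in which all replicates
of a design run share a fold, is available; it is the honest estimate of
generalisation to *new formulations*, and is systematically pessimistic on
a DSD because each held-out design point is deliberately unlike the rest.
Users estimating transfer to unseen formulations should prefer it; the
pipeline's selection stage only needs a consistent comparison across
candidates.

**Selection.** One final model per donor × response by ascending CV RMSE,
ties by descending CV R², restricted to the elastic-net and random-forest
candidates: regularised and ensemble learners are preferred over stepwise
OLS for prediction robustness even when an OLS candidate scores better.
Candidate ids follow `b<block>.model<n><e|v>` with `n` enumerating
OLS (1–3), random forest (4–6) and elastic net (7–9).

## Grid search, pooling, consensus

The in-silico search draws each free component independently and uniformly
from the *continuous* interval [−1, 1] — the screen's three levels are
estimation points, not the decision space — while constrained components are
fixed (the study's cost constraint pins `c02` at 0) or bounded. One shared
sample serves all models. Each final model ranks the sample (both responses
maximised; ties by row index for determinism) and its top 40 join the pool
with full provenance, duplicates across models retained: 8 models × 40 =
320 candidates.

The pool is centred and scaled columnwise (the recorded scaler makes
centroid back-transformation exact; the constrained column is centred
only). Diagnostics before clustering: the Hopkins statistic
`H = Σu/(Σu + Σw)` compares nearest-neighbour distances of uniform
pseudo-points in the data bounding box (`u`) against sampled real points
(`w`), at a 10 % sample fraction — ≈ 0.5 means spatially uniform, → 1 means
clustered; it is calibrated against the uniform null in the tests. The
elbow curve reports total within-cluster sum of squares across `k`
(Hartigan–Wong k-means, best of 25 seeded restarts), and silhouette widths
`(b − a)/max(a, b)` with the singleton-cluster convention `s = 0` quantify
cluster integrity. The number of clusters is a config choice (default 6,
read off the elbow as in the original workflow); an automated
largest-relative-drop heuristic exists in the tests but is not the default
because the elbow choice is a judgement call, not an optimum.

Each cluster's medium formulation is the component-wise median of its
members (even counts: midpoint of the central order statistics), which by
construction stays inside the members' range per component. Back-evaluation
predicts every cluster medium in all final models and summarises per
cluster and response by median and IQR across donors. Selection makes the
published rationale executable: clusters whose expansion candidates come
from *all* donors form the top eligibility tier (full representation is the
signal that a formulation family suits every donor); within tiers, ranking
is by back-evaluated median expansion. If fewer clusters than requested are
eligible the selection is filled from the best-ranked remainder with a
warning — the confirmation experiment always receives its configured number
of media.

## Baselines and confirmation

The traditional arm pools all donors' expansion data (donor identity
discarded) into one stepwise-AIC OLS and selects six diverse media by
greedy descent through its ranking subject to a minimum pairwise Chebyshev
separation (default 0.5 coded units; halved with a warning if infeasible).
The ablation arm is the naive ensemble: the component-wise median of the
expansion-filtered pool with no clustering step — definitionally the
one-cluster special case of the consensus construction.

The confirmation experiment simulates fresh test donors from the same
scenario population: selected cluster media + six baseline media + the
reference, one randomized block per test donor (9 × 4 = 36 runs, 3
replicates each). Evaluation averages replicates within donor, then takes
median and IQR across donors, and pairs these with each arm's predictions —
per-donor-model median/IQR for the cluster media, the single pooled-model
value for the baseline media.

## Numerical choices and edge cases

* One master seed deterministically derives every stage seed (a hash-free
  affine map kept below 2³¹); identical configs reproduce byte-identical
  CSV/JSON artifacts, which the tests verify by file hash.
* Elastic-net single-feature inputs are padded with a zero column
  (a backend requirement) and the pad coefficient is dropped.
* `folds > number of runs` degrades to leave-one-out with a warning;
  degenerate (zero-variance) responses raise an error.
* k-means with `k = n` returns the exact zero-WSS solution directly;
  silhouette with all-singleton clusters returns widths of 0 by convention.
* A single-block study skips the pooled baseline and confirmation stages
  (they require ≥ 2 donors) with a warning, still producing per-donor
  finals and a pool.

## Problem sizes used in the checks

The test suite fits one full-scale study (72 candidates, 10-fold CV,
2 × 10⁴-formulation search) for the structural checks, and uses scaled
configurations for replicate-based properties: the elastic-net arm only,
5-fold CV with a reduced tuning grid, and a 10⁴-formulation search, with 20
seeded replicates per property and 50 for the statistical calibrations.
These sizes were chosen so the whole suite exercises every stage many times
on a single CPU; the acceptance script runs the full study-scale pipeline
(10⁵ formulations, all three algorithms).

## Known limitations

* The selection tier rule makes donor coverage a hard priority; with very
  heterogeneous donors no cluster may be donor-complete, and the fallback
  then simply ranks by predicted expansion.
* CV-based ranking compares candidates under a shared split; it does not
  provide an unbiased generalisation estimate for the winner (winner's
  curse), which is why train and CV metrics are both stored.
* The simulator's clamping at response bounds slightly biases surfaces near
  0 or 100 % viability relative to the unbounded polynomial the models
  assume.
* Hopkins and silhouette values depend on the scaling choice; both are
  computed on the same centred/scaled coordinates k-means uses.
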