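---
title: "moodcast: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{moodcast: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodcast)
```

## The problem

`moodcast` builds *personalised* models of a self-rated depressed-mood score.
In digital-phenotyping studies of depression, participants answer ecological
momentary assessments (EMAs) on a phone several times a day — mood and
anxiety on 7-point Likert scales, a short breathing assessment, yesterday's
diet — while a smartwatch passively records heart rate, heart-rate
variability, steps, exercise and sleep. Periodic lab sessions add
neurocognitive scores. The prediction target is the ordinal `depressed`
rating (1 = not depressed … 7 = severely depressed), and because depression
is strongly heterogeneous between people, one model is fitted *per
participant* on that participant's month of data.

The pipeline has four stages, each usable on its own:

1. **Synthetic cohorts** (`cohort_spec()`, `generate_participant()`) —
   seeded participant tables with the statistical structure the pipeline
   assumes, standing in for clinical data that cannot be shared.
2. **Missing-data handling** (`preprocess()`) — three schemes of increasing
   sophistication: deletion, type-aware manual imputation, and automatic
   per-feature imputation selected by a two-sample Kolmogorov–Smirnov
   criterion.
3. **Modelling** (`train_with_cv()`, `run_experiment_grid()`) —
   multilayer-perceptron classification and regression under stratified
   5-fold cross-validation, with the four architecture hyperparameters tuned
   by a suite of evolutionary optimisers.
4. **Explanation** (`rank_features_by_shap()`, `ale_curve()`,
   `find_anchor()`) — post hoc attributions, effect curves, and IF–THEN
   anchor rules, including a before/after rule comparison around anomalous
   mood jumps.

## The synthetic-cohort generator

The generator emulates the study conditions the pipeline is designed for:
four EMA prompts per day (08:00/12:00/16:00/20:00) for 30 days, i.e. 120
rows per participant — comfortably inside the 34–123 sample range typical of
such deployments — with 43 input features: 16 wearable/EMA features carrying
their conventional field names (`anxious`, `distracted`, `past-day-sugars`,
`heart-rate`, `cumm-step-count`, `prev-night-sleep`, `time_of_day`, …) and
27 neurocognitive features. Two neurocognitive names (`GLbias-dACC`,
`fo-leftDLPFC`) are meaningful neural-signal labels; the remaining 25 are
systematic task-by-measure placeholders, because no public schema exists
for the full assessment battery — they claim structure, not fidelity.

Feature processes are deliberately simple: wearable/EMA features follow a
day-level AR(1) latent with within-day jitter, mapped into each feature's
plausible range (discrete features are rounded); neurocognitive features
are piecewise-constant within assessment epochs (lab days 1, 15, 30,
extrapolated forward), mirroring how sparse lab measurements are reconciled
to the EMA cadence; `time_of_day` is the integer prompt slot 0–3.

Labels come from a latent mood score

$$\ell_i \;=\; \sum_f w_f\,\tilde x_{if} \;+\; \varepsilon_i,\qquad
\varepsilon_i \sim N(0, \sigma^2),$$

with standardised features $\tilde x$, the spec'd planted effect weights
$w$, then thresholded into 7 ordinal bins at equal-width cut points on the
standardised latent scale. The `label_skew` parameter shifts all cut points
upward, concentrating mass on the low end of the scale — the imbalance one
sees in mild-to-moderately depressed cohorts, where both scale extremes are
rare. Defaults: a handful of plausible signed effects (anxiety and diet up,
sleep and activity down), `noise_sd = 0.8`, `label_skew = 0.4`,
`missing_rate = 0.05` concentrated in three wearable columns. These defaults
were fixed once as a realistic operating point and are not tuned.

Missingness can be injected cell-wise (MCAR) or in contiguous blocks
(sensor dropout); an injection never leaves a row entirely missing, and the
label series is always complete. A constant-sensor artifact
(`inject_constant_artifact()`) freezes wearable columns to a single value —
only wearable/EMA columns, since constant *cognitive* performance is
plausible real behaviour and must not be faked as a fault.

What the generator does **not** emulate: physiological waveform structure
(PPG, step cadence), circadian rhythms, informative (MNAR) missingness, and
autocorrelated label noise. Tests that pass on this generator therefore
demonstrate algorithmic correctness and recoverability of planted structure,
not clinical validity on real wearable data.

## Missing-data schemes

**Deletion** — if any wearable/EMA feature is constant, the participant is
excluded outright (a month of identical heart-rate readings indicates a
faulty sensor, not a phenotype); otherwise any row with a missing cell is
dropped.

**Manual imputation** — constant wearable features are removed as columns,
then each incomplete feature is filled by type: discrete EMA features with
their mode, continuous features by round-robin regression
(`iterative_impute()`), neurocognitive features with zero (an empty
assessment scores zero).

**Automatic imputation** — every applicable fill method (mean, median,
forward fill, backward fill, linear interpolation, iterative, KNN) is run on
each incomplete feature and scored by the two-sample KS statistic between
the *completed* column and the *observed-only* values; the minimum-KS method
wins. Comparing the full filled column against the observed marginal is the
literal reading of "preserve the original distribution" and penalises fills
that pile mass at a single value (a mean-fill spike) relative to fills that
follow the local trend.

Numerical choices worth knowing:

* `ks_two_sample()` is a direct scan over the union of sample points —
  well defined under ties, which dominate discrete EMA columns (the
  distributional test in `stats::ks.test()` warns on ties; its statistic is
  used as an independent oracle in the tests).
* Forward fill with a leading missing run has nothing to carry, so the
  leading run backfills from the first observation (and symmetrically for
  backward fill); this guarantees completeness.
* `iterative_impute()` initialises with column means, fits each incomplete
  feature by OLS *on the originally complete rows only*, and re-predicts
  missing cells for up to 10 sweeps or until the largest per-cell change on
  the per-column-sd scale drops below `1e-3` — conventional round-robin
  imputer defaults at this data scale. With no complete rows it falls back
  to mean imputation and signals a `moodcast_fallback` condition.
* `knn_impute()` uses `k = 5` and rescales squared distances by
  `p / n_shared` so row pairs sharing few observed features are not
  spuriously close; ties break by row order for determinism.
* Constant-feature detection ignores missing cells: a column observed at a
  single value carries no signal either way.

## The MLP and its training loop

Networks are dense feed-forward stacks whose width profile is defined by
two numbers: the first hidden width and the output width (7 softmax units
for classification, 1 linear unit for regression). Intermediate hidden
widths are linear interpolation between the two, rounded to integers —
so the four tuned hyperparameters (hidden-layer count 2–4, first hidden
width 30–60, activation in {tanh, relu, elu, linear}, batch size in
{4, 6, 8}) fully determine the architecture. This keeps the search space at
3 × 31 × 4 × 3 = 1116 candidates instead of exploding with per-layer widths.

Training is Adam (step 1e-3, β₁ 0.9, β₂ 0.999 — the standard defaults) on
shuffled batches for up to 100 epochs. Classification minimises the sparse
categorical cross-entropy, the mean over samples of −log p(true class), with
probabilities clipped at 1e-12; regression minimises MSE by default, MAE on
request. Because a test fold must never steer training, early stopping
monitors a stratified 15% slice held out *of the training fold* (patience
10 epochs, best-epoch weights retained); with fewer than 20 rows the
training loss itself is monitored. Features are z-scored with the
*population* standard deviation and a zero-variance guard (σ ← 1, mapping
constant columns to zero).

Scaling is fitted on each training fold and applied to its test fold by
default. The alternative of normalising the full table once before
splitting slightly leaks test statistics into training; it remains available
as `paper_faithful_scaling = TRUE` for reproducing workflows that normalise
first, but the leakage-free order is the default.

Stratified 5-fold cross-validation is used for both problem types (the
labels are discrete either way): per-class test counts differ by at most one
across folds, folds are disjoint and exhaustive, and all shuffling is
seeded. Metrics: MAE, MAPE (on the 1–7 scale, which never contains zero, so
the division is safe), MSE, and for classification macro-F1 and balanced
accuracy averaged over the classes present in the true labels. A degenerate
training fold (single class) is flagged and scored worst-case rather than
fitted.

Labels are handled on the 1–7 scale throughout the R interface. Anchor
rules are rendered with the same 1–7 display; any external convention that
displays a 0-based class index is simply an off-by-one of presentation, not
of modelling.

## Hyperparameter search

Eight methods share one harness: candidates live in a continuous
$[0,1]^4$ encoding whose decode maps each coordinate to the nearest valid
value of its dimension. `random` samples uniformly; `one_plus_one` is a
single-parent Gaussian mutator with 1/5th-success step adaptation; `pso`
uses inertia 0.7 and cognitive/social constants 1.5; `de` is rand/1/bin
with F = 0.8, CR = 0.9; `es` is a (μ+λ) strategy with per-individual
self-adaptive step sizes; `cma_es` is a compact covariance-matrix-adaptation
ES; `bayesian` initialises with a Latin hypercube (via the `lhs` package)
and refines around the incumbent with a shrinking Gaussian; `ngopt_like` is
a meta-alias that picks a native method by space size (DE for small
enumerable spaces, CMA-ES otherwise) rather than imitating any external
library's policy. PSO/DE constants are the canonical textbook defaults;
population size defaults to 10 and one "iteration" of budget is one
generation.

Because the decoded space is tiny and exhaustible, fitnesses are cached per
candidate and a proposal that duplicates an already-evaluated candidate
reuses the archive while one *unseen* candidate, drawn uniformly, is
evaluated in its place. This "novelty top-up" keeps the evaluation budget
meaningful: `random` becomes sampling without replacement, and any method
whose budget covers the space provably enumerates it — which is also how
the test suite checks every optimiser against the exhaustive optimum.
Evaluations within a generation are order-independent (the contract a
parallel evaluator needs); results merge deterministically by candidate.

The experiment grid crosses problem type × preprocessing scheme ×
optimisation metric (classification tuned on macro-F1 or balanced accuracy,
maximised; regression on MSE or MAE, minimised) — 12 cells for three
schemes. Each cell keeps each optimiser's best mean 5-fold test objective,
then the best-of-all-optimisers. The overall winner across cells is the one
with the lowest mean test MAE — the only metric shared by both problem
types that reads in absolute scale points; exact ties fall back to lower
MAPE, then to fewer model parameters.

## Explanation stack

All explanation operations consume **un-normalised** data and normalise
inside the model wrapper, so SHAP units, ALE axes and anchor thresholds are
in raw feature units (a heart-rate threshold reads "88.2", not "0.73 sd").
For classification the scalar being explained is the predicted-class
probability of the instance at hand; for regression, the raw output.

* `exact_shapley()` enumerates all 2^p coalitions (capped at p ≤ 14) with
  v(S) = the mean model output over background rows hybridised with the
  instance on S. It exists as the oracle: the axioms (efficiency, dummy,
  symmetry) are asserted on it directly in the tests.
* `kernel_shap()` samples coalition sizes proportional to the Shapley
  kernel, draws coalitions in complementary pairs, and solves the weighted
  least squares with the efficiency constraint eliminated exactly, so
  attributions always sum to f(x) − base. A singular system falls back to a
  ridge solve and signals a condition.
* Feature importance is the fold-averaged mean |SHAP| over each fold's test
  instances, background = up to 100 training rows (seeded subsample),
  restricted by default to the 16 wearable/EMA features — the actionable
  ones for lifestyle intervention — and reported as a top-5.
* `ale_curve()` uses 10 quantile bins by default, accumulates within-bin
  finite differences and centres by the data-weighted mean; fold averaging
  puts all folds on one pooled-quantile grid.
* `find_anchor()` discretises features into quartile bins of the training
  data; candidates are the instance's own bin bounds as ≤/> predicates. The
  search is plain greedy (add the predicate that most raises estimated
  precision, stop at the 0.95 target, the predicate cap, or no improvement)
  with a fixed 1000 perturbations per estimate and common random numbers
  within a round — a deliberate, documented simplification of the
  bandit-based search in the original anchors method, chosen for
  desk-scale determinism. Precision fixes anchored features at the
  instance's values and resamples the rest from training marginals (the
  perturbation distribution is stated because published variants leave it
  implicit); coverage is the fraction of freely resampled points satisfying
  the rule. Rules are returned with their estimates even when the target is
  missed, flagged via `target_met`.
* Anomalous mood jumps default to |Δ| ≥ 2 scale points within 24 h —
  generous enough to capture the textbook patterns of interest (a 2-point
  jump over half a day up to a 4-point jump within hours) while ignoring
  slow drift. `explain_anomaly()` pairs anchor rules before/after a jump
  and only runs where the model classifies both endpoints correctly,
  since a rule for a wrong prediction explains the model's error, not the
  mood change.

## Problem sizes and limitations

The test suite and the acceptance script run everything at desk scale by
the package's own choice: 120-row participants, search budgets of 3–5
generations with populations of 4–12, 15–40 training epochs, 150–500
kernel-SHAP coalitions, 600–1000 anchor perturbations. These sizes keep a
laptop run in minutes while leaving every property checkable; study-scale
runs (budget 100, population 10, 100 epochs, all eight optimisers) use the
same code paths and only larger settings.

Known limitations: ordinality enters classification only through the
evaluation metrics, not the loss (no cumulative-link head); multiple
imputation uncertainty is not propagated; kernel-SHAP backgrounds are
subsampled, so attributions carry Monte-Carlo noise quantified only
indirectly by the oracle tests; anchors are greedy, so a rule is a good —
not provably optimal — anchor; and every explanation is a statement about
the *model*, and about association rather than causation. If the model for
a participant is poor, its explanations inherit that weakness.
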