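---
title: "Predicting and explaining country-level dementia prevalence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and explaining country-level dementia prevalence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Age-standardized prevalence of Alzheimer's disease and other dementias
(PAD, cases per 100,000 people) varies severalfold across countries and is
remarkably stable in time within a country. `padxplain` asks, per calendar
year, how well PAD can be predicted from a panel of *intensive* lifestyle
indicators — country-level variables such as per-capita protein supply,
overweight prevalence or hospital-bed density that are comparable across
countries because they do not scale with population — and, more
importantly, *which* indicators drive each country's prediction. Every year
is modeled independently: dementia prevalence aggregates people at very
different disease stages, and risk factors act on heterogeneous time
scales, so cross-year pooling would mix regimes. The pipeline is

1. gap filling and per-year standardization of the indicator panel;
2. all-relevant feature selection with shadow features around a random
   forest;
3. a cross-year *competition network* summarizing rank instability of the
   yearly importance scores;
4. repeated k-fold cross-validated random-forest regression with
   permutation significance;
5. per-country Shapley attribution of the predictions, with a
   25%-of-total retention rule identifying the dominant indicators.

Because the real indicator panels live in public repositories with
availability that fluctuates by year, the package ships a synthetic-panel
generator with known ground truth; every stage is tested against it.

# Preprocessing

Real panels have two kinds of holes: years outside an indicator's
availability window (structural, never imputed) and scattered gaps inside
the window, on the order of 2% of entries. Each (indicator, country)
series is filled by one of two rules:

- **quadratic fill** — a least-squares quadratic in the year, when the
  series has at least 5 observed values and no run of two or more missing
  entries at either end. We read the end-gap rule as: one missing value at
  an end is allowed and extrapolated; two consecutive are not, because
  quadratic extrapolation over a longer stretch is unstable. The fit is
  computed on centered years for conditioning and is exact on any series
  generated by a polynomial of degree at most two.
- **mean fill** — otherwise, the mean of the observed values of that same
  series. Series with no observation at all are excluded, and their
  country is dropped from the affected year's design matrix.

After filling, each year's indicator distribution over countries is
standardized to mean 0 and variance 1. The variance is the *population*
variance (divide by the number of countries): the year's countries are the
whole modeled population, not a sample from it; a flag switches to the
sample variance. Constant columns are dropped rather than zero-filled so
that downstream selection never sees constant pseudo-features. An
indicator enters a year's matrix only when at least 80% of countries had
an observed value before filling (configurable); availability-based
inclusion is deliberately conservative since mean-filled columns carry no
cross-sectional signal.

# Shadow-feature selection

Selection is an all-relevant wrapper in the Boruta family, written around
`ranger`. At each of `n_iterations` (default 100) iterations the design
matrix is extended with freshly shuffled *shadow* copies of every column —
re-shuffled each iteration, so the shadow null is resampled independently
— and a 500-tree forest with `mtry = floor(p/3)` is fit on the extension.
A feature scores a *hit* when its importance strictly exceeds the maximum
shadow importance of that iteration; ties count as no hit. Hits are
compared with a Binomial(n_iterations, 1/2) reference by two one-sided
binomial tests (select / reject) at level 0.05 with Bonferroni correction
across candidate features (Holm available). Features that remain tentative
are resolved by comparing their median importance over iterations with the
median of the per-iteration maximum shadow importance; the returned
`selected`/`rejected` sets therefore partition the candidates, with the
originally tentative members recorded separately. The importance measure
defaults to mean decrease impurity, matching the regression stage, so that
the yearly importance value attached to every candidate (the mean over
iterations) is on one consistent scale; permutation importance is
available by configuration. Iteration count, level and importance kind are
package defaults, stated here because the procedure is often run with
other conventions.

# The competition network

Yearly importance rankings are unstable in an informative way. For each
pair of features and each year where both carry an importance value, we
record 1 when the first strictly out-ranks the second and 0 otherwise; the
edge weight is the Shannon entropy (base 2, so weights live in (0, 1]
bits) of that binary record. A pair with a constant record — one feature
always dominant, or only a single shared year — has zero entropy and *no
edge*: those features do not compete. Nodes are all features that entered
at least one yearly table, annotated with availability (number of yearly
tables) and mean importance over those years; mean-over-available-years is
used rather than mean-over-all-years so that short-lived indicators are
not penalized twice. In the degree-versus-importance scatter the
informative reading is: low degree + high importance = steadily dominant
predictors; low degree + low importance = steadily irrelevant ones; high
degree = rank-switching middle field.

# Regression protocol

Per year, a random forest (500 trees, `mtry = floor(F/3)`, minimum 1 — the
F/3 rule needs a rounding convention and flooring is the conservative
choice) is evaluated under 5-fold cross-validation repeated 100 times,
each repetition with a fresh seeded partition, so every country has
exactly one out-of-fold prediction per repetition. R², RMSE and MAPE are
computed per repetition on that repetition's pooled out-of-fold
predictions and summarized as mean ± standard deviation across
repetitions (standard error by flag); computing metrics per fold first
would mix fold-size effects into the dispersion. Mean-decrease-impurity
importances are normalized to sum to one within each fold model, averaged
over folds within a repetition, then summarized across repetitions.

Significance of the yearly R² is assessed by permutation: the target is
permuted before each null CV run and the p-value is
`(1 + #{null >= observed}) / (1 + permutations)` (default 1000
permutations; each null run uses one CV repetition, which keeps the null
exchangeable with the observed statistic's ingredients at a fraction of
the cost). The permutation test is chosen over an F-type approximation
because at ~137 countries per year no distributional assumption is needed.
Across-year multiplicity is handled by Bonferroni at level 0.01. Setting
`permutations = 0` skips the test (NA p-value) — useful in large
simulation sweeps.

# Shapley attribution

The attribution of a prediction to the features is the Shapley value of
the cooperative game whose players are features. The package implements it
twice, deliberately:

- `exact_shapley_retrain()` — the literal definition: retrain the model on
  every feature subset and combine marginal contributions with the
  combinatorial weights. This is exponential (capped at 12 features) and
  requires a deterministic trainer, but it is the ground truth against
  which everything else is validated: on noiseless orthogonal designs it
  satisfies efficiency, dummy and symmetry to 1e-8.
- `shapley_marginal_estimate()` — the production path: a single trained
  model and the *marginal* (interventional) value function, where a
  subset's value is the model output averaged over background rows with
  the subset's features set to the instance's values. `exact_subsets` mode
  enumerates all subsets (≤ 15 features, batched into one prediction
  call); `sampled` mode averages marginal contributions over random
  feature permutations paired with random background rows. For a linear
  model both modes reproduce the closed form
  `beta_j * (x_j - mean(background_j))`.

The two value functions (retraining vs. marginal) answer slightly
different questions and agree only approximately on finite data; the test
suite pins their agreement on a deterministic toy to 5% of the target
range. Retraining over subsets inside a 500-fit CV scheme would be
computationally absurd for 30+ features, which is why the marginal path is
the default.

`shap_over_cv()` aggregates over the same seeded CV scheme as the
regression: per repetition, each country's vector is computed from the
fold model that held that country out — the out-of-fold reading avoids
explaining a model with its own training points — with (a subsample of)
that model's training fold as background, since the training fold is the
model's reference distribution. The final matrix is the mean over
repetitions. The retention rule then keeps the features whose mean
absolute Shapley value over countries is strictly larger than 25% of the
total over features ("larger than" read as strict); a direct arithmetic
consequence is that at most three features can ever be retained, and at
most one can exceed 50%.

# The synthetic generator

`generate_panel()` emulates the statistical structure of the real
repositories: per-(country, indicator) polynomial time trends (degree
0–2) plus observation noise on unit-scale indicator levels; contiguous
availability windows with roughly a third of indicators shortened, biased
toward early endings, to mimic the late-year availability drop of real
data; MCAR in-window missingness at 2% (the mechanism of real gaps is
uncharacterized, so the simplest mechanism is used); and a target built
from a known sparse support — linear with effects of 60 PAD units per
standard unit by default, optionally with one pairwise interaction so
that a forest has a regime in which it must beat a linear baseline —
plus Gaussian noise (sd 65) around an intercept of 700 per 100,000. The
default scale mirrors real PAD magnitudes (hundreds per 100,000) so that
RMSE values are comparable in order of magnitude to real-panel results;
with five support features the default signal-to-total-variance ratio is
about 0.8. The generator does *not* emulate spatial correlation between
neighboring countries, informative missingness, or measurement-error
heteroscedasticity; recovery results on synthetic panels are therefore
statements about the machinery, not about real-world attainable accuracy.

# Numerical and design choices

- **Determinism.** Every stochastic step takes a seed; child seeds are
  derived from a master seed with a counter-based hash
  (`derive_seed()`), so per-year analyses are decoupled: adding a year
  never changes another year's results. Reruns are byte-identical.
- **Ties.** Importance ties in the rank comparison count as "not above"
  (the 0 branch); a feature tying with the max shadow scores no hit.
  Equality is exact floating-point comparison on stored importances,
  which are means of finite sums — documented rather than fuzzed.
- **Degenerate inputs.** Constant indicator columns are dropped with a
  warning; all-missing series are excluded and logged; years whose design
  matrix is empty or smaller than `2k` are skipped without aborting the
  run; an empty selected set falls back to the full feature set with a
  warning.
- **Problem sizes in the test suite.** The heavier property checks run at
  137×30 with 50 selector iterations and 500 trees (selector recovery),
  n = 500 for the calibration of the CV estimate, 200 permutations × 50
  seeds for null uniformity, and a 100×10×25 panel with 10 CV repetitions
  for end-to-end recovery — sizes chosen to exercise the full stack on a
  single CPU in minutes.
- **Calibration design.** The check that the mean CV R² matches the
  analytic ceiling `1 - sigma^2/Var(y)` uses a binary feature design whose
  target a tree ensemble can represent exactly. On smooth linear signals a
  finite-n forest sits measurably below the ceiling — that gap measures
  the learner's approximation bias, not a defect of the CV protocol, and
  the protocol is what the calibration is meant to check.

# Known limitations

- The marginal value function ignores feature dependence; with strongly
  correlated indicators, attribution mass can be placed on off-manifold
  evaluations. Conditional (tree-path-dependent) Shapley values are out
  of scope.
- Mean filling flattens within-window dynamics and can only dilute, never
  fabricate, cross-sectional signal; no uncertainty is propagated from
  imputation.
- The selector's binomial test treats iterations as independent; they
  share the data, so the test is calibrated for ranking, not as an exact
  error rate.
- Yearly models are fit independently; the package deliberately makes no
  attempt at temporal smoothing or lagged prediction.
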