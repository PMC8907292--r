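---
title: "Survival-time estimation with evolutionary signature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-time estimation with evolutionary signature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survsig)
```

## The problem

Bulk miRNA-seq profiles of a tumour cohort provide a few hundred mature
miRNA abundances per patient. The goal is a *regression* of survival
time — not merely a risk grouping — from a small subset of those
features: a signature compact enough to interpret and robust enough to
recur when the procedure is repeated. Two things make this hard: the
feature pool (p of order 500) dwarfs typical cohort sizes (n of order
100), and the predictive value of any one miRNA is weak, so subset
selection and model fitting have to be solved together.

`survsig` implements a coupled solution: an RBF-kernel
nu-support-vector regression (nu-SVR) whose feature subset *and*
hyperparameters are selected jointly by an inheritable bi-objective
combinatorial genetic algorithm (IBCGA), robustified across repeated
runs by an appearance score, with an orthogonal-array main-effect
analysis to prioritise the chosen features.

## Data model and conventions

* Expression is a features-by-samples matrix of non-negative normalised
  abundances (`expr_matrix`); `NA` encodes "not detected".
* Candidate features must be present — non-missing and strictly
  positive — in **strictly more than** a presence fraction of samples
  (default 0.7); this is the usual miRNA-seq candidate filter. "Present"
  is not defined by the data format, so the package takes the
  read-count reading: zero means not detected. Missing cells that
  survive the filter are imputed as 0 by default (configurable).
* The internal time unit is **years**; readers accept a declared unit
  and convert once at ingest, so months never leak into the core.
* Follow-up times are right-censored observations: a patient still
  alive at 0.6 years constrains the survival time from below.

## The regression and its fitness

For a feature subset S and hyperparameters (C, gamma, nu), the model is
the standard nu-SVR with RBF kernel, delegated to libsvm (through
e1071). nu-SVR is preferred over epsilon-SVR here because nu has a
bounded, interpretable range — it caps the fraction of support vectors
and tunes the insensitive tube automatically — which makes it easy to
encode in a 4-bit gene.

Performance is measured by

* R² — the squared Pearson correlation between actual and predicted
  survival times, and
* MAE — the mean absolute error in years,

both computed on *pooled* out-of-fold predictions of a 10-fold
cross-validation: each fold is predicted by a model trained on its
complement, and one correlation is computed over all n samples. Pooling
(rather than averaging per-fold R²) matches how a single R² against
"actual vs estimated" survival times is conventionally reported and is
well-defined even for small folds.

When either vector is constant the correlation is undefined; the
package defines R² = 0 there (with a warning) so that optimisation over
model candidates never sees a missing value.

### A pitfall of correlation-squared objectives

Squaring the correlation makes anti-correlated predictions look as good
as correlated ones. That is not hypothetical: an *uninformative* kernel
model shrinks each fold's predictions toward its training mean, and the
training mean of fold k is mechanically anti-correlated with the
held-out fold's mean, so pooled out-of-fold predictions of junk models
have systematically negative correlation with y. During development we
measured r = −0.28 for a constant-per-fold predictor at n = 120 and
k = 10 folds, and an unguarded GA amplified junk feature sets to
r = −0.67 ("fitness" 0.45 on pure noise). The GA fitness therefore
clamps the anti-predictive direction:

> fitness(S, C, gamma, nu) = max(r, 0)² with r the pooled out-of-fold
> correlation.

The *reporting* metric `r_squared()` keeps the symmetric textbook
definition; the clamp only shapes the search. The same guarded fitness
is used by the MED analysis below.

## The IBCGA search

A chromosome is a binary mask of length p (feature in/out) plus three
4-bit genes decoding to

* C = 2^(c−7) ∈ {2⁻⁷, …, 2⁸},
* gamma = 2^(g−8) ∈ {2⁻⁸, …, 2⁷},
* nu = (v+1)/16 ∈ {1/16, …, 1},

powers-of-two grids that span the useful RBF regime; the grids are
configurable. The algorithm maintains exactly r mask bits per
individual and sweeps r from `r_start` to `r_end`:

1. **Initialise** a population with r_start uniformly chosen bits and
   uniform genes.
2. **Evaluate** each individual with the guarded 10-CV fitness. The CV
   partition is drawn once per run from the run seed and reused for
   every evaluation, so fitness values are comparable across
   individuals; fitness values are memoised by (mask, genes).
3. **Select** a mating pool by binary tournaments.
4. **Recombine** pairs by *orthogonal-array crossover*: the positions
   where the parents differ (mask and genes jointly) are grouped into
   at most `max_oa_factors` contiguous factor groups; a two-level
   orthogonal array over the groups enumerates candidate children; the
   per-factor main effects compose a predicted-best child; the two best
   distinct chromosomes among candidates and composed child survive.
   Masks are repaired to exactly r bits by random flips before
   evaluation. On additive fitness landscapes the composed child
   provably equals the exhaustive-recombination optimum, which the test
   suite verifies.
5. **Mutate**: with probability pm one set and one unset bit swap
   (popcount preserved), and each gene is independently resampled with
   probability pm.
6. Elitism keeps the stage best alive; after the configured generations
   (or earlier if the stage stagnates, see below) the stage best is
   recorded and every individual **inherits** to r+1 by switching one
   random 0-bit on.

The run's answer is the best chromosome across stages, with ties broken
by fewer features, then lower r, then first found. This realises the
bi-objective trade-off (accuracy vs signature size) through the r-sweep
and inheritance rather than a Pareto front.

### Robust signature and MED ranking

A single GA run is stochastic, so `run_signature_workflow()` performs
Ns independent runs (Ns = 50 at production scale) and selects the
*robust* signature by the appearance score: with f(m) the number of
run-signatures containing feature m, each run scores
F_i = mean of f over its features, and the run maximising F_i (ties:
fewer features, then lower run index) supplies the signature. The
report carries mean, sample standard deviation, and maximum of the
scores.

The signature's features are then prioritised by **main effect
difference (MED)**: a two-level orthogonal array with one factor per
feature (level 1 = included, level 2 = excluded) induces a set of
subsets; each subset is evaluated with the signature's own
hyperparameters and fold partition (MED measures contribution to the
*reported* model, not to a re-tuned one); the MED of a feature is the
absolute difference of mean fitness between its two levels. Rows that
would induce an empty subset are skipped, and exact ties rank
lexicographically for reproducibility.

## Evaluation toolkit

* **Baselines**: ridge, lasso and elastic net (glmnet) on the full
  filtered pool. The penalty weight is the minimiser of mean CV error
  averaged over `n_rep` (default 100) seeded 10-fold repetitions on a
  common lambda path; metrics come from pooled out-of-fold predictions
  at that weight so the comparison with the SVR is like-for-like.
  Ridge reports all p features as selected; lasso and elastic net
  report their nonzero counts.
* **Diagnostics**: per-feature ROC/AUC by the Mann–Whitney rank
  statistic (ties count one half; direction reported as-is), two-sided
  Wilcoxon rank-sum differential expression (nonparametric default for
  skewed abundances; a t-test is available), and a random-forest
  classifier over a feature subset evaluated by repeated *stratified*
  10-fold CV with metrics at the 0.5 vote threshold, tumor as the
  positive class. Because it is ambiguous whether a "selected after
  repeated CV" figure refers to the mean or the best repetition, the
  classifier reports mean, sd and max, labelled.
* **Prognosis**: Kaplan–Meier curves (survival package) per feature
  after a median split of expression (the split quantile is
  configurable), compared by the log-rank test.
* **Follow-up validation**: for a right-censored follow-up cohort the
  only falsifiable event is a prediction *below* the observed follow-up
  time; the coverage accuracy is the fraction of patients whose
  predicted survival is at least their follow-up time.

## Synthetic cohorts

The generators provide every input the method needs, with ground truth
exposed:

* `simulate_survival_cohort()`: i.i.d. log-normal expression (meanlog 3,
  sdlog 0.6 — count-like positivity and right skew), survival
  `softplus(baseline + sum w_j z_j + noise)` with z the theoretical
  standardisation of the true features' expression. Defaults (n = 106,
  p = 485, baseline 2 y, weights 0.5, noise sd 0.6 y) give times
  spanning roughly 0.05–8 years around a 2-year baseline and an oracle
  R² — the squared correlation between noiseless and noisy times on a
  fresh held-out draw — of about 0.85, an upper bound for any
  estimator's cross-validated fit.
* `simulate_diagnostic_cohort()`: latent-normal mean shifts on selected
  features in the tumor group (theoretical per-feature
  AUC = pnorm(shift/sqrt(2))), defaults mirroring a 418-vs-18
  imbalanced cohort.
* `simulate_followup_cohort()`: scaled-beta follow-up times inside a
  one-year window with a target mean of 5.54/12 years.

What these cohorts deliberately do **not** model: correlation structure
among miRNAs (real signatures contain correlated members), non-linear
or interaction effects on survival, censoring informativeness, and
batch structure. Passing recovery tests on them therefore demonstrates
that the search and scoring machinery works, not that the method will
attain any particular accuracy on real cohorts.

## Numerical choices

* The nu-SVR is always solved by libsvm; for the GA's high eval volume
  the package calls e1071's registered training routine directly and
  computes RBF predictions from the dual coefficients in vectorised R
  (verified identical to e1071::svm to 1e-15). Fitness screening uses a
  slightly relaxed optimizer tolerance (0.01; predictions agree with
  the 0.001 default to ~1e-5 in correlation); user-facing fits keep the
  default.
* Per-fold standardization of features (affine map estimated on the
  training fold only) is the default, as RBF kernels are not
  scale-invariant; a switch disables it. The per-fold statistics depend
  only on the partition, so they are precomputed once per run.
* CV folds are a uniform seeded partition without stratification; LOO
  is available by passing explicit fold ids.
* Degenerate cases: constant targets fit without support vectors and
  predict the bias; empty feature masks score -Inf; constant
  predictions define R² = 0 with a warning.
* Every stochastic routine is a pure function of an explicit integer
  seed; workflows derive per-run seeds as master_seed + run index and
  record them in a manifest sufficient for bit-identical replay.

## Reduced profiles and problem sizes

Production-scale defaults follow the method lineage: population 50, 30
generations per stage, crossover probability 0.8, mutation 0.05, L8
crossover designs, r from 10 to 50, Ns = 50 runs. The package also
ships `ibcga_smoke_config()` — population 12, 5 generations, L4
designs, crossover probability 0.25, early stop after 3 stagnant
generations — used in examples and continuous testing.

The test suite exercises the full pipeline at intermediate scale
(n = 120, p = 150, k = 8 planted features; population 30, 15
generations, r 4–16, Ns = 5 runs per master seed) with a sparing
crossover rate and an early stop after a few stagnant generations.
Whether a stage should run a fixed number of generations or stop on
convergence is genuinely open; the package defaults to fixed
generations with the early stop as an explicit option, because an
elitist stage that has stopped improving only reshuffles the
population. These sizes were chosen so that a full multi-seed recovery
study completes on a single core in minutes while leaving the planted
signal clearly recoverable; all of them scale up by configuration only.

## Known limitations

* The appearance score favours smaller signatures when feature overlap
  is comparable (F_i is a mean); with very heterogeneous run results it
  can select a small, middling-fitness run. Report both the score and
  the fitness, as `compare_methods()` does.
* MED on an L_N array estimates main effects under heavy aliasing with
  interactions; it ranks, it does not test.
* The coverage accuracy is a one-sided check — predicting far beyond
  every follow-up time trivially scores 1 — so it is only meaningful
  alongside MAE/R² on uncensored data.
* The GA fitness clamp removes the anti-predictive failure mode but
  selection bias on the CV estimate remains (fitness of the selected
  model is optimistically biased); treat reported CV R² of a *searched*
  model as an upper estimate, and prefer the independent-cohort checks.
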