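# survsig

Survival-time estimation from high-dimensional expression profiles with
evolutionary signature selection.

`survsig` is for analysts who have a features-by-samples table of
normalised expression values (typically mature miRNA abundances from a
tumour cohort) with per-patient survival times, and who want a *compact,
robust* feature signature together with a regression of survival time —
not just a risk grouping. The core is:

* a **nu-support-vector regression** (RBF kernel, libsvm) of survival
  time on a feature subset,
* an **inheritable bi-objective combinatorial genetic algorithm
  (IBCGA)** that selects the subset and the SVR hyperparameters
  (C, gamma, nu — encoded as three 4-bit genes) jointly, maximising the
  pooled 10-fold cross-validated squared correlation R² between actual
  and predicted survival times while sweeping the signature size r over
  a configured range,
* **orthogonal-array crossover**: candidate children enumerated by a
  two-level orthogonal array over the positions where two parents
  differ, with factor main effects composing a predicted-best child,
* the **appearance score** across Ns independent runs,
  F_i = Σ_t f(miR_it)/m_i (f = how many runs selected that feature),
  whose maximiser is the robust signature,
* **main-effect-difference (MED)** ranking of the signature's features
  on an orthogonal include/exclude design,
* baselines (ridge / lasso / elastic net), diagnostics (rank-based
  ROC/AUC, Wilcoxon differential expression, a random-forest combined
  classifier), prognostics (Kaplan–Meier + log-rank on median-split
  expression), and **coverage accuracy** on right-censored follow-up
  cohorts (fraction of patients whose predicted survival is at least
  the observed follow-up time),
* seeded synthetic-cohort generators with exposed ground truth, so the
  whole pipeline is testable without any external download.

## A worked example

Simulate a cohort of 120 patients with 150 candidate miRNAs of which 8
drive survival, then run a reduced-scale workflow (5 independent GA
runs; production scale would use `ibcga_config()` defaults and
`n_runs = 50`):

```r
library(survsig)

sim <- simulate_survival_cohort(n = 120, p = 150, k = 8, seed = 1)
sim$truth$oracle_r2
#> [1] 0.8479713

cfg <- ibcga_config(pop_size = 30, r_start = 4, r_end = 16,
                    generations = 15, pc = 0.15, pm = 0.05,
                    max_oa_factors = 3, early_stop = 3)
wf <- run_signature_workflow(sim$expression, sim$cohort, n_runs = 5,
                             config = cfg, master_seed = 1000)
wf
#> <sig_workflow> 5 runs; robust signature: 16 features, CV R^2 = 0.834, MAE = 0.384 yr
#> appearance score mean 3.07 +/- 0.18, max 3.31

sum(sim$truth$true_features %in% wf$asc$signature)
#> [1] 8

head(wf$med, 5)
#> # A tibble: 5 x 3
#>    rank feature_id    med
#>   <int> <chr>       <dbl>
#> 1     1 miR-0014   0.216
#> 2     2 miR-0068   0.146
#> 3     3 miR-0021   0.144
#> 4     4 miR-0051   0.139
#> 5     5 miR-0129   0.0937
```

The printed numbers mean: across the 5 runs the appearance scores
averaged 3.07 (out of a maximum of 5 — higher means the runs agree),
and the winning run's signature of 16 features reaches a pooled
out-of-fold R² of 0.83 against an oracle ceiling of 0.85, with a mean
absolute error of 0.38 years; it contains all 8 planted driver
features. `wf$med` ranks the signature members by their marginal
contribution (main effect difference) to that fit — here the five
top-ranked members are all planted drivers — and
`compare_methods(wf)` adds ridge/lasso/elastic-net rows in the
conventional comparison-table layout. `tidy()`, `glance()` and
`autoplot()` methods cover the run, score and curve objects.

A thin command-line driver is installed at `exec/survsig` with
subcommands `simulate`, `run`, `compare`, `diagnose`, `prognose` and
`validate`, configured by a flat YAML file.

## Design notes

The methods vignette (`vignettes/survsig-methods.Rmd`) documents the
model and fitness definition (including the guard against the
anti-predictive degeneracy of correlation-squared CV objectives), the
orthogonal-array constructions, all tunable parameters with their
defaults, what the synthetic cohorts do and do not emulate, and known
limitations.
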