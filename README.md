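# survsig

Survival-supervised discovery and validation of gene-expression
recurrence-risk signatures from heavily censored cohorts.

## The problem

Slowly-recurring tumors (the motivating case is meningioma) yield discovery
cohorts in which 80–86% of patients are censored. survsig turns a
probe-by-sample log2 expression matrix plus a censored outcome table into a
small probe signature with a Favorable / Non-favorable risk classification,
and applies the frozen signature to an independent validation cohort.
It is aimed at computational biologists building or auditing prognostic
expression classifiers.

## The method

With follow-up times `t_i` and event indicators `δ_i`, the covariate-free
martingale residual is `m_i = δ_i − Λ̂(t_i)` (Nelson–Aalen
`Λ̂(t) = Σ_{t_j ≤ t} d_j / n_j`), symmetrized into the deviance residual

    d_i = sign(m_i) · sqrt(−2 [ m_i + δ_i log(δ_i − m_i) ])

which serves as a continuous, censoring-aware response. The pipeline:

1. median scaling and per-probe batch mean-centring;
2. MAD ≥ 0.5 variability filter, then a correlation-radius (0.95) k-means
   redundancy filter;
3. genetic-algorithm probe-subset search over RBF ε-SVR fits of `d`
   (standardized to unit mean square), selected lexicographically by
   Harrell's C, then AIC, BIC, RMSE, with the concordance computed on
   out-of-fold predictions;
4. 50 repeated 10%-holdout cross-validations of the selected model;
5. logistic scores → rank-based inverse-normal transform → single
   CART-style partition cutoff `c`: transformed score > c ⇒ Non-favorable;
6. evaluation: misclassification among recurrences, per-class Kaplan–Meier
   and median RFS, log-rank, univariate and multivariable Cox tables
   (HR, 95% CI, Wald p) against WHO grade, mitotic index, Simpson grade,
   sex and location.

All survival statistics (Nelson–Aalen, KM, log-rank, Breslow Cox,
Harrell's C) are implemented in the package and cross-checked against the
survival package in the tests. A synthetic-study generator with planted
prognostic probes, co-expression blocks, batch effects and calibrated
censoring makes the whole pipeline testable without any external data.

## Worked example

```r
library(survsig)

study <- generate_study(sim_config(), seed = 1)       # 127 + 62 samples
cfg   <- run_config(ga = ga_config(pop_size = 50, generations = 25), seed = 1)
disc  <- run_discovery(study$train$expression, study$train$clinical, cfg)
glance(disc)
#> # A tibble: 1 × 11
#>   n_probes_selected cutoff train_c_index cv_rmse     n events misclassification
#>               <int>  <dbl>         <dbl>   <dbl> <int>  <int>             <dbl>
#> 1                22  0.705         0.942   0.844   127     18             0.278
#> # i 4 more variables: logrank_statistic <dbl>, logrank_p <dbl>, ...

val <- run_validation(disc$model, study$validation$expression,
                      study$validation$clinical)
glance(val)[, c("events", "misclassification", "logrank_p")]
#> # A tibble: 1 × 3
#>   events misclassification logrank_p
#>    <int>             <dbl>     <dbl>
#> 1     14             0.714   0.00855
```

The discovery run selected 22 probes with an out-of-fold training
concordance of 0.94 and a risk cutoff of 0.705 on the transformed score
scale; applied frozen to the 62-sample validation cohort, the Non-favorable
class shows significantly shorter recurrence-free survival (log-rank
p ≈ 0.0086; univariate hazard ratio ≈ 4.3). `tidy(val$evaluation)` prints
the Cox tables and `autoplot(val$evaluation)` draws the per-class
Kaplan–Meier curves.

A thin command-line front end (`inst/scripts/survsig`) exposes `simulate`,
`discover` and `validate` subcommands over the same functions.

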