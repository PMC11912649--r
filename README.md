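# recurreval

Fitting and evaluating prediction models for **recurrent clinical
events** — repeated deteriorations of the same kind in one person, such
as seizures in epilepsy or exacerbations in asthma.  Time-to-first-event
models throw away most of the event history; `recurreval` is for
biostatisticians and epidemiologists who want to model the whole history
and, crucially, to *measure how well the resulting predictions perform*.

## What it implements

Four model classes with a common prediction target, the expected event
count for a subject by a horizon τ:

| Model  | Form | Prediction ŷ(τ) |
|--------|------|------------------|
| NB     | negative binomial counts, log link, log-exposure offset | `E·exp(x'β)` |
| ZINB   | logit structural-zero component π(x) + NB counts | `(1−π(x))·E·exp(x'β)` |
| AG     | Andersen–Gill counting-process Cox intensity | `H₀(τ)·exp(x'β)` |
| PWP-TT | Prentice–Williams–Peterson total-time stratified Cox | Monte-Carlo path sampling over the stratified hazards (or a plug-in sum) |

The Cox machinery (stratified Breslow partial likelihood,
Newton–Raphson, baseline cumulative hazards, subject-clustered
score-residual sandwich = infinitesimal jackknife) is implemented in the
package and verified against `survival::coxph` in the tests.

Performance is evaluated the way the recurrent-event literature does:

* **numerical** — RMSPE `sqrt(mean((y−ŷ)²))`, MAPE `mean(|y−ŷ|)`,
  prediction bias `mean(ŷ−y)` (positive = over-prediction), subgroup
  bias tables, generalized deviance residuals
  `d_i = sign(y−ŷ)·sqrt(2[ℓ_sat − ℓ_fit])`;
* **graphical** — count-calibration curves (observed on x, predicted on
  y, loess smoother with bootstrap band, identity reference) and
  Bland–Altman plots with limits of agreement at `mean(d) ± 1.96·sd(d)`,
  with an advisory when the observed-count range is too narrow for the
  plot to be informative.

Supporting operators cover the field's data-preparation conventions:
merging events within a resolution window (14 days for asthma
exacerbations), capping counts at an empirical quantile (99% for
seizure tallies), constant-rate imputation of event times from
visit-interval counts, log transforms, and counting-process conversion
(AG or PWP-TT).  A gamma-frailty Poisson-process simulator with
structural zeros generates realistic cohorts — presets emulate a
low-event-rate asthma register (~49% event-free over 3 years) and a
high-event-rate epilepsy trial arm (~30% event-free, heavy tail) — so
everything is testable without patient data.

## Worked example

```r
library(recurreval)

cfg <- preset_config("asthma_like", n_subjects = 2000, seed = 42)
ch  <- merge_events(simulate_cohort(cfg)$cohort, window = 14)
tau <- 1095  # 3 years, in days

fits <- list(
  NB       = fit_nb(ch, names(ch$schema), tau),
  ZINB     = fit_zinb(ch, names(ch$schema), names(ch$schema), tau),
  AG       = fit_cox_counting(to_counting_process(ch, "AG", tau)),
  `PWP-TT` = fit_cox_counting(to_counting_process(ch, "PWP-TT", tau)))

report <- evaluate_all(ch, fits, tau, n_draws = 300, seed = 1)
report
```

```
<evaluation_report> horizon 1095 days, 2000 subjects evaluated (reaching_horizon)
  model    rmspe     mape          bias    n
     NB 1.907015 1.375801  6.730161e-04 2000
   ZINB 1.907014 1.375743  1.321435e-04 2000
     AG 1.906722 1.375658  1.108404e-15 2000
 PWP-TT 1.911461 1.370165 -1.711167e-02 2000
best by |rmspe|: AG; |mape|: PWP-TT; |bias|: AG
note: PWP-TT: strata 14..18 have fewer than 5 events; pooled onto stratum 13 for prediction
```

Read it as: all four models predict this simulated low-event-rate cohort
about equally well on RMSPE/MAPE; the AG bias is zero to machine
precision because AG predictions on the fitting data are mean-calibrated
by construction (a property discussed at length in the methods
vignette); sparse-strata pooling for the PWP prediction is surfaced in
the report, not just the log.  The count-calibration curves and
`report$bland_altman` carry the per-model detail.

The same pipeline runs from the command line:

```sh
inst/cli/recurreval run --preset asthma_like --n-subjects 500 \
    --horizon 1095 --seed 7 --out-dir out/
```

writing cohort CSVs, counting-process tables, fit summaries,
predictions, `metrics.csv`, `report.json`, calibration/Bland–Altman
plot data and PNG figures, and a manifest.

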