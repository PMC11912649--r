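---
title: "Models and evaluation methods for recurrent clinical events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and evaluation methods for recurrent clinical events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chronic conditions such as epilepsy and asthma are typified by *recurrent
events* — repeated acute deteriorations of the same kind (seizures,
exacerbations).  Prediction models in this setting are usually built for
the time to the *first* event, discarding most of the event history.
`recurreval` implements four model classes that use the full history, a
common prediction target (the expected number of events for a subject by
a horizon $\tau$), and the numerical and graphical machinery needed to
compare them:

* **NB** — negative binomial regression on per-subject event counts, log
  link, `log(exposure)` offset, variance $\mu + \alpha\mu^2$;
* **ZINB** — a zero-inflated NB mixture: with probability
  $\pi(x) = \operatorname{logit}^{-1}(x^\top\gamma)$ a subject is a
  *structural zero* (no events possible); otherwise counts are NB.
  Zeros contribute $\pi + (1-\pi)\,\mathrm{NB}(0)$, positive counts
  $(1-\pi)\,\mathrm{NB}(y)$;
* **AG** — the Andersen–Gill multiplicative-intensity Cox model on
  counting-process rows $(s, t]$, common baseline hazard for all events;
* **PWP-TT** — the Prentice–Williams–Peterson *total-time* model: a Cox
  model stratified by event order $k$, each stratum on the
  time-since-entry scale, a subject entering stratum $k$ only after event
  $k-1$.

Both Cox variants are fitted by a counting-process partial-likelihood
engine written in this package (Newton–Raphson from $\beta = 0$,
risk sets $\{i : s_i < t \le t_i\}$, Breslow tie handling), with the
inverse observed information as naive covariance and a subject-clustered
score-residual sandwich — the infinitesimal jackknife — as robust
covariance.  `survival::coxph` is used in the test suite only, as an
independent oracle; agreement there is to seven decimals including the
robust standard errors.

## Predicted counts

For count models, $\hat y = (1-\hat\pi(x))\,E\,e^{x^\top\hat\beta}$ with
exposure $E$ (for NB, $\hat\pi \equiv 0$).  For AG,
$\hat y = \hat H_0(\tau)\,e^{x^\top\hat\beta}$, the expected event count
under a multiplicative intensity.  The PWP-TT model has no closed-form
count; `predict_count_pwp()` offers:

* `"montecarlo"` (default): sample event paths — $T_1$ by inverse
  transform from the stratum-1 cumulative hazard
  $\hat H_{01}(t)e^{x^\top\hat\beta}$; given $T_{k-1}$, draw $T_k$ from
  the stratum-$k$ *total-time* hazard conditioned on $T_k > T_{k-1}$
  (i.e. an Exp(1) deviate against
  $e^{x^\top\hat\beta}[\hat H_{0k}(t) - \hat H_{0k}(T_{k-1})]$); the
  prediction is the mean number of events by $\tau$ over `n_draws`
  seeded paths.  This is the statistically faithful reconstruction of
  the sequential stratified hazards.
* `"plugin"`: $\sum_k\bigl(1 - e^{-\hat H_{0k}(\tau)e^{x^\top\hat\beta}}\bigr)$
  — fast, but it ignores the sequential conditioning and is documented
  as an approximation.

Strata with fewer than `min_stratum_events` (default 5) events are
pooled onto the last well-populated stratum for prediction, with a
warning: very sparse strata otherwise make the PWP model look better
than it is.

## Performance measures

With $y_i$ the observed and $\hat y_i$ the predicted count by $\tau$:

* RMSPE $= \sqrt{n^{-1}\sum_i (y_i - \hat y_i)^2}$;
* MAPE $= n^{-1}\sum_i |y_i - \hat y_i|$ — an absolute error in count
  units, *not* a percentage;
* prediction bias $= n^{-1}\sum_i (\hat y_i - y_i)$.

**Sign convention.** Differences are *predicted minus observed*
everywhere (bias and Bland–Altman alike), so positive values mean
over-prediction.  The source literature is not internally consistent on
this point; one convention is fixed here and documented.

Smaller absolute values indicate better fit for all three.  Subgroup
bias tables (`subgroup_bias()`) repeat the bias within each combination
of categorical covariates; the $n$-weighted average of the cells equals
the overall bias exactly, which the tests assert.

Graphical measures:

* **Count-calibration curve** — observed counts on the x-axis, predicted
  on the y-axis (event *probabilities* are meaningless for count
  predictions, hence the count-adapted axes), a local-linear smoother
  (`stats::loess`, degree 1, default span 0.75) over an even grid, a 95%
  pointwise band from a subject-level bootstrap (default B = 200,
  seeded), and the identity line as reference.  With fewer than 10
  distinct observed values the smoother degenerates, so the curve falls
  back to group means per observed count.
* **Bland–Altman** — difference against pairwise mean with limits of
  agreement at the mean difference $\pm 1.96$ sample standard
  deviations.  When observed counts span fewer than 5 distinct values
  (configurable) the object is flagged `suppressed` with an advisory —
  the plot conveys little for low-event-rate data, where deviance
  residuals (`deviance_residuals()`) are the better tool.

Deviance residuals are
$d_i = \operatorname{sign}(y_i - \hat y_i)\sqrt{2[\ell_i(\text{sat}) - \ell_i(\text{fit})]}$
with the saturated per-observation likelihood at $\mu = y_i$ (dispersion
held at its estimate).  For the ZINB no standard saturated model exists;
here $\pi$ is freed per observation, attaining the maximum at the
observed zero/nonzero pattern ($\pi = 1$ for zeros, $\pi = 0$
otherwise).  $\sum d_i^2$ equals the model deviance, which the tests
verify against a brute-force per-point likelihood oracle.

## Data-preparation operators

* `merge_events()` — events within `window` days (the asthma convention
  is 14) of the last *retained* event are treated as non-resolution of
  the initial exacerbation and dropped.  The scan is greedy and anchored
  on retained events, not pairwise chained, because the clinical reading
  is "still the initial event".  "Within" is read as $\le$ `window`.
* `cap_counts()` — per-subject counts capped at an empirical quantile of
  all counts (epilepsy practice caps at the 99% quantile) to draw in the
  extreme tail.  The quantile is the inverse-CDF (type-1) convention,
  stated explicitly because a quantile of a discrete count distribution
  is convention-dependent.  Truncation keeps the *earliest* events,
  preserving the time-to-early-event structure the survival models use.
* `impute_event_times()` — visit-interval counts to event times under a
  constant-rate assumption: $k$ events in $(a, b]$ become $k$ equally
  spaced times $a + j(b-a)/(k+1)$; zero-count intervals yield nothing;
  records carrying exactly recorded times (customary when only one or
  two events occurred between visits) pass them through verbatim.
  Equal spacing was chosen over uniform draws for reproducibility; a
  seeded `"uniform"` mode exists.
* `transform_covariate()` — log (or identity) transform of continuous
  covariates, the transformation conventionally applied across all
  models for comparability.  Zeros are handled by a documented shift
  $\log(x + c)$ with $c$ chosen so the minimum maps to $\log 1 = 0$.
* `to_counting_process()` — expands a cohort into $(s, t]$ rows.  An
  event exactly at the horizon is included (the count target is events
  in $(0, \tau]$); this boundary convention is stated once and used
  everywhere.  Two tied events for one subject are a validation error:
  counting-process rows need positive length, so ties must be merged or
  jittered upstream.

Time is measured in days from each subject's entry (time 0); the
follow-up origin is fixed at entry and documented, since trial-based
data could also count from randomisation or first dose.

## The synthetic-data generator

`simulate_cohort()` draws, per subject: covariates (Bernoulli,
categorical, normal or lognormal), an optional structural-zero flag from
a logit model, a gamma frailty $z$ (mean 1, variance $\theta$), and a
Poisson event process with intensity
$z\,\lambda_0(t)\,e^{x^\top\beta}$ over $(0, T]$, censored
administratively at $T$ (fixed or uniform).  With constant
$\lambda_0$ and no structural zeros the marginal counts are negative
binomial with variance $\mu(1 + \theta\mu)$ — exactly the structure the
count models assume, which is what makes parameter recovery a meaningful
acceptance surface.  A piecewise-constant $\lambda_0$ option breaks the
count models' constant-rate assumption.  One seed feeds one generator
stream; the same configuration and seed reproduce the cohort exactly.

Two frozen presets emulate the published cohort shapes: `"asthma_like"`
(3-year fixed window, ~49% of subjects event-free, mean count ~1.4) and
`"epilepsy_like"` (variable follow-up, ~30% event-free, heavily
right-skewed counts, medians in the tens).  Their baseline rates were
calibrated once, analytically, from the mixture zero probability
$\pi + (1-\pi)(1 + \theta\mu)^{-1/\theta}$ averaged over the covariate
distribution, then frozen.

What the generator does **not** emulate: informative dropout (censoring
correlated with the event process), self-exciting or event-dependent
intensities, covariate measurement error, and calendar-time effects.  A
green parameter-recovery or evaluation test therefore establishes that
the estimators and measures are implemented correctly — not that any
model is adequate for a particular clinical dataset.

## Numerical choices

* NB/ZINB are maximized directly (BFGS) over $(\beta, \log\alpha)$ and
  $(\gamma, \beta, \log\alpha)$; the log scale keeps $\alpha > 0$.  The
  ZINB starts from the NB fit plus a logistic fit on the zero indicator,
  with a no-inflation second start; the better optimum is kept.  Zero
  likelihoods use a log-sum-exp form.  A logit coefficient beyond
  $\pm 10$ triggers a separation warning.
* The Cox engine uses Breslow tie handling (simplest to verify against a
  brute-force partial-likelihood oracle); tie-heavy data triggers a
  note.  Newton steps are halved when the partial likelihood would
  decrease; convergence requires the score's largest entry below 1e-9,
  and every fit exposes its final `score_norm`.
* Robust variance is the grouped score-residual sandwich (infinitesimal
  jackknife); `jackknife_covariance()` provides the exact
  leave-one-subject-out jackknife as a small-$n$ cross-check.
* Baseline-hazard evaluation beyond the last observed time extrapolates
  flat, with a warning surfaced into the evaluation report.
* Evaluation at horizon $\tau$ uses, by default, only subjects whose
  follow-up reaches $\tau$ (their exposure is exactly $\tau$),
  mirroring the practice of predicting at a fixed landmark on the
  subset with complete follow-up; `subset = "all"` keeps everyone with
  truncated exposure.
* Count-model exposure offsets are always included by default: published
  analyses fit counts over nominally fixed windows, but follow-up
  varies in practice, and the offset is the defensible general choice.
  `use_offset = FALSE` reproduces the fixed-window behaviour.
* Exponentiated count-model coefficients are labelled rate ratios (RR);
  parts of the applied literature label the same quantities "odds
  ratios", which is not what a log-linear count model estimates, so the
  package does not propagate that label.  Zero-component coefficients
  are genuine odds ratios (OR) for being a structural zero.

## Known limitations

* **The AG mean-calibration identity.**  On its own fitting data the AG
  model's predicted counts are mean-calibrated essentially by
  construction: the Breslow estimator distributes each event's mass over
  the at-risk set, so summed predictions reproduce observed event totals
  at any horizon all evaluated subjects were followed through (the
  package's tests show bias at machine precision in that case).  A
  consequence: in simulated worlds with censoring independent of the
  event process, the *mean prediction bias* cannot separate AG from a
  well-calibrated competitor, and the published finding that the PWP
  model attains the smallest bias on real data is not reproducible from
  this simulator — it must originate in features the generator
  deliberately excludes (informative dropout above all).  The acceptance
  test encoding that qualitative pattern is kept as stated and fails
  honestly; the count models, whose constant-rate assumption the
  piecewise world does violate, show the expected large bias there.
* PWP-TT predictions under strong frailty carry a small systematic
  under-prediction (~5% in the shipped experiment) from the shared
  $\beta$ across strata and the sparse-stratum pooling; both mechanisms
  are documented above, and the pooling threshold is configurable.
* Monte-Carlo PWP prediction cost grows with subjects × draws × strata;
  very heavy-tailed cohorts (hundreds of strata) are better served by
  `method = "plugin"` or capped counts.
* No discrimination measures (C-index analogues) and no gap-time PWP
  variant are provided, by design.
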