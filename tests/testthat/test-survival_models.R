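library(survival)

# single binary covariate, one spell per subject, event at stop
single_event_table <- function(times, x, event = rep(1L, length(times))) {
  tab <- data.frame(subject_id = sprintf("P%02d", seq_along(times)),
                    start = 0, stop = times, event = event, stratum = 1L,
                    x = x, stringsAsFactors = FALSE)
  structure(tab, class = c("counting_process", "data.frame"),
            representation = "AG", horizon = Inf,
            schema = covariate_schema(x = "binary"))
}

recurrent_sim_table <- function(n = 300, seed = 17, representation = "AG",
                                theta = 0.8) {
  cfg <- simulation_config(
    n_subjects = n,
    covariates = list(x = list(dist = "bernoulli", p = 0.5),
                      z = list(dist = "normal", mean = 0, sd = 1)),
    beta = c(x = 0.4, z = -0.3), baseline_rate = 0.01,
    frailty_variance = theta, follow_up = 300, seed = seed)
  ch <- simulate_cohort(cfg)$cohort
  to_counting_process(ch, representation, Inf)
}

test_that("4-subject fit matches the brute-force 1-D partial likelihood", {
  tab <- single_event_table(times = 1:4, x = c(1, 0, 1, 0))
  fit <- fit_cox_counting(tab)
  # hand-written log partial likelihood: events at t = 1(x=1), 2(x=0),
  # 3(x=1), 4(x=0); risk sets shrink as subjects fail
  pl <- function(b) {
    (b - log(2 * exp(b) + 2)) +
      (0 - log(exp(b) + 2)) +
      (b - log(exp(b) + 1)) +
      (0 - log(1))
  }
  gs <- optimize(pl, c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$coefficients), gs$maximum, tolerance = 1e-6)
  expect_lt(fit$score_norm, 1e-6)
})

test_that("single-event data reduces to the classical Cox fit", {
  set.seed(23)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.6 * x))
  cens <- runif(n, 0, 15)
  obs <- pmin(t, cens)
  d <- as.integer(t <= cens)
  tab <- single_event_table(obs, x, d)
  fit <- fit_cox_counting(tab)
  oracle <- coxph(Surv(obs, d) ~ x, ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(fit$naive_covariance))),
               unname(sqrt(diag(oracle$var))), tolerance = 1e-8)
})

test_that("AG and PWP fits agree with survival::coxph on recurrent data", {
  for (rep_kind in c("AG", "PWP-TT")) {
    tab <- suppressWarnings(recurrent_sim_table(representation = rep_kind))
    fit <- suppressWarnings(fit_cox_counting(tab))
    df <- as.data.frame(tab)
    oracle <- if (rep_kind == "AG") {
      coxph(Surv(start, stop, event) ~ x + z + cluster(subject_id),
            data = df, ties = "breslow")
    } else {
      coxph(Surv(start, stop, event) ~ x + z + strata(stratum) +
              cluster(subject_id), data = df, ties = "breslow")
    }
    expect_equal(unname(fit$coefficients), unname(coef(oracle)),
                 tolerance = 1e-7)
    expect_equal(unname(sqrt(diag(fit$naive_covariance))),
                 unname(sqrt(diag(oracle$naive.var))), tolerance = 1e-7)
    expect_equal(unname(sqrt(diag(fit$robust_covariance))),
                 unname(sqrt(diag(oracle$var))), tolerance = 1e-7)
    expect_lt(fit$score_norm, 1e-6)
    expect_true(fit$converged)
  }
})

test_that("AG coefficient recovery within 3 robust SE at n = 5000", {
  cfg <- simulation_config(
    n_subjects = 5000,
    covariates = list(x = list(dist = "bernoulli", p = 0.5)),
    beta = c(x = 0.5), baseline_rate = 0.008, frailty_variance = 0.5,
    follow_up = 300, seed = 515)
  ch <- simulate_cohort(cfg)$cohort
  tab <- to_counting_process(ch, "AG", Inf)
  fit <- fit_cox_counting(tab)
  se <- sqrt(diag(fit$robust_covariance))
  expect_lt(abs(unname(fit$coefficients["x"]) - 0.5), 3 * se["x"])
})

test_that("Breslow at beta = 0 is exactly Nelson-Aalen", {
  tab <- single_event_table(times = c(1, 2, 3), x = c(1, 0, 1),
                            event = c(1L, 1L, 0L))
  fit <- fit_cox_counting(tab, fixed_beta = 0)
  bh <- breslow_cumhaz(fit)[[1]]
  expect_equal(bh$time, c(1, 2))
  expect_equal(bh$jump, c(1 / 3, 1 / 2))
  expect_equal(bh$cumhaz, c(1 / 3, 1 / 3 + 1 / 2))
})

test_that("doubling every row leaves the baseline hazard unchanged", {
  tab <- suppressWarnings(recurrent_sim_table(n = 80, seed = 31))
  tab2 <- rbind(as.data.frame(tab), within(as.data.frame(tab), {
    subject_id <- paste0(subject_id, "_d")
  }))
  attr(tab2, "schema") <- attr(tab, "schema")
  attr(tab2, "representation") <- "AG"
  f1 <- fit_cox_counting(tab)
  f2 <- fit_cox_counting(tab2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-7)
  expect_equal(breslow_cumhaz(f1)[[1]]$cumhaz,
               breslow_cumhaz(f2)[[1]]$cumhaz, tolerance = 1e-7)
})

test_that("robust SE exceeds naive SE under within-subject correlation", {
  tab <- recurrent_sim_table(n = 800, seed = 47, theta = 1.2)
  fit <- fit_cox_counting(tab)
  expect_true(all(sqrt(diag(fit$robust_covariance)) >
                    sqrt(diag(fit$naive_covariance))))
})

test_that("exact jackknife agrees with the sandwich at small n", {
  tab <- suppressMessages(recurrent_sim_table(n = 40, seed = 53,
                                              theta = 0.5))
  fit <- fit_cox_counting(tab)
  jk <- jackknife_covariance(tab)
  ratio <- sqrt(diag(jk)) / sqrt(diag(fit$robust_covariance))
  expect_true(all(ratio > 0.7 & ratio < 1.5))
})

test_that("empty strata are dropped with a warning", {
  tab <- single_event_table(times = 1:4, x = c(1, 0, 1, 0))
  tab$stratum <- c(1L, 1L, 1L, 2L)
  tab$event[4] <- 0L
  expect_warning(fit_cox_counting(tab), "without events")
})

test_that("predict_count_ag: arithmetic, identity and monotonicity", {
  # arithmetic on a handmade fit: H0(tau) = 0.5, x beta = log 2 -> 1.0
  fit <- structure(list(
    variant = "AG", coefficients = c(x = log(2)),
    baseline_cumhaz = list(`1` = list(stratum = 1, time = c(1, 2),
                                      jump = c(0.2, 0.3),
                                      cumhaz = c(0.2, 0.5), max_time = 3)),
    stratum_events = c(`1` = 10), covariates = "x",
    schema = covariate_schema(x = "binary")),
    class = "survival_model_fit")
  expect_equal(predict_count_ag(fit, data.frame(x = 1), 2.5), 1.0)
  expect_equal(predict_count_ag(fit, data.frame(x = 0), 2.5), 0.5)
  expect_warning(predict_count_ag(fit, data.frame(x = 0), 10),
                 "extrapolating")

  # martingale-mean identity: on the fitting data at full follow-up the
  # mean predicted count equals the mean observed count
  cfg <- simulation_config(
    n_subjects = 600,
    covariates = list(x = list(dist = "bernoulli", p = 0.5)),
    beta = c(x = 0.5), baseline_rate = 0.01, frailty_variance = 0.5,
    follow_up = 250, seed = 616)
  ch <- simulate_cohort(cfg)$cohort
  tab <- to_counting_process(ch, "AG", Inf)
  agfit <- fit_cox_counting(tab)
  yhat <- predict_count_ag(agfit, ch$subjects, 250)
  y <- as.numeric(event_counts(ch))
  expect_equal(mean(yhat), mean(y), tolerance = 1e-6)

  # non-decreasing in tau
  taus <- c(0, 50, 100, 200, 250)
  preds <- vapply(taus, function(tt)
    predict_count_ag(agfit, data.frame(x = 1), tt), numeric(1))
  expect_true(all(diff(preds) >= 0))
})

test_that("predict_count_pwp: closed-form single stratum, tau 0, bound K", {
  # single-stratum PWP: at most one event; both methods share a closed form
  set.seed(71)
  n <- 150
  x <- rbinom(n, 1, 0.5)
  t1 <- rexp(n, 0.05 * exp(0.5 * x))
  obs <- pmin(t1, 20)
  d <- as.integer(t1 <= 20)
  tab <- single_event_table(obs, x, d)
  attr(tab, "representation") <- "PWP-TT"
  fit <- fit_cox_counting(tab)
  bh <- breslow_cumhaz(fit)[[1]]
  tau <- 10
  for (xv in c(0, 1)) {
    closed <- 1 - exp(-recurreval:::eval_cumhaz(bh, tau) *
                        exp(unname(fit$coefficients) * xv))
    plug <- predict_count_pwp(fit, data.frame(x = xv), tau,
                              method = "plugin")
    mc <- predict_count_pwp(fit, data.frame(x = xv), tau,
                            method = "montecarlo", n_draws = 4000,
                            seed = 5)
    expect_equal(plug, closed, tolerance = 1e-10)
    expect_lt(abs(mc - closed), 3 * sqrt(closed * (1 - closed) / 4000))
  }
  expect_equal(predict_count_pwp(fit, data.frame(x = 1), 0,
                                 method = "plugin"), 0)
  expect_error(predict_count_pwp(fit, data.frame(x = 1), 5,
                                 method = "montecarlo"), "seed")

  # multi-stratum: predictions never exceed the number of strata
  tabp <- suppressWarnings(recurrent_sim_table(n = 250, seed = 88,
                                               representation = "PWP-TT"))
  fp <- suppressWarnings(fit_cox_counting(tabp))
  K <- length(breslow_cumhaz(fp))
  pr <- suppressWarnings(
    predict_count_pwp(fp, data.frame(x = c(0, 1), z = c(0, 1)), 300,
                      method = "montecarlo", n_draws = 300, seed = 3))
  expect_true(all(pr <= K))
  expect_true(all(pr >= 0))
})

test_that("montecarlo PWP prediction matches simulation truth", {
  # Poisson process world: every stratum shares the true hazard, so the
  # expected count at tau is rate * tau; the stratified MC path sampler
  # must land within Monte-Carlo error of it
  cfg <- simulation_config(
    n_subjects = 1500,
    covariates = list(x = list(dist = "bernoulli", p = 0.5)),
    beta = c(x = 0.4), baseline_rate = 0.012, frailty_variance = 0,
    follow_up = 300, seed = 717)
  ch <- simulate_cohort(cfg)$cohort
  tab <- to_counting_process(ch, "PWP-TT", Inf)
  fit <- suppressWarnings(fit_cox_counting(tab))
  tau <- 200
  for (xv in c(0, 1)) {
    truth <- 0.012 * exp(0.4 * xv) * tau
    mc <- suppressWarnings(
      predict_count_pwp(fit, data.frame(x = xv), tau,
                        method = "montecarlo", n_draws = 2000, seed = 11))
    # generous band: estimation error + MC error
    expect_lt(abs(mc - truth), 0.15 * truth + 3 * sqrt(truth / 2000))
  }
})

test_that("sparse strata are pooled with a warning", {
  tabp <- suppressWarnings(recurrent_sim_table(n = 60, seed = 97,
                                               representation = "PWP-TT"))
  fp <- suppressWarnings(fit_cox_counting(tabp))
  if (any(fp$stratum_events < 5)) {
    expect_warning(
      predict_count_pwp(fp, data.frame(x = 1, z = 0), 100,
                        method = "plugin"),
      "pooled")
  } else {
    succeed("no sparse stratum in this draw")
  }
})
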