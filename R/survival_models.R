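# Counting-process Cox machinery for recurrent events: stratified partial
# likelihood with Breslow tie handling, Newton-Raphson from beta = 0,
# Breslow baseline cumulative hazards, and a subject-clustered
# score-residual sandwich (infinitesimal jackknife) for robust variance.
# Risk-set membership follows the counting-process convention
# start < t <= stop (left-open, right-closed).

# Per-stratum sufficient statistics at the distinct event times.
# Returns loglik pieces, score, information, and per-event-time quantities
# (S0, S1) needed by the Breslow estimator and the score residuals.
stratum_quantities <- function(start, stop, event, X, w) {
  p <- ncol(X)
  ev_rows <- which(event == 1L)
  times <- sort(unique(stop[ev_rows]))
  E <- length(times)
  S0 <- numeric(E)
  S1 <- matrix(0, E, p)
  dvec <- numeric(E)
  sx <- matrix(0, E, p)       # sum of covariates over events at each time
  info <- matrix(0, p, p)
  loglik <- 0
  U <- numeric(p)

  # two-pointer suffix accumulation, event times processed descending
  os <- order(stop, decreasing = TRUE)
  oa <- order(start, decreasing = TRUE)
  i_s <- 1L; i_a <- 1L
  s0_s <- 0; s1_s <- numeric(p); s2_s <- matrix(0, p, p)
  s0_a <- 0; s1_a <- numeric(p); s2_a <- matrix(0, p, p)
  n <- length(stop)
  ev_at <- split(ev_rows, match(stop[ev_rows], times))

  for (e in seq(E, 1L)) {
    t <- times[e]
    while (i_s <= n && stop[os[i_s]] >= t) {
      r <- os[i_s]
      s0_s <- s0_s + w[r]
      s1_s <- s1_s + w[r] * X[r, ]
      s2_s <- s2_s + w[r] * tcrossprod(X[r, ])
      i_s <- i_s + 1L
    }
    while (i_a <= n && start[oa[i_a]] >= t) {
      r <- oa[i_a]
      s0_a <- s0_a + w[r]
      s1_a <- s1_a + w[r] * X[r, ]
      s2_a <- s2_a + w[r] * tcrossprod(X[r, ])
      i_a <- i_a + 1L
    }
    S0[e] <- s0_s - s0_a
    S1[e, ] <- s1_s - s1_a
    S2_t <- s2_s - s2_a
    rows_e <- ev_at[[as.character(e)]]
    d <- length(rows_e)
    dvec[e] <- d
    sx[e, ] <- colSums(X[rows_e, , drop = FALSE])
    xbar <- S1[e, ] / S0[e]
    loglik <- loglik + sum(log(w[rows_e])) - d * log(S0[e])
    U <- U + sx[e, ] - d * xbar
    info <- info + d * (S2_t / S0[e] - tcrossprod(xbar))
  }
  list(times = times, S0 = S0, S1 = S1, d = dvec, sx = sx,
       loglik = loglik, U = U, info = info)
}

cox_eval <- function(beta, strata_data) {
  p <- length(beta)
  loglik <- 0; U <- numeric(p); info <- matrix(0, p, p)
  per <- vector("list", length(strata_data))
  for (k in seq_along(strata_data)) {
    sd_k <- strata_data[[k]]
    w <- exp(drop(sd_k$X %*% beta))
    q <- stratum_quantities(sd_k$start, sd_k$stop, sd_k$event, sd_k$X, w)
    loglik <- loglik + q$loglik
    U <- U + q$U
    info <- info + q$info
    per[[k]] <- c(q, list(w = w))
  }
  list(loglik = loglik, U = U, info = info, per = per)
}

#' Fit a counting-process Cox model (Andersen-Gill / PWP total time)
#'
#' Maximizes the stratified Cox partial likelihood with Breslow tie
#' handling over the risk sets `{rows with start < t <= stop, same
#' stratum}` by Newton-Raphson from `beta = 0` with step-halving.  The
#' naive covariance is the inverse observed information; the robust
#' covariance is the subject-grouped score-residual sandwich — the
#' infinitesimal-jackknife estimate appropriate for correlated rows within
#' a subject.  With all strata equal to 1 this is the Andersen-Gill model;
#' with stratum = event order it is the Prentice-Williams-Peterson
#' total-time model.
#'
#' @param table A `counting_process` table from [to_counting_process()]
#'   (or any data.frame with columns `subject_id`, `start`, `stop`,
#'   `event`, `stratum` plus covariates and a `schema` attribute).
#' @param covariates Covariate names to include (default: all schema
#'   covariates).
#' @param max_iter,tol Newton-Raphson controls (convergence when the
#'   score's maximum absolute entry falls below `tol`).
#' @param fixed_beta Optional coefficient vector at which to hold the
#'   model (no maximization); with `fixed_beta = 0` the Breslow baseline
#'   is exactly the Nelson-Aalen estimator.
#' @return Object of class `survival_model_fit`: `variant`, `coefficients`,
#'   `naive_covariance`, `robust_covariance`, `baseline_cumhaz` (per
#'   stratum: `time`, `jump`, `cumhaz`), `n_subjects`, `n_events`,
#'   `stratum_events`, `converged`, `loglik`, `score_norm`.
#' @export
fit_cox_counting <- function(table, covariates = NULL, max_iter = 25,
                             tol = 1e-9, fixed_beta = NULL) {
  schema <- attr(table, "schema")
  if (is.null(schema)) stop("table lacks a covariate schema attribute",
                            call. = FALSE)
  if (is.null(covariates)) covariates <- names(schema)
  if (length(covariates) == 0) stop("no covariates to fit", call. = FALSE)
  if (sum(table$event) < 1) stop("need at least one event", call. = FALSE)
  X <- build_design(as.data.frame(table), schema, covariates,
                    intercept = FALSE)
  p <- ncol(X)

  strata_ids <- sort(unique(table$stratum))
  ev_per_stratum <- vapply(strata_ids, function(k) {
    sum(table$event[table$stratum == k])
  }, numeric(1))
  if (any(ev_per_stratum == 0)) {
    warning("dropping stratum/strata without events: ",
            paste(strata_ids[ev_per_stratum == 0], collapse = ", "))
  }
  keep <- strata_ids[ev_per_stratum > 0]
  strata_data <- lapply(keep, function(k) {
    idx <- which(table$stratum == k)
    list(start = table$start[idx], stop = table$stop[idx],
         event = table$event[idx], X = X[idx, , drop = FALSE],
         rows = idx)
  })

  max_d <- max(vapply(strata_data, function(sd_k) {
    ev <- sd_k$stop[sd_k$event == 1L]
    if (length(ev) == 0) 0 else max(table(ev))
  }, numeric(1)))
  if (max_d > 1) {
    message("tied event times present (max multiplicity ", max_d,
            "); Breslow tie handling in use")
  }

  beta <- if (is.null(fixed_beta)) numeric(p) else rep_len(fixed_beta, p)
  ev <- cox_eval(beta, strata_data)
  converged <- !is.null(fixed_beta)
  for (it in if (is.null(fixed_beta)) seq_len(max_iter) else integer(0)) {
    step <- tryCatch(solve(ev$info, ev$U), error = function(e) {
      stop("information matrix is singular (monotone likelihood or ",
           "collinear covariates)", call. = FALSE)
    })
    halve <- 0
    repeat {
      cand <- beta + step / 2^halve
      ev_new <- cox_eval(cand, strata_data)
      if (ev_new$loglik >= ev$loglik - 1e-12 || halve >= 8) break
      halve <- halve + 1
    }
    beta <- cand
    ev <- ev_new
    if (max(abs(ev$U)) < tol) { converged <- TRUE; break }
  }
  if (!converged && max(abs(ev$U)) < 1e-5) converged <- TRUE
  if (is.null(fixed_beta) && any(abs(beta) > 15)) {
    warning("coefficient(s) diverging; likely monotone partial likelihood")
    converged <- FALSE
  }
  names(beta) <- colnames(X)

  naive <- solve(ev$info)
  dimnames(naive) <- list(colnames(X), colnames(X))

  # Breslow baseline cumulative hazards, one step function per stratum
  basehaz <- lapply(seq_along(keep), function(j) {
    q <- ev$per[[j]]
    jump <- q$d / q$S0
    list(stratum = keep[j], time = q$times, jump = jump,
         cumhaz = cumsum(jump),
         max_time = max(strata_data[[j]]$stop))
  })
  names(basehaz) <- as.character(keep)

  # score residuals per row, then grouped by subject for the sandwich
  score_res <- matrix(0, nrow(table), p)
  for (j in seq_along(keep)) {
    sd_k <- strata_data[[j]]
    q <- ev$per[[j]]
    if (length(q$times) == 0) next
    xbar <- q$S1 / q$S0                       # E x p
    a_t <- q$d / q$S0                         # hazard jumps
    b_t <- xbar * a_t                         # E x p
    cum_a <- c(0, cumsum(a_t))
    cum_b <- rbind(0, apply(b_t, 2, cumsum))
    hi <- findInterval(sd_k$stop, q$times)
    lo <- findInterval(sd_k$start, q$times)
    A <- cum_a[hi + 1] - cum_a[lo + 1]
    B <- cum_b[hi + 1, , drop = FALSE] - cum_b[lo + 1, , drop = FALSE]
    w <- q$w
    contrib <- -w * (sd_k$X * A - B)
    is_ev <- sd_k$event == 1L
    if (any(is_ev)) {
      e_idx <- match(sd_k$stop[is_ev], q$times)
      contrib[is_ev, ] <- contrib[is_ev, ] +
        sd_k$X[is_ev, , drop = FALSE] - xbar[e_idx, , drop = FALSE]
    }
    score_res[sd_k$rows, ] <- contrib
  }
  G <- rowsum(score_res, group = as.character(table$subject_id))
  meat <- crossprod(G)
  robust <- naive %*% meat %*% naive
  dimnames(robust) <- dimnames(naive)

  structure(list(
    variant = if (!is.null(attr(table, "representation"))) {
      attr(table, "representation")
    } else if (length(keep) > 1) "PWP-TT" else "AG",
    coefficients = beta,
    naive_covariance = naive,
    robust_covariance = robust,
    baseline_cumhaz = basehaz,
    n_subjects = length(unique(table$subject_id)),
    n_events = sum(table$event),
    stratum_events = stats::setNames(ev_per_stratum[ev_per_stratum > 0],
                                     as.character(keep)),
    converged = converged,
    loglik = ev$loglik,
    score_norm = max(abs(ev$U)),
    covariates = covariates,
    schema = schema
  ), class = "survival_model_fit")
}

#' @export
print.survival_model_fit <- function(x, ...) {
  cat("<survival_model_fit> ", x$variant, ", ", x$n_subjects, " subjects, ",
      x$n_events, " events", if (!x$converged) " [NOT CONVERGED]", "\n",
      sep = "")
  se_n <- sqrt(diag(x$naive_covariance))
  se_r <- sqrt(diag(x$robust_covariance))
  print(data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                   se = se_n, robust_se = se_r, check.names = FALSE))
  invisible(x)
}

#' Breslow baseline cumulative hazard step functions
#'
#' Jump at each distinct event time `t` in stratum `k` of size
#' `d_k(t) / sum_{at risk} exp(x'beta)`.  At `beta = 0` with a single
#' stratum this is exactly the Nelson-Aalen estimator.
#'
#' @param fit A `survival_model_fit`.
#' @return Named list (by stratum) of lists with `time`, `jump`, `cumhaz`.
#' @export
breslow_cumhaz <- function(fit) {
  stopifnot(inherits(fit, "survival_model_fit"))
  fit$baseline_cumhaz
}

# evaluate a stored cumulative-hazard step function, extrapolating flat
eval_cumhaz <- function(bh, t) {
  if (length(bh$time) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, bh$time)
  out <- c(0, bh$cumhaz)[idx + 1]
  out
}

#' Exact leave-one-subject-out jackknife covariance
#'
#' Refits the model dropping one subject at a time; intended as a small-n
#' cross-check of the score-residual (infinitesimal jackknife) sandwich in
#' [fit_cox_counting()].
#'
#' @param table A `counting_process` table.
#' @param covariates Covariates to fit (default: all schema covariates).
#' @return Covariance matrix `sum_g (beta_(-g) - beta_bar)(...)'`.
#' @export
jackknife_covariance <- function(table, covariates = NULL) {
  ids <- unique(table$subject_id)
  fits <- vapply(ids, function(g) {
    sub <- table[table$subject_id != g, , drop = FALSE]
    attr(sub, "schema") <- attr(table, "schema")
    attr(sub, "representation") <- attr(table, "representation")
    fit_cox_counting(sub, covariates)$coefficients
  }, numeric(length(fit_cox_counting(table, covariates)$coefficients)))
  fits <- if (is.matrix(fits)) t(fits) else matrix(fits, ncol = 1)
  center <- colMeans(fits)
  crossprod(sweep(fits, 2, center))
}

fit_linear_predictor <- function(fit, newdata) {
  X <- build_design(as.data.frame(newdata), fit$schema, fit$covariates,
                    intercept = FALSE)
  drop(X %*% fit$coefficients[colnames(X)])
}

#' Predicted event count at a horizon from an Andersen-Gill fit
#'
#' Under the multiplicative-intensity model the expected number of events
#' in `(0, tau]` is `H_0(tau) * exp(x'beta)`.
#'
#' @param fit An AG `survival_model_fit` (single stratum).
#' @param newdata `data.frame` of covariate values.
#' @param tau Horizon in days; beyond the last observed time the baseline
#'   is extrapolated flat, with a warning.
#' @return Numeric vector of expected counts.
#' @export
predict_count_ag <- function(fit, newdata, tau) {
  stopifnot(inherits(fit, "survival_model_fit"))
  if (length(fit$baseline_cumhaz) != 1) {
    stop("predict_count_ag expects a single-stratum (AG) fit", call. = FALSE)
  }
  bh <- fit$baseline_cumhaz[[1]]
  if (tau > bh$max_time) {
    warning("tau = ", tau, " beyond last observed time ", bh$max_time,
            "; extrapolating the baseline hazard flat")
  }
  lp <- fit_linear_predictor(fit, newdata)
  unname(eval_cumhaz(bh, tau) * exp(lp))
}

#' Predicted event count at a horizon from a PWP total-time fit
#'
#' The PWP-TT fit provides one baseline hazard per event-order stratum.
#' `method = "montecarlo"` (the default, statistically faithful) samples
#' event paths: the first event time is drawn from the stratum-1 hazard
#' `H_01(t) exp(x'beta)` by inverse transform on the step function; given
#' the (k-1)-th event at `t`, the k-th is drawn from the stratum-k
#' total-time hazard conditioned on exceeding `t`; the path stops at `tau`
#' or when strata are exhausted, and the prediction is the mean path
#' length.  `method = "plugin"` returns
#' `sum_k (1 - exp(-H_0k(tau) exp(x'beta)))`, which ignores the sequential
#' conditioning and is documented as a fast approximation.  Sparse strata
#' (fewer events than `min_stratum_events`) are pooled into the last
#' well-populated stratum for prediction, with a warning.
#'
#' @param fit A PWP-TT `survival_model_fit`.
#' @param newdata `data.frame` of covariate values.
#' @param tau Horizon in days.
#' @param method `"montecarlo"` or `"plugin"`.
#' @param n_draws Monte Carlo sample size per subject.
#' @param seed Integer seed; required for `"montecarlo"`.
#' @param min_stratum_events Pooling threshold (default 5).
#' @return Numeric vector of expected counts (bounded by the number of
#'   strata).
#' @export
predict_count_pwp <- function(fit, newdata, tau,
                              method = c("montecarlo", "plugin"),
                              n_draws = 1000, seed = NULL,
                              min_stratum_events = 5) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "survival_model_fit"))
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (method == "montecarlo" && is.null(seed)) {
    stop("montecarlo prediction requires a seed", call. = FALSE)
  }
  bhs <- fit$baseline_cumhaz
  K <- length(bhs)
  nev <- fit$stratum_events
  k_keep <- 0
  for (k in seq_len(K)) {
    if (nev[k] >= min_stratum_events) k_keep <- k else break
  }
  if (k_keep == 0) k_keep <- 1
  if (k_keep < K) {
    warning("strata ", k_keep + 1, "..", K, " have fewer than ",
            min_stratum_events,
            " events; pooled onto stratum ", k_keep, " for prediction")
  }
  hazard_for <- function(k) bhs[[min(k, k_keep)]]
  lp <- fit_linear_predictor(fit, newdata)
  if (tau == 0) return(rep(0, length(lp)))

  if (method == "plugin") {
    out <- vapply(seq_along(lp), function(i) {
      sum(vapply(seq_len(K), function(k) {
        1 - exp(-eval_cumhaz(hazard_for(k), tau) * exp(lp[i]))
      }, numeric(1)))
    }, numeric(1))
    return(unname(out))
  }

  set.seed(as.integer(seed))
  out <- numeric(length(lp))
  for (i in seq_along(lp)) {
    elp <- exp(lp[i])
    t_prev <- rep(0, n_draws)
    alive <- rep(TRUE, n_draws)
    counts <- integer(n_draws)
    for (k in seq_len(K)) {
      if (!any(alive)) break
      bh <- hazard_for(k)
      if (length(bh$time) == 0) break
      na <- sum(alive)
      H_prev <- eval_cumhaz(bh, t_prev[alive])
      target <- H_prev + stats::rexp(na) / elp
      idx <- findInterval(target, bh$cumhaz, left.open = TRUE) + 1
      t_new <- rep(Inf, na)
      ok <- idx <= length(bh$time)
      t_new[ok] <- bh$time[idx[ok]]
      success <- t_new <= tau
      w_alive <- which(alive)
      counts[w_alive[success]] <- counts[w_alive[success]] + 1L
      t_prev[w_alive[success]] <- t_new[success]
      alive[w_alive[!success]] <- FALSE
    }
    out[i] <- mean(counts)
  }
  unname(out)
}
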