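# Count-based recurrent-event models: negative binomial and zero-inflated
# negative binomial regression on per-subject event counts at a horizon,
# fitted by direct maximization of the log-likelihood.  The dispersion is
# parameterized as alpha with Var(Y) = mu + alpha*mu^2 (alpha = 1/size) and
# optimized on the log scale for positivity.

nb_loglik_i <- function(y, mu, alpha) {
  if (alpha < 1e-10) {
    stats::dpois(y, mu, log = TRUE)
  } else {
    stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)
  }
}

model_response <- function(x, horizon, use_offset) {
  y <- as.numeric(event_counts(x, horizon))
  exposure <- pmin(x$subjects$follow_up_end, horizon)
  off <- if (use_offset) log(exposure) else rep(0, length(y))
  list(y = y, exposure = exposure, offset = off)
}

#' Fit a negative binomial count model
#'
#' Regresses per-subject event counts in `(0, min(follow_up_end, horizon)]`
#' on covariates with a log link.  By default a `log(exposure)` offset is
#' included so subjects censored before the horizon contribute their
#' observed exposure.  Maximum likelihood over `(beta, log alpha)` via
#' quasi-Newton optimization with a Poisson warm start; standard errors
#' from the observed information.
#'
#' @param x A `recur_cohort`.
#' @param covariates Character vector of covariate names (may be empty for
#'   an intercept-only model).
#' @param horizon Horizon in days (default `Inf` = full follow-up).
#' @param dispersion `NULL` to estimate `alpha`, or a fixed value
#'   (`0` gives the Poisson special case).
#' @param use_offset Include the `log(exposure)` offset (default `TRUE`).
#' @return Object of class `count_model_fit` with elements `model`
#'   (`"NB"`), `count_coefficients`, `dispersion`, `covariance` (over all
#'   free parameters; `log_alpha` last when estimated), `log_likelihood`,
#'   `converged`, `n_used`.
#' @export
fit_nb <- function(x, covariates = character(), horizon = Inf,
                   dispersion = NULL, use_offset = TRUE) {
  stopifnot(inherits(x, "recur_cohort"))
  if (n_subjects(x) < 2) stop("need at least 2 subjects", call. = FALSE)
  r <- model_response(x, horizon, use_offset)
  y <- r$y
  if (all(y == 0)) {
    stop("all observed counts are zero; the count model degenerates",
         call. = FALSE)
  }
  X <- build_design(x$subjects, x$schema, covariates, intercept = TRUE)
  p <- ncol(X)

  warm <- stats::glm.fit(X, y, family = stats::poisson(), offset = r$offset)
  beta0 <- warm$coefficients
  beta0[is.na(beta0)] <- 0

  estimate_alpha <- is.null(dispersion)
  negll <- function(par) {
    beta <- par[seq_len(p)]
    alpha <- if (estimate_alpha) exp(par[p + 1]) else dispersion
    mu <- exp(drop(X %*% beta) + r$offset)
    -sum(nb_loglik_i(y, mu, alpha))
  }
  start <- if (estimate_alpha) c(beta0, log_alpha = log(0.5)) else beta0
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  par <- opt$par
  beta <- par[seq_len(p)]
  names(beta) <- colnames(X)
  alpha <- if (estimate_alpha) unname(exp(par[p + 1])) else dispersion

  H <- stats::optimHess(par, negll)
  cov <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; covariance unavailable")
    matrix(NA_real_, length(par), length(par))
  })
  pn <- c(colnames(X), if (estimate_alpha) "log_alpha")
  dimnames(cov) <- list(pn, pn)

  mu <- exp(drop(X %*% beta) + r$offset)
  grad_norm <- sqrt(sum(numeric_grad(negll, par)^2))
  structure(list(
    model = "NB",
    count_coefficients = beta,
    dispersion = alpha,
    zero_coefficients = NULL,
    covariance = cov,
    log_likelihood = -opt$value,
    converged = opt$convergence == 0 && is.finite(grad_norm),
    n_used = length(y),
    covariates = covariates,
    zero_covariates = NULL,
    schema = x$schema,
    use_offset = use_offset,
    horizon = horizon,
    fitted_mean = mu
  ), class = "count_model_fit")
}

numeric_grad <- function(f, par, eps = 1e-6) {
  vapply(seq_along(par), function(j) {
    h <- eps * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    (f(pp) - f(pm)) / (2 * h)
  }, numeric(1))
}

zinb_negll_factory <- function(y, Xz, Xc, offset) {
  pz <- ncol(Xz); pc <- ncol(Xc)
  is0 <- y == 0
  function(par) {
    gam <- par[seq_len(pz)]
    beta <- par[pz + seq_len(pc)]
    alpha <- exp(par[pz + pc + 1])
    eta_z <- drop(Xz %*% gam)
    mu <- exp(drop(Xc %*% beta) + offset)
    ll <- numeric(length(y))
    ll_nb <- nb_loglik_i(y, mu, alpha)
    # zeros: log(pi + (1 - pi) * NB(0)) via stable log-sum-exp
    lp_pi <- stats::plogis(eta_z, log.p = TRUE)          # log pi
    lp_1mpi <- stats::plogis(-eta_z, log.p = TRUE)       # log(1 - pi)
    a <- lp_pi[is0]
    b <- lp_1mpi[is0] + ll_nb[is0]
    m <- pmax(a, b)
    ll[is0] <- m + log(exp(a - m) + exp(b - m))
    ll[!is0] <- lp_1mpi[!is0] + ll_nb[!is0]
    -sum(ll)
  }
}

#' Fit a zero-inflated negative binomial model
#'
#' Mixture model for counts with excess zeros: with probability
#' `pi(x) = plogis(x'gamma)` a subject is a structural zero (count 0 with
#' certainty); otherwise the count is negative binomial with mean
#' `exp(x'beta + offset)`.  Zeros have likelihood
#' `pi + (1 - pi) * NB(0)`; positive counts `(1 - pi) * NB(y)`.  Fitted by
#' direct joint maximization with two starts (a warm start from the NB fit
#' plus a logistic fit on the zero indicator, and a no-inflation start) —
#' the better optimum is kept.  A logit coefficient exceeding 10 in
#' absolute value triggers a separation warning.
#'
#' @param x A `recur_cohort`.
#' @param count_covariates,zero_covariates Covariate names for the count
#'   (NB) and zero (logit) components.
#' @param horizon,use_offset As in [fit_nb()] (the offset applies to the
#'   count component only).
#' @return Object of class `count_model_fit` with `model = "ZINB"`,
#'   `zero_coefficients` for the logit component, and parameter order
#'   `(gamma, beta, log_alpha)` in `covariance`.
#' @export
fit_zinb <- function(x, count_covariates = character(),
                     zero_covariates = count_covariates, horizon = Inf,
                     use_offset = TRUE) {
  stopifnot(inherits(x, "recur_cohort"))
  r <- model_response(x, horizon, use_offset)
  y <- r$y
  if (all(y == 0)) stop("all observed counts are zero", call. = FALSE)
  Xc <- build_design(x$subjects, x$schema, count_covariates, intercept = TRUE)
  Xz <- build_design(x$subjects, x$schema, zero_covariates, intercept = TRUE)
  pz <- ncol(Xz); pc <- ncol(Xc)

  nb <- fit_nb(x, count_covariates, horizon, use_offset = use_offset)
  logit_warm <- suppressWarnings(
    stats::glm.fit(Xz, as.numeric(y == 0),
                   family = stats::binomial())$coefficients
  )
  logit_warm[is.na(logit_warm)] <- 0
  negll <- zinb_negll_factory(y, Xz, Xc, r$offset)
  starts <- list(
    c(logit_warm, nb$count_coefficients, log(max(nb$dispersion, 1e-3))),
    c(c(-5, rep(0, pz - 1)), nb$count_coefficients,
      log(max(nb$dispersion, 1e-3)))
  )
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      stats::optim(st, negll, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("ZINB optimization failed", call. = FALSE)
  par <- best$par
  gam <- par[seq_len(pz)]; names(gam) <- colnames(Xz)
  beta <- par[pz + seq_len(pc)]; names(beta) <- colnames(Xc)
  alpha <- unname(exp(par[pz + pc + 1]))
  if (any(abs(gam) > 10)) {
    warning("possible separation in the zero (logit) component: ",
            "coefficient(s) exceed 10 in absolute value")
  }
  H <- stats::optimHess(par, negll)
  cov <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; covariance unavailable")
    matrix(NA_real_, length(par), length(par))
  })
  pn <- c(paste0("zero_", colnames(Xz)), colnames(Xc), "log_alpha")
  dimnames(cov) <- list(pn, pn)

  mu <- exp(drop(Xc %*% beta) + r$offset)
  pi0 <- stats::plogis(drop(Xz %*% gam))
  structure(list(
    model = "ZINB",
    count_coefficients = beta,
    dispersion = alpha,
    zero_coefficients = gam,
    covariance = cov,
    log_likelihood = -best$value,
    converged = best$convergence == 0,
    n_used = length(y),
    covariates = count_covariates,
    zero_covariates = zero_covariates,
    schema = x$schema,
    use_offset = use_offset,
    horizon = horizon,
    fitted_mean = (1 - pi0) * mu
  ), class = "count_model_fit")
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat("<count_model_fit> ", x$model, ", n = ", x$n_used,
      ", logLik = ", format(x$log_likelihood),
      ", alpha = ", format(x$dispersion),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  cat("count coefficients:\n"); print(x$count_coefficients)
  if (!is.null(x$zero_coefficients)) {
    cat("zero (logit) coefficients:\n"); print(x$zero_coefficients)
  }
  invisible(x)
}

# per-subject (mu, pi) for a count fit on new covariate data
count_fit_components <- function(fit, newdata, exposure) {
  Xc <- build_design(newdata, fit$schema, fit$covariates, intercept = TRUE)
  off <- if (fit$use_offset) log(exposure) else rep(0, nrow(Xc))
  mu <- exp(drop(Xc %*% fit$count_coefficients) + off)
  pi0 <- if (is.null(fit$zero_coefficients)) {
    rep(0, nrow(Xc))
  } else {
    Xz <- build_design(newdata, fit$schema, fit$zero_covariates,
                       intercept = TRUE)
    stats::plogis(drop(Xz %*% fit$zero_coefficients))
  }
  list(mu = mu, pi = pi0)
}

#' Predicted event count from a count model
#'
#' `NB`: `exposure * exp(x'beta)` (through the model's offset convention);
#' `ZINB`: `(1 - pi(x)) * exposure * exp(x'beta)`.
#'
#' @param fit A `count_model_fit`.
#' @param newdata `data.frame` of covariate values (one row per subject).
#' @param exposure Exposure in days (recycled).
#' @return Numeric vector of predicted counts.
#' @export
predict_count <- function(fit, newdata, exposure) {
  stopifnot(inherits(fit, "count_model_fit"))
  exposure <- rep_len(exposure, nrow(newdata))
  cmp <- count_fit_components(fit, newdata, exposure)
  # without an offset the intercept absorbs the (fixed) fitting window and
  # predictions are per-window; with the offset they scale with exposure
  (1 - cmp$pi) * cmp$mu
}

#' Deviance residuals for a fitted count model
#'
#' `d_i = sign(y_i - yhat_i) * sqrt(2 * (l_i(saturated) - l_i(fitted)))`
#' with the per-observation saturated likelihood evaluated at `mu = y_i`
#' (dispersion held at its estimate).  For the ZINB the saturated model
#' additionally frees `pi` per observation (`pi = 1` for zeros, `pi = 0`
#' for positive counts), attaining the maximum at the observed
#' zero/nonzero pattern.  The sum of squared residuals equals the model
#' deviance.
#'
#' @param fit A `count_model_fit`.
#' @param x The `recur_cohort` the model was fitted to.
#' @param horizon Horizon in days (defaults to the fit's horizon).
#' @return Numeric vector `d_i`, one per subject.
#' @export
deviance_residuals <- function(fit, x, horizon = fit$horizon) {
  stopifnot(inherits(fit, "count_model_fit"), inherits(x, "recur_cohort"))
  r <- model_response(x, horizon, fit$use_offset)
  y <- r$y
  cmp <- count_fit_components(fit, x$subjects, r$exposure)
  alpha <- fit$dispersion
  if (fit$model == "NB") {
    ll_fit <- nb_loglik_i(y, cmp$mu, alpha)
    ll_sat <- ifelse(y == 0, 0, nb_loglik_i(y, y, alpha))
    yhat <- cmp$mu
  } else {
    pi0 <- cmp$pi
    ll_nb <- nb_loglik_i(y, cmp$mu, alpha)
    ll_fit <- ifelse(y == 0,
                     log(pi0 + (1 - pi0) * exp(nb_loglik_i(0, cmp$mu, alpha))),
                     log1p(-pi0) + ll_nb)
    ll_sat <- ifelse(y == 0, 0, nb_loglik_i(y, y, alpha))
    yhat <- (1 - pi0) * cmp$mu
  }
  sign(y - yhat) * sqrt(pmax(0, 2 * (ll_sat - ll_fit)))
}

#' Coefficient table for a fitted count model
#'
#' One row per free coefficient with the exponentiated estimate and a
#' normal-theory confidence interval.  Exponentiated count-component
#' coefficients are labelled rate ratios (`RR`); zero-component
#' coefficients are odds ratios (`OR`) for being a structural zero.
#'
#' @param fit A `count_model_fit`.
#' @param level Confidence level (default 0.95).
#' @return `data.frame` with columns `component`, `term`, `estimate`,
#'   `exp_estimate`, `measure`, `lower`, `upper`.
#' @export
coef_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "count_model_fit"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  pull <- function(component, coefs, prefix, measure) {
    nm_cov <- paste0(prefix, names(coefs))
    se <- sqrt(diag(fit$covariance)[nm_cov])
    data.frame(component = component, term = names(coefs),
               estimate = unname(coefs),
               exp_estimate = exp(unname(coefs)), measure = measure,
               lower = exp(unname(coefs) - z * se),
               upper = exp(unname(coefs) + z * se),
               stringsAsFactors = FALSE)
  }
  rows[["count"]] <- pull("count", fit$count_coefficients, "", "RR")
  if (!is.null(fit$zero_coefficients)) {
    rows[["zero"]] <- pull("zero", fit$zero_coefficients, "zero_", "OR")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
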