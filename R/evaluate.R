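# Numerical and graphical performance measures for recurrent-event
# prediction models: RMSPE, MAPE and prediction bias on per-subject
# observed vs predicted counts, subgroup bias tables, count-calibration
# curves, and Bland-Altman limits of agreement.
#
# Sign convention, fixed once and used everywhere: differences are
# predicted - observed, so positive bias means over-prediction.

#' Assemble a prediction set
#'
#' Pairs each subject's observed event count at the horizon with a model's
#' predicted count, retaining covariates for subgroup summaries.
#'
#' @param x A `recur_cohort` (the evaluation cohort).
#' @param predicted Numeric vector of predicted counts, one per subject in
#'   subjects-table order.
#' @param horizon Horizon in days used for the observed counts.
#' @param model Model label (e.g. `"NB"`, `"PWP-TT"`).
#' @return `data.frame` of class `prediction_set` with columns
#'   `subject_id`, `observed`, `predicted` and the covariates; attributes
#'   `horizon`, `model`, `schema`.
#' @export
prediction_set <- function(x, predicted, horizon, model = "model") {
  stopifnot(inherits(x, "recur_cohort"),
            length(predicted) == n_subjects(x))
  if (any(predicted < 0)) stop("predicted counts must be >= 0",
                               call. = FALSE)
  df <- data.frame(subject_id = x$subjects$subject_id,
                   observed = as.numeric(event_counts(x, horizon)),
                   predicted = as.numeric(predicted),
                   stringsAsFactors = FALSE)
  df <- cbind(df, x$subjects[, names(x$schema), drop = FALSE])
  rownames(df) <- NULL
  structure(df, class = c("prediction_set", "data.frame"),
            horizon = horizon, model = model, schema = x$schema)
}

check_preds <- function(preds, min_n = 1) {
  stopifnot(is.data.frame(preds),
            all(c("observed", "predicted") %in% names(preds)))
  if (nrow(preds) < min_n) {
    stop("need at least ", min_n, " prediction(s)", call. = FALSE)
  }
  invisible(preds)
}

#' Root mean squared prediction error
#'
#' `sqrt(mean((y - yhat)^2))` over subjects; smaller is better.
#' @param preds A [prediction_set()] (any data frame with `observed` and
#'   `predicted` columns works).
#' @return Non-negative scalar.
#' @export
rmspe <- function(preds) {
  check_preds(preds)
  sqrt(mean((preds$observed - preds$predicted)^2))
}

#' Mean absolute prediction error
#'
#' `mean(|y - yhat|)` — an absolute error in count units, not a
#' percentage error.
#' @inheritParams rmspe
#' @return Non-negative scalar.
#' @export
mape <- function(preds) {
  check_preds(preds)
  mean(abs(preds$observed - preds$predicted))
}

#' Prediction bias
#'
#' `mean(yhat - y)`; positive values mean over-prediction.
#' @inheritParams rmspe
#' @return Signed scalar.
#' @export
prediction_bias <- function(preds) {
  check_preds(preds)
  mean(preds$predicted - preds$observed)
}

#' Subgroup prediction bias table
#'
#' Prediction bias within every non-empty combination of the grouping
#' covariates (which must be categorical or binary); empty combinations
#' are omitted.  The n-weighted average of the cell biases equals the
#' overall bias exactly.
#'
#' @param preds A [prediction_set()].
#' @param by Character vector of grouping covariate names.
#' @return `data.frame` with the grouping columns, `bias` and `n`.
#' @export
subgroup_bias <- function(preds, by) {
  check_preds(preds)
  schema <- attr(preds, "schema")
  for (nm in by) {
    if (!nm %in% names(preds)) {
      stop("unknown grouping covariate '", nm, "'", call. = FALSE)
    }
    if (!is.null(schema) && nm %in% names(schema) &&
        schema[[nm]]$type == "continuous") {
      stop("grouping covariate '", nm,
           "' is continuous; bin it before grouping", call. = FALSE)
    }
  }
  key <- interaction(preds[, by, drop = FALSE], drop = TRUE, sep = "\r")
  d <- preds$predicted - preds$observed
  agg_b <- tapply(d, key, mean)
  agg_n <- tapply(d, key, length)
  parts <- do.call(rbind, strsplit(names(agg_b), "\r", fixed = TRUE))
  out <- data.frame(parts, bias = as.numeric(agg_b),
                    n = as.integer(agg_n), stringsAsFactors = FALSE)
  names(out)[seq_along(by)] <- by
  rownames(out) <- NULL
  out
}

#' Count-calibration curve
#'
#' Calibration adapted to event counts: observed counts on the x-axis,
#' predicted counts on the y-axis, with a local-linear smoother
#' (`stats::loess`, degree 1) of predicted on observed evaluated over an
#' evenly spaced grid, a 95% pointwise band from a subject-level
#' bootstrap, and the identity line as the reference of perfect
#' calibration.  With fewer than 10 distinct observed values the smoother
#' is replaced by group means at each observed count.
#'
#' @param preds A [prediction_set()] with at least 10 subjects.
#' @param span Loess span (default 0.75).
#' @param n_boot Bootstrap replicates for the band (default 200).
#' @param seed Integer seed for the bootstrap.
#' @param grid_n Grid size (default 40).
#' @return Object of class `calibration_curve`: list with `points`
#'   (raw observed/predicted), `grid`, `fitted`, `lower`, `upper`,
#'   `method` (`"loess"` or `"group_means"`).
#' @export
calibration_curve <- function(preds, span = 0.75, n_boot = 200, seed = 1,
                              grid_n = 40) {
  check_preds(preds, min_n = 10)
  y <- preds$observed
  yhat <- preds$predicted
  distinct <- sort(unique(y))
  use_loess <- length(distinct) >= 10

  if (use_loess) {
    grid <- seq(min(y), max(y), length.out = grid_n)
    smooth_once <- function(yy, hh) {
      fit <- suppressWarnings(stats::loess(hh ~ yy, span = span, degree = 1,
                                           family = "gaussian"))
      suppressWarnings(stats::predict(fit, newdata = data.frame(yy = grid)))
    }
  } else {
    grid <- distinct
    smooth_once <- function(yy, hh) {
      m <- tapply(hh, factor(yy, levels = distinct), mean)
      as.numeric(m)
    }
  }
  fitted <- smooth_once(y, yhat)
  set.seed(as.integer(seed))
  n <- length(y)
  boot <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- smooth_once(y[idx], yhat[idx])
  }
  lower <- apply(boot, 2, stats::quantile, probs = 0.025, na.rm = TRUE)
  upper <- apply(boot, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
  structure(list(points = data.frame(observed = y, predicted = yhat),
                 grid = grid, fitted = fitted, lower = lower, upper = upper,
                 method = if (use_loess) "loess" else "group_means",
                 model = attr(preds, "model")),
            class = "calibration_curve")
}

#' Bland-Altman agreement data
#'
#' For each subject the mean `m_i = (y_i + yhat_i)/2` and difference
#' `d_i = yhat_i - y_i`; the limits of agreement are the mean difference
#' plus/minus 1.96 sample standard deviations (n-1 denominator), between
#' which about 95% of differences are expected to lie under normality.
#' When the observed counts span fewer than `min_distinct` distinct
#' values the plot conveys little (many stacked points, discrete bands)
#' and the result is flagged `suppressed` with an advisory — the numbers
#' are still returned.
#'
#' @param preds A [prediction_set()] with at least 2 subjects.
#' @param min_distinct Distinct-observed-value threshold below which the
#'   advisory is raised (default 5).
#' @return Object of class `bland_altman`: list with `mean`, `difference`
#'   (vectors), `mean_difference`, `sd_difference`, `lower_limit`,
#'   `upper_limit`, `multiplier` (1.96), `suppressed`, `advisory`.
#' @export
bland_altman <- function(preds, min_distinct = 5) {
  check_preds(preds, min_n = 2)
  y <- preds$observed
  yhat <- preds$predicted
  d <- yhat - y
  m <- (y + yhat) / 2
  dbar <- mean(d)
  s <- stats::sd(d)
  distinct <- length(unique(y))
  suppressed <- distinct < min_distinct
  structure(list(
    mean = m, difference = d, mean_difference = dbar, sd_difference = s,
    lower_limit = dbar - 1.96 * s, upper_limit = dbar + 1.96 * s,
    multiplier = 1.96,
    suppressed = suppressed,
    advisory = if (suppressed) {
      paste0("Bland-Altman is of limited value here: only ", distinct,
             " distinct observed values (threshold ", min_distinct,
             "); consider deviance residuals instead")
    } else {
      NA_character_
    },
    model = attr(preds, "model")
  ), class = "bland_altman")
}

# dispatch a fitted model to its prediction operation
model_predictions <- function(fit, x, horizon, exposure,
                              pwp_method = "montecarlo", n_draws = 1000,
                              seed = 1) {
  nd <- x$subjects
  if (inherits(fit, "count_model_fit")) {
    predict_count(fit, nd, exposure)
  } else if (inherits(fit, "survival_model_fit")) {
    if (fit$variant == "AG") {
      predict_count_ag(fit, nd, horizon)
    } else {
      predict_count_pwp(fit, nd, horizon, method = pwp_method,
                        n_draws = n_draws, seed = seed)
    }
  } else {
    stop("unknown fit class", call. = FALSE)
  }
}

#' Evaluate several fitted models on one cohort
#'
#' Builds a [prediction_set()] for each fitted model at the horizon and
#' assembles the model-comparison report: RMSPE, MAPE and prediction bias
#' per model, the best model per metric (smallest absolute value),
#' deviance-residual summaries for the count models, plus calibration and
#' Bland-Altman data.  By default only subjects whose follow-up reaches
#' the horizon are evaluated (their exposure is exactly `horizon`);
#' `subset = "all"` keeps everyone with exposure truncated at their
#' follow-up end.
#'
#' @param x A `recur_cohort`.
#' @param fits Named list of `count_model_fit` / `survival_model_fit`
#'   objects fitted to (a superset of) this cohort.
#' @param horizon Evaluation horizon in days.
#' @param subset `"reaching_horizon"` (default) or `"all"`.
#' @param pwp_method,n_draws,seed Passed to [predict_count_pwp()].
#' @param span,n_boot Passed to [calibration_curve()].
#' @param ba_min_distinct Passed to [bland_altman()].
#' @return Object of class `evaluation_report`: list with `metrics`
#'   (data.frame model/rmspe/mape/bias/n), `best` (named list per
#'   metric), `prediction_sets`, `calibration`, `bland_altman`,
#'   `deviance_summary`, `horizon`, `n_evaluated`, `warnings`.
#' @export
evaluate_all <- function(x, fits, horizon,
                         subset = c("reaching_horizon", "all"),
                         pwp_method = "montecarlo", n_draws = 1000,
                         seed = 1, span = 0.75, n_boot = 200,
                         ba_min_distinct = 5) {
  subset <- match.arg(subset)
  stopifnot(inherits(x, "recur_cohort"), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    stop("fits must be a named list", call. = FALSE)
  }
  for (f in fits) {
    h <- if (inherits(f, "count_model_fit")) f$horizon else NULL
    if (!is.null(h) && is.finite(h) && is.finite(horizon) && h != horizon) {
      stop("fit horizon ", h, " does not match evaluation horizon ",
           horizon, call. = FALSE)
    }
  }
  keep <- if (subset == "reaching_horizon" && is.finite(horizon)) {
    x$subjects$follow_up_end >= horizon
  } else {
    rep(TRUE, n_subjects(x))
  }
  ev_cohort <- x
  ev_cohort$subjects <- x$subjects[keep, , drop = FALSE]
  ev_cohort$events <- x$events[ev_cohort$subjects$subject_id]
  exposure <- pmin(ev_cohort$subjects$follow_up_end, horizon)

  warn <- character(0)
  psets <- list()
  rows <- list()
  calib <- list()
  ba <- list()
  devsum <- list()
  for (nm in names(fits)) {
    pred <- withCallingHandlers(
      model_predictions(fits[[nm]], ev_cohort, horizon, exposure,
                        pwp_method, n_draws, seed),
      warning = function(w) {
        warn <<- c(warn, paste0(nm, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    ps <- prediction_set(ev_cohort, pred, horizon, model = nm)
    psets[[nm]] <- ps
    rows[[nm]] <- data.frame(model = nm, rmspe = rmspe(ps), mape = mape(ps),
                             bias = prediction_bias(ps), n = nrow(ps),
                             stringsAsFactors = FALSE)
    calib[[nm]] <- if (nrow(ps) >= 10) {
      calibration_curve(ps, span = span, n_boot = n_boot, seed = seed)
    }
    ba[[nm]] <- bland_altman(ps, min_distinct = ba_min_distinct)
    if (isTRUE(ba[[nm]]$suppressed)) {
      warn <- c(warn, paste0(nm, ": ", ba[[nm]]$advisory))
    }
    if (inherits(fits[[nm]], "count_model_fit")) {
      d <- deviance_residuals(fits[[nm]], ev_cohort, horizon)
      devsum[[nm]] <- c(mean = mean(d), sd = stats::sd(d),
                        min = min(d), max = max(d),
                        deviance = sum(d^2))
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  best <- list(
    rmspe = metrics$model[which.min(abs(metrics$rmspe))],
    mape = metrics$model[which.min(abs(metrics$mape))],
    bias = metrics$model[which.min(abs(metrics$bias))]
  )
  structure(list(metrics = metrics, best = best, prediction_sets = psets,
                 calibration = calib, bland_altman = ba,
                 deviance_summary = devsum, horizon = horizon,
                 n_evaluated = sum(keep), subset = subset,
                 warnings = warn),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> horizon ", x$horizon, " days, ",
      x$n_evaluated, " subjects evaluated (", x$subset, ")\n", sep = "")
  print(x$metrics, row.names = FALSE)
  cat("best by |rmspe|: ", x$best$rmspe, "; |mape|: ", x$best$mape,
      "; |bias|: ", x$best$bias, "\n", sep = "")
  for (w in x$warnings) cat("note: ", w, "\n", sep = "")
  invisible(x)
}

#' Serialize an evaluation report's numerical content to JSON
#'
#' Writes metrics, best-model labels, Bland-Altman summaries and
#' deviance summaries with 17 significant digits so that a read back via
#' [read_evaluation_metrics()] is lossless.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  payload <- list(
    horizon = report$horizon,
    n_evaluated = report$n_evaluated,
    subset = report$subset,
    metrics = report$metrics,
    best = report$best,
    bland_altman = lapply(report$bland_altman, function(b) {
      b[c("mean_difference", "sd_difference", "lower_limit", "upper_limit",
          "multiplier", "suppressed")]
    }),
    deviance_summary = lapply(report$deviance_summary, as.list),
    warnings = report$warnings
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read back the numerical content of a serialized evaluation report
#' @param path Path written by [write_evaluation_report()].
#' @return List mirroring the serialized payload, with `metrics` as a
#'   data.frame.
#' @export
read_evaluation_metrics <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$metrics <- as.data.frame(payload$metrics,
                                   stringsAsFactors = FALSE)
  payload
}
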