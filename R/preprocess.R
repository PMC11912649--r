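#' Merge events occurring within a resolution window
#'
#' In exacerbation data, events recorded within a short window of a
#' preceding event are treated as lack of resolution of the initial event
#' rather than a new one (the asthma convention uses 2 weeks = 14 days).
#' The scan is greedy and anchored on retained events: walking left to
#' right, an event is dropped when it falls at most `window` days after the
#' last *retained* event.  The result has all gaps strictly greater than
#' `window` and the operation is idempotent.
#'
#' @param x A numeric vector of increasing event times, or a
#'   `recur_cohort` (merging is then applied to every subject).
#' @param window Non-negative merge window in days; `0` leaves input
#'   unchanged (tied times excepted).
#' @return Same type as `x`.
#' @export
merge_events <- function(x, window) {
  stopifnot(is.numeric(window), length(window) == 1L, window >= 0)
  if (inherits(x, "recur_cohort")) {
    x$events <- lapply(x$events, merge_times, window = window)
    validate_cohort(x)
    return(x)
  }
  merge_times(as.numeric(x), window)
}

merge_times <- function(t, window) {
  if (length(t) <= 1L) return(t)
  keep <- t[1]
  anchor <- t[1]
  for (ti in t[-1]) {
    if (ti - anchor > window) {
      keep <- c(keep, ti)
      anchor <- ti
    }
  }
  keep
}

#' Cap per-subject event counts at an empirical quantile
#'
#' To draw in the extreme tail of heavily skewed count distributions, each
#' subject's events are truncated to at most the empirical `quantile` of
#' all per-subject counts (e.g. seizure counts capped at the 99% quantile).
#' The quantile is the inverse-CDF (type-1) convention: the smallest
#' observed count with cumulative frequency at least `quantile`, with no
#' interpolation.  Truncation keeps the *earliest* events, preserving the
#' time-to-early-event structure used by the survival models.
#'
#' @param x A `recur_cohort`.
#' @param quantile Fraction in `(0, 1]`; `1` caps at the maximum (no-op).
#' @return List with elements `cohort` (capped `recur_cohort`) and `cap`
#'   (the cap value, an integer count).
#' @export
cap_counts <- function(x, quantile = 0.99) {
  stopifnot(inherits(x, "recur_cohort"))
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile > 1) {
    stop("quantile must be in (0, 1]", call. = FALSE)
  }
  if (n_subjects(x) == 0L) stop("cohort is empty", call. = FALSE)
  counts <- lengths(x$events)
  sorted <- sort(counts)
  cap <- sorted[ceiling(quantile * length(sorted))]
  x$events <- lapply(x$events, function(t) {
    if (length(t) > cap) t[seq_len(cap)] else t
  })
  list(cohort = x, cap = as.integer(cap))
}

#' Impute event times from interval-reported counts
#'
#' Visit-based studies record a count of events per inter-visit interval;
#' fitting time-based models then requires imputed event dates.  Assuming a
#' constant event rate within the interval, a count of `k > 0` in `(a, b]`
#' yields `k` equally spaced times `a + j*(b-a)/(k+1)`, `j = 1..k`,
#' strictly inside the interval.  Intervals with zero events yield nothing.
#' When a record carries exact recorded times (conventionally kept when
#' only one or two events occurred between visits), those are used verbatim
#' instead of imputing.  A seeded `"uniform"` mode draws order statistics
#' of Uniform(a, b) instead of the deterministic equal spacing.
#'
#' @param records An [interval_counts()] data frame for a single subject.
#' @param mode `"equal_spacing"` (default, deterministic) or `"uniform"`.
#' @param seed Integer seed, required for `mode = "uniform"`.
#' @return Sorted numeric vector of event times.
#' @export
impute_event_times <- function(records, mode = c("equal_spacing", "uniform"),
                               seed = NULL) {
  mode <- match.arg(mode)
  validate_interval_counts(records)
  if (length(unique(records$subject_id)) > 1L) {
    stop("impute_event_times expects records for a single subject",
         call. = FALSE)
  }
  if (mode == "uniform") {
    if (is.null(seed)) stop("uniform mode requires a seed", call. = FALSE)
    set.seed(as.integer(seed))
  }
  records <- records[order(records$interval_start), , drop = FALSE]
  out <- numeric(0)
  for (i in seq_len(nrow(records))) {
    k <- records$count[i]
    if (k == 0L) next
    a <- records$interval_start[i]
    b <- records$interval_end[i]
    exact <- records$exact_times[i]
    if (!is.na(exact) && nzchar(exact)) {
      t <- as.numeric(strsplit(exact, ";", fixed = TRUE)[[1]])
      if (length(t) != k) {
        stop("record ", i, ": exact_times length ", length(t),
             " does not match count ", k, call. = FALSE)
      }
      out <- c(out, sort(t))
    } else if (mode == "equal_spacing") {
      out <- c(out, a + seq_len(k) * (b - a) / (k + 1))
    } else {
      out <- c(out, sort(stats::runif(k, a, b)))
    }
  }
  out
}

#' Transform a continuous covariate
#'
#' Adds a transformed copy of a continuous covariate (suffix `"_log"` for
#' log; `"_linear"` is the identity, provided so model formulas can name
#' the transform explicitly).  For the log transform all values must be
#' positive; when zeros are present a documented shift `log(x + c)` is
#' applied with `c` chosen so that `min(x) + c = 1` (hence a zero minimum
#' maps to `log(1) = 0`).
#'
#' @param x A `recur_cohort`.
#' @param name Covariate name (must be declared continuous).
#' @param transform `"log"` or `"linear"`.
#' @param shift `NULL` to forbid shifting (non-positive values then error),
#'   `"auto"` to apply the minimum-to-one rule when needed, or an explicit
#'   numeric shift `c`.
#' @return The cohort with the new column appended to the subjects table
#'   and registered as continuous in the schema; the original column is
#'   retained.  The applied shift is attached as attribute `"shift"` of
#'   the returned cohort.
#' @export
transform_covariate <- function(x, name, transform = c("log", "linear"),
                                shift = NULL) {
  transform <- match.arg(transform)
  stopifnot(inherits(x, "recur_cohort"))
  if (!name %in% names(x$schema)) {
    stop("unknown covariate '", name, "'", call. = FALSE)
  }
  if (x$schema[[name]]$type != "continuous") {
    stop("covariate '", name, "' is not continuous", call. = FALSE)
  }
  v <- x$subjects[[name]]
  newname <- paste0(name, "_", transform)
  applied_shift <- 0
  if (transform == "log") {
    if (any(v <= 0, na.rm = TRUE)) {
      if (is.null(shift)) {
        stop("covariate '", name, "' has non-positive values; ",
             "supply shift = \"auto\" or a numeric shift", call. = FALSE)
      }
      applied_shift <- if (identical(shift, "auto")) {
        1 - min(v, na.rm = TRUE)
      } else {
        as.numeric(shift)
      }
      if (any(v + applied_shift <= 0, na.rm = TRUE)) {
        stop("shift ", applied_shift, " leaves non-positive values",
             call. = FALSE)
      }
    } else if (is.numeric(shift)) {
      applied_shift <- shift
    }
    x$subjects[[newname]] <- log(v + applied_shift)
  } else {
    x$subjects[[newname]] <- v
  }
  x$schema[[newname]] <- list(type = "continuous", levels = NULL)
  class(x$schema) <- "covariate_schema"
  attr(x, "shift") <- applied_shift
  validate_cohort(x)
  x
}

#' Convert a cohort to counting-process form
#'
#' Expands each subject's event history into the `(start, stop]` interval
#' rows consumed by Cox-type recurrent-event models: intervals
#' `(0, t1], (t1, t2], ..., (tk, min(follow_up_end, horizon)]`, each with
#' an event indicator.  Both representations run on the total-time scale
#' (time since entry).  Under Andersen-Gill (`"AG"`) all rows share stratum
#' 1; under Prentice-Williams-Peterson total time (`"PWP-TT"`) a row's
#' stratum is 1 + the number of prior events for that subject, so a subject
#' is at risk for event `k` only after event `k - 1`.  Events after the
#' horizon are excluded; an event exactly at the horizon is included (the
#' final interval then ends in an event).
#'
#' @param x A `recur_cohort`.
#' @param representation `"AG"` or `"PWP-TT"`.
#' @param horizon Positive horizon in days (may be `Inf`).
#' @return `data.frame` of class `counting_process` with columns
#'   `subject_id`, `start`, `stop`, `event`, `stratum`, then the covariate
#'   columns; attributes `representation` and `horizon`.
#' @export
to_counting_process <- function(x, representation = c("AG", "PWP-TT"),
                                horizon = Inf) {
  representation <- match.arg(representation)
  stopifnot(inherits(x, "recur_cohort"))
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("horizon must be > 0", call. = FALSE)
  }
  s <- x$subjects
  rows <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    id <- s$subject_id[i]
    end <- min(s$follow_up_end[i], horizon)
    t <- x$events[[id]]
    t <- t[t <= end]
    k <- length(t)
    has_terminal <- as.integer(k == 0L || t[k] < end)
    starts <- c(0, t)[seq_len(k + has_terminal)]
    stops <- if (has_terminal) c(t, end) else t
    rows[[i]] <- data.frame(
      subject_id = id,
      start = starts,
      stop = stops,
      event = c(rep(1L, k), integer(has_terminal)),
      stratum = if (representation == "AG") 1L else seq_len(k + has_terminal),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  cov_cols <- names(x$schema)
  if (length(cov_cols) > 0) {
    idx <- match(tab$subject_id, s$subject_id)
    tab <- cbind(tab, s[idx, cov_cols, drop = FALSE])
  }
  rownames(tab) <- NULL
  structure(tab, class = c("counting_process", "data.frame"),
            representation = representation, horizon = horizon,
            schema = x$schema)
}

#' Write a counting-process table to CSV
#' @param tab A `counting_process` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counting_process <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
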