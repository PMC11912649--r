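#' Declare a covariate schema for a cohort
#'
#' A schema names each covariate and declares its type: `"binary"` (0/1),
#' `"categorical"` (with an ordered vector of levels, the first being the
#' reference), or `"continuous"`.
#'
#' @param ... Named arguments, one per covariate.  Each value is either a
#'   type string (`"binary"`, `"continuous"`) or, for categorical
#'   covariates, a character vector of levels (reference level first), or a
#'   list with elements `type` and optionally `levels`.
#' @return An object of class `covariate_schema`: a named list with
#'   elements `type` and `levels` per covariate.
#' @examples
#' covariate_schema(male = "binary", age = "continuous",
#'                  smoking = c("never", "current", "ex"))
#' @export
covariate_schema <- function(...) {
  args <- list(...)
  if (length(args) == 0L) {
    return(structure(list(), class = "covariate_schema"))
  }
  if (is.null(names(args)) || any(names(args) == "")) {
    stop("every covariate in a schema must be named", call. = FALSE)
  }
  schema <- lapply(args, function(a) {
    if (is.list(a)) {
      type <- match.arg(a$type, c("binary", "categorical", "continuous"))
      list(type = type, levels = a$levels)
    } else if (is.character(a) && length(a) == 1L &&
               a %in% c("binary", "continuous")) {
      list(type = a, levels = NULL)
    } else if (is.character(a) && length(a) >= 2L) {
      list(type = "categorical", levels = a)
    } else {
      stop("invalid schema entry; give a type string or a level vector",
           call. = FALSE)
    }
  })
  structure(schema, class = "covariate_schema")
}

#' Construct a recurrent-event cohort
#'
#' A cohort couples a subjects table (one row per subject: identifier,
#' administrative censoring time and covariates) with per-subject ordered
#' event times.  Time is measured in days from each subject's entry
#' (time 0); events lie in `(0, follow_up_end]`, where a tie with
#' `follow_up_end` means the event occurred at the censoring instant and
#' still counts.
#'
#' @param subjects `data.frame` with columns `subject_id`, `follow_up_end`
#'   and one column per schema covariate.
#' @param events Either a `data.frame` with columns `subject_id` and
#'   `event_time`, or a named list of numeric event-time vectors keyed by
#'   subject id (subjects without events may be omitted).
#' @param schema A [covariate_schema()].
#' @return An object of class `recur_cohort` with elements `subjects`
#'   (data.frame), `events` (named list of sorted numeric vectors, one per
#'   subject) and `schema`.
#' @export
cohort <- function(subjects, events = NULL, schema = covariate_schema()) {
  stopifnot(is.data.frame(subjects))
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "follow_up_end") %in% names(subjects))) {
    stop("subjects table must have columns 'subject_id' and 'follow_up_end'",
         call. = FALSE)
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  ids <- subjects$subject_id

  ev <- vector("list", nrow(subjects))
  names(ev) <- ids
  ev[] <- list(numeric(0))
  if (is.data.frame(events)) {
    if (nrow(events) > 0) {
      if (!all(c("subject_id", "event_time") %in% names(events))) {
        stop("events table must have columns 'subject_id' and 'event_time'",
             call. = FALSE)
      }
      eid <- as.character(events$subject_id)
      unknown <- setdiff(unique(eid), ids)
      if (length(unknown) > 0) {
        stop("events refer to unknown subject id(s): ",
             paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
      }
      sp <- split(as.numeric(events$event_time), eid)
      ev[names(sp)] <- lapply(sp, sort)
    }
  } else if (is.list(events)) {
    unknown <- setdiff(names(events), ids)
    if (length(unknown) > 0) {
      stop("events refer to unknown subject id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    ev[names(events)] <- lapply(events, function(x) sort(as.numeric(x)))
  } else if (!is.null(events)) {
    stop("events must be a data.frame, a named list, or NULL", call. = FALSE)
  }

  out <- structure(list(subjects = subjects, events = ev, schema = schema),
                   class = "recur_cohort")
  validate_cohort(out)
  out
}

#' Validate a cohort against its invariants
#'
#' Checks subject-id uniqueness, positive follow-up, schema consistency
#' (declared covariates present, categorical values within declared levels),
#' and per-subject event sequences (strictly increasing, in
#' `(0, follow_up_end]`).  Errors name the offending subject and field.
#'
#' @param x A `recur_cohort`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "recur_cohort"))
  s <- x$subjects
  if (anyDuplicated(s$subject_id)) {
    dup <- s$subject_id[duplicated(s$subject_id)][1]
    stop("duplicate subject_id: '", dup, "'", call. = FALSE)
  }
  if (!is.numeric(s$follow_up_end) || anyNA(s$follow_up_end)) {
    stop("follow_up_end must be numeric and non-missing", call. = FALSE)
  }
  bad <- which(s$follow_up_end <= 0)
  if (length(bad) > 0) {
    stop("subject '", s$subject_id[bad[1]],
         "': follow_up_end must be > 0", call. = FALSE)
  }
  for (nm in names(x$schema)) {
    if (!nm %in% names(s)) {
      stop("schema covariate '", nm, "' missing from subjects table",
           call. = FALSE)
    }
    decl <- x$schema[[nm]]
    v <- s[[nm]]
    if (decl$type == "binary") {
      if (!all(v %in% c(0, 1, NA))) {
        stop("covariate '", nm, "' declared binary but has values outside 0/1",
             call. = FALSE)
      }
    } else if (decl$type == "categorical") {
      extra <- setdiff(unique(as.character(v[!is.na(v)])), decl$levels)
      if (length(extra) > 0) {
        stop("covariate '", nm, "' has undeclared level(s): ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
    } else {
      if (!is.numeric(v)) {
        stop("covariate '", nm, "' declared continuous but is not numeric",
             call. = FALSE)
      }
    }
  }
  if (!setequal(names(x$events), s$subject_id)) {
    stop("events list keys must match subject ids exactly", call. = FALSE)
  }
  for (id in s$subject_id) {
    t <- x$events[[id]]
    if (length(t) == 0) next
    end <- s$follow_up_end[s$subject_id == id]
    if (any(t <= 0)) {
      stop("subject '", id, "': event_time must be > 0", call. = FALSE)
    }
    if (any(t > end)) {
      stop("subject '", id, "': event_time ", max(t),
           " exceeds follow_up_end ", end, call. = FALSE)
    }
    if (any(diff(t) <= 0)) {
      stop("subject '", id, "': event times must be strictly increasing ",
           "(merge or jitter tied events upstream)", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.recur_cohort <- function(x, ...) {
  n <- nrow(x$subjects)
  ne <- sum(lengths(x$events))
  cat("<recur_cohort> ", n, " subjects, ", ne, " events, ",
      length(x$schema), " covariates (",
      paste(names(x$schema), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x A `recur_cohort`.
#' @return Integer count.
#' @export
n_subjects <- function(x) nrow(x$subjects)

#' Per-subject observed event counts at a horizon
#'
#' Counts events in `(0, min(follow_up_end, horizon)]`; an event exactly at
#' the horizon is included.
#'
#' @param x A `recur_cohort`.
#' @param horizon Horizon in days; `Inf` counts all events.
#' @return Named integer vector, one entry per subject in subjects-table
#'   order.
#' @export
event_counts <- function(x, horizon = Inf) {
  ids <- x$subjects$subject_id
  ends <- pmin(x$subjects$follow_up_end, horizon)
  n <- vapply(seq_along(ids), function(i) {
    sum(x$events[[ids[i]]] <= ends[i])
  }, integer(1))
  names(n) <- ids
  n
}

#' Read a cohort from subjects and events CSV files
#'
#' Files are comma-separated with a header row (RFC-4180 quoting, UTF-8).
#' The subjects file needs columns `subject_id`, `follow_up_end` plus the
#' schema covariates; the events file needs `subject_id`, `event_time`.
#' Rows with missing covariate values are dropped (with their events) and
#' the dropped count reported via a message; no covariate imputation is
#' performed.
#'
#' @param subjects_path,events_path Paths to the two CSV files.
#' @param schema A [covariate_schema()].
#' @return A validated `recur_cohort`.
#' @export
read_cohort <- function(subjects_path, events_path, schema) {
  if (!file.exists(subjects_path)) {
    stop("subjects file not found: ", subjects_path, call. = FALSE)
  }
  if (!file.exists(events_path)) {
    stop("events file not found: ", events_path, call. = FALSE)
  }
  subj <- utils::read.csv(subjects_path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  need <- c("subject_id", "follow_up_end", names(schema))
  miss <- setdiff(need, names(subj))
  if (length(miss) > 0) {
    stop("subjects file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(subj$follow_up_end)) {
    stop("subjects file: follow_up_end is not numeric", call. = FALSE)
  }
  # drop rows with missing covariate values (no imputation)
  if (length(schema) > 0) {
    cc <- stats::complete.cases(subj[, names(schema), drop = FALSE])
    if (any(!cc)) {
      message("read_cohort: dropped ", sum(!cc),
              " subject(s) with missing covariate values")
      subj <- subj[cc, , drop = FALSE]
    }
  }
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(ev) > 0) {
    miss <- setdiff(c("subject_id", "event_time"), names(ev))
    if (length(miss) > 0) {
      stop("events file missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    et <- suppressWarnings(as.numeric(ev$event_time))
    if (anyNA(et)) {
      stop("events file row ", which(is.na(et))[1],
           ": event_time is not numeric", call. = FALSE)
    }
    ev <- data.frame(subject_id = ev$subject_id, event_time = et,
                     stringsAsFactors = FALSE)
  } else {
    ev <- data.frame(subject_id = character(0), event_time = numeric(0))
  }
  cohort(subj, ev, schema)
}

#' Write a cohort to subjects and events CSV files
#'
#' Inverse of [read_cohort()]: the written pair round-trips to an identical
#' cohort.  Values containing the delimiter are RFC-4180-quoted.
#'
#' @param x A `recur_cohort`.
#' @param subjects_path,events_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(x, subjects_path, events_path) {
  validate_cohort(x)
  utils::write.csv(x$subjects, subjects_path, row.names = FALSE, na = "")
  k <- lengths(x$events)
  ev <- data.frame(
    subject_id = rep(names(x$events), k),
    event_time = unlist(x$events, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(ev) == 0) {
    ev <- data.frame(subject_id = character(0), event_time = numeric(0))
  }
  utils::write.csv(ev, events_path, row.names = FALSE)
  invisible(c(subjects = subjects_path, events = events_path))
}

#' Construct interval-count records
#'
#' Interval-reported data arise when events are tallied between clinic
#' visits rather than dated individually.  Each record covers a half-open
#' interval `(interval_start, interval_end]` with a non-negative event
#' count; when one or two events occurred, their exact dates are often
#' recorded and may be carried in `exact_times` (a `";"`-separated string
#' per record, `NA` when exact times were discarded).
#'
#' @param subject_id Character vector.
#' @param interval_start,interval_end Numeric vectors, days;
#'   `interval_start < interval_end`.
#' @param count Non-negative integer vector.
#' @param exact_times Optional character vector of `";"`-joined exact event
#'   times, `NA` where unavailable.
#' @return `data.frame` of class `interval_counts`.
#' @export
interval_counts <- function(subject_id, interval_start, interval_end, count,
                            exact_times = NA_character_) {
  df <- data.frame(subject_id = as.character(subject_id),
                   interval_start = as.numeric(interval_start),
                   interval_end = as.numeric(interval_end),
                   count = as.integer(count),
                   exact_times = as.character(exact_times),
                   stringsAsFactors = FALSE)
  validate_interval_counts(df)
  class(df) <- c("interval_counts", "data.frame")
  df
}

#' Read or write interval-count records as CSV
#'
#' Columns: `subject_id,interval_start,interval_end,count[,exact_times]`.
#' @param path CSV path.
#' @return For the reader, an [interval_counts()] data frame.
#' @export
read_interval_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  need <- c("subject_id", "interval_start", "interval_end", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("interval-counts file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  exact <- if ("exact_times" %in% names(df)) {
    as.character(df$exact_times)
  } else {
    NA_character_
  }
  exact[!is.na(exact) & !nzchar(exact)] <- NA_character_
  interval_counts(df$subject_id, df$interval_start, df$interval_end,
                  df$count, exact)
}

#' @rdname read_interval_counts
#' @param x An `interval_counts` data frame.
#' @export
write_interval_counts <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

validate_interval_counts <- function(df) {
  if (any(df$count < 0)) stop("interval count must be non-negative",
                              call. = FALSE)
  if (any(df$interval_start >= df$interval_end)) {
    stop("interval_start must be < interval_end", call. = FALSE)
  }
  for (sp in split(df, df$subject_id)) {
    sp <- sp[order(sp$interval_start), ]
    if (nrow(sp) > 1 &&
        any(sp$interval_start[-1] < sp$interval_end[-nrow(sp)])) {
      stop("subject '", sp$subject_id[1],
           "': intervals overlap", call. = FALSE)
    }
  }
  invisible(df)
}
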