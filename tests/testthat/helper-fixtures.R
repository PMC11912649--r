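# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

toy_schema <- function() {
  covariate_schema(x = "binary", grp = c("a", "b"), age = "continuous")
}

# small deterministic cohort: 3 subjects, 5 events
toy_cohort <- function() {
  cohort(
    subjects = data.frame(
      subject_id = c("A", "B", "C"),
      follow_up_end = c(100, 80, 60),
      x = c(1, 0, 1),
      grp = c("a", "b", "a"),
      age = c(40.5, 55.25, 61),
      stringsAsFactors = FALSE
    ),
    events = list(A = c(10, 35, 90), B = c(20, 70)),
    schema = toy_schema()
  )
}

# random valid cohort for property-style tests
random_cohort <- function(seed, n = 25) {
  set.seed(seed)
  subj <- data.frame(
    subject_id = sprintf("R%03d", seq_len(n)),
    follow_up_end = round(stats::runif(n, 30, 400), 3),
    x = stats::rbinom(n, 1, 0.5),
    grp = sample(c("a", "b"), n, replace = TRUE),
    age = round(stats::rnorm(n, 50, 10), 2),
    stringsAsFactors = FALSE
  )
  ev <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, 2)
    sort(round(stats::runif(k, 0.5, subj$follow_up_end[i]), 4))
  })
  names(ev) <- subj$subject_id
  cohort(subj, ev, toy_schema())
}

# prediction set straight from vectors (no cohort needed)
pred_df <- function(y, yhat) {
  data.frame(observed = y, predicted = yhat)
}
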