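# Shared builders and independent oracles for the test suite.

# Build a scan table tersely: one row per element of `activities`.
make_scans <- function(activities, locations, follow_id = "F1",
                       platform = "BOAT", n_boats = 0L, n_kayaks = 0L,
                       n_swimmers = 0L, start = "2011-01-01 08:00",
                       step_min = 10, bays = kona_bays()) {
  n <- length(activities)
  t0 <- as.POSIXct(start, tz = "UTC")
  as_scan_table(data.frame(
    follow_id = rep_len(follow_id, n),
    timestamp = t0 + 60 * step_min * (seq_len(n) - 1L),
    platform = rep_len(platform, n),
    location = rep_len(locations, n),
    activity = activities,
    n_boats = rep_len(n_boats, n),
    n_kayaks = rep_len(n_kayaks, n),
    n_swimmers = rep_len(n_swimmers, n)
  ), bays)
}

# Degenerate bootstrap distribution: B identical replicates of one budget.
constant_budget_dist <- function(p, stratum, B = 50L) {
  m <- matrix(rep(p, each = B), nrow = B,
              dimnames = list(NULL, c("rest", "social", "travel")))
  structure(m, stratum = stratum, n_scans = NA_integer_, B = B,
            class = c("budget_distribution", class(m)))
}

constant_time_dist <- function(a, bay) {
  structure(a, bay = bay, follow_ids = as.character(seq_along(a)),
            class = "time_inside_distribution")
}

# Independent closed-form expectation of the cumulative budget: linearity of
# the daily-budget equation in the allocation, the time-inside draw and the
# budget draws. Hand-rolled double loop, no shared code with simulate_study.
closed_form_cumulative <- function(om, acoustic, budget_dists, time_dists,
                                   presence_probs, study_days) {
  bays <- om$bays
  nd <- length(study_days)
  stay <- vapply(bays, function(b) {
    st <- acoustic$status[acoustic$bay == b & acoustic$date %in% study_days]
    (sum(st == "PRESENT") + presence_probs[[b]] * sum(st == "MISSING")) / nd
  }, numeric(1))
  mo <- colMeans(unclass(budget_dists[[OUTSIDE]]))
  E <- matrix(0, nrow(om$probs), 3)
  for (i in seq_len(nrow(om$probs))) {
    for (b in seq_along(bays)) {
      pb <- om$probs[i, b]
      if (pb == 0) next
      Ea <- mean(unclass(time_dists[[bays[b]]]))
      mb <- colMeans(unclass(budget_dists[[bays[b]]]))
      E[i, ] <- E[i, ] +
        pb * (stay[b] * (Ea * mb + (1 - Ea) * mo) + (1 - stay[b]) * mo)
    }
  }
  E
}

# Estimated pipeline inputs for a synthetic dataset (shared by the oracle and
# recovery tests).
pipeline_inputs <- function(syn, B = 500L) {
  om <- occurrence_matrix(syn$sightings)
  bays <- om$bays
  strata <- c(bays, OUTSIDE)
  dists <- lapply(strata, function(s) bootstrap_budget(syn$scans, s, B = B))
  names(dists) <- strata
  tds <- lapply(bays, function(b) time_inside_distribution(syn$scans, b))
  names(tds) <- bays
  list(om = om, dists = dists, tds = tds,
       presence = presence_probabilities(syn$acoustic))
}
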