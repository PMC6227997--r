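# The cumulative activity-budget simulation.
#
# For each identified individual and each study day, the model:
#   1. allocates the individual to one bay, drawn from its relative
#      occurrence across bays (photo-identification);
#   2. gates the allocation by that bay's acoustic presence call for the day:
#      ABSENT moves the individual outside the bays, MISSING is imputed by a
#      Bernoulli draw at the bay's observed presence rate;
#   3. draws the proportion of daytime spent inside the bay (a) from the
#      bay's empirical time-inside distribution (a = 0 outside; b = 1 - a);
#   4. draws one bootstrap replicate of the bay budget and one of the
#      outside budget, and forms the daily budget as the convex combination
#        daily budget = a * (budget inside bay) + b * (budget outside bays);
#   5. accumulates daily budgets over the study period into the individual's
#      cumulative activity budget (the equal-duration mean of daily budgets).
#
# Individuals visit at most one bay per day, and all daytime minutes not
# inside the allocated bay count as outside.

#' Study configuration for the cumulative simulation
#'
#' @param study_days Date vector of study days, strictly increasing.
#' @param individuals character vector of individual ids to simulate.
#' @param seed integer RNG seed; the whole simulation is reproducible from it.
#' @param n_bootstrap number of bootstrap replicates behind each stratum
#'   budget distribution (used by the pipeline when it builds them).
#' @param daytime_minutes daytime window length in minutes (default 720,
#'   06:00-18:00).
#' @return a `study_config` list.
#' @export
study_config <- function(study_days, individuals, seed = 1L,
                         n_bootstrap = 1000L, daytime_minutes = 720L) {
  if (!inherits(study_days, "Date") || !length(study_days)) {
    abort_config("study_config: study_days must be a non-empty Date vector")
  }
  if (is.unsorted(study_days, strictly = TRUE)) {
    abort_config("study_config: study_days must be strictly increasing")
  }
  if (!length(individuals)) abort_config("study_config: individuals must be non-empty")
  structure(
    list(study_days = study_days, individuals = as.character(individuals),
         seed = as.integer(seed), n_bootstrap = as.integer(n_bootstrap),
         daytime_minutes = as.integer(daytime_minutes)),
    class = "study_config"
  )
}

#' Allocate an individual to a bay (or outside) for one day
#'
#' Draws a bay from the individual's allocation probabilities, then applies
#' the acoustic gate: `ABSENT` for that (bay, day) empties the bay, sending
#' the individual outside; `MISSING` imputes presence by a Bernoulli draw at
#' the bay's observed presence rate. Consumes the current RNG stream.
#'
#' @param individual individual id (must exist in `matrix`).
#' @param date a study day.
#' @param matrix an `occurrence_matrix`.
#' @param acoustic an `acoustic_table`.
#' @param presence_probs named per-bay presence probabilities (for MISSING
#'   days); defaults to `presence_probabilities(acoustic)`.
#' @return a `daily_allocation` list: `individual_id`, `date`, `stratum`
#'   (bay or `OUTSIDE`), `a`, `b` (unset, `NA`, until [draw_time_inside()]).
#' @export
allocate_day <- function(individual, date, matrix, acoustic,
                         presence_probs = presence_probabilities(acoustic)) {
  i <- match(individual, matrix$individuals)
  if (is.na(i)) abort_validation(sprintf("allocate_day: unknown individual '%s'", individual))
  bays <- matrix$bays
  bay <- bays[sample.int(length(bays), 1L, prob = matrix$probs[i, ])]
  status <- acoustic$status[acoustic$bay == bay & acoustic$date == date]
  if (!length(status)) status <- "MISSING"
  stratum <- if (status == "PRESENT") {
    bay
  } else if (status == "ABSENT") {
    OUTSIDE
  } else if (stats::runif(1) < presence_probs[[bay]]) {
    bay
  } else {
    OUTSIDE
  }
  structure(list(individual_id = individual, date = date, stratum = stratum,
                 a = NA_real_, b = NA_real_),
            class = "daily_allocation")
}

#' Draw the proportion of daytime spent inside the allocated bay
#'
#' Samples `a` uniformly with replacement from the bay's empirical
#' time-inside sample; outside allocations get `a = 0`. Always sets
#' `b = 1 - a` exactly.
#'
#' @param allocation a `daily_allocation`.
#' @param dist the allocated bay's `time_inside_distribution` (ignored for
#'   `OUTSIDE` allocations).
#' @return the completed `daily_allocation`.
#' @export
draw_time_inside <- function(allocation, dist = NULL) {
  if (allocation$stratum == OUTSIDE) {
    allocation$a <- 0
  } else {
    if (is.null(dist) || !length(dist)) {
      abort_coverage(sprintf(
        "draw_time_inside: empty time-inside distribution for bay '%s'", allocation$stratum
      ))
    }
    v <- unclass(dist)
    allocation$a <- v[sample.int(length(v), 1L)]
  }
  allocation$b <- 1 - allocation$a
  allocation
}

#' Daily activity budget as a convex combination
#'
#' `a x (budget inside the bay) + b x (budget outside bays)`, with
#' `b = 1 - a`. Since both inputs are valid budgets and the weights are
#' convex, the result is always a valid budget.
#'
#' @param allocation a completed `daily_allocation`, or a bare numeric `a`.
#' @param bay_budget_draw `activity_budget` drawn from the bay's bootstrap
#'   distribution.
#' @param outside_budget_draw `activity_budget` drawn from the outside
#'   distribution.
#' @return an `activity_budget`.
#' @export
daily_budget <- function(allocation, bay_budget_draw, outside_budget_draw) {
  a <- if (is.numeric(allocation)) allocation else allocation$a
  if (is.na(a) || a < 0 || a > 1) abort_validation("daily_budget: a must be in [0, 1]")
  activity_budget(a * as.numeric(bay_budget_draw) + (1 - a) * as.numeric(outside_budget_draw))
}

status_codes <- function(acoustic, bays, study_days) {
  # bays x days integer matrix: 1 PRESENT, 2 ABSENT, 3 MISSING
  m <- matrix(3L, nrow = length(bays), ncol = length(study_days),
              dimnames = list(bays, format(study_days, "%Y-%m-%d")))
  bi <- match(acoustic$bay, bays)
  di <- match(acoustic$date, study_days)
  keep <- !is.na(bi) & !is.na(di)
  m[cbind(bi[keep], di[keep])] <- match(acoustic$status[keep], acoustic_statuses())
  m
}

#' Simulate cumulative daytime activity budgets for all individuals
#'
#' Runs the full allocation chain for every (individual, study day) and
#' accumulates each individual's daily budgets into a cumulative budget.
#' Deterministic given `config$seed`. Per individual, random draws are made
#' in fixed blocks over days — bay allocations, presence-imputation
#' uniforms, time-inside draws (grouped by bay), then bay and outside
#' replicate indices — with a fixed number of draws per block regardless of
#' which are consumed, so results are reproducible across runs.
#'
#' @param config a `study_config`.
#' @param matrix an `occurrence_matrix` (its individuals are simulated unless
#'   `config$individuals` restricts them).
#' @param acoustic an `acoustic_table` covering the study days.
#' @param budget_dists named list of `budget_distribution`s, one per bay any
#'   individual can reach plus one for `OUTSIDE`.
#' @param time_dists named list of `time_inside_distribution`s, one per
#'   reachable bay.
#' @param presence_probs optional named per-bay presence probabilities;
#'   defaults to the acoustic table's observed rates.
#' @param keep_daily if `TRUE`, also return the full per-day budget log.
#' @return a `study_simulation` list with `cumulative` (data.frame:
#'   `individual_id`, `p_rest`, `p_social`, `p_travel`, `total_minutes`),
#'   `daily` (data.frame or `NULL`), and the `config`.
#' @export
simulate_study <- function(config, matrix, acoustic, budget_dists, time_dists,
                           presence_probs = NULL, keep_daily = FALSE) {
  stopifnot(inherits(config, "study_config"))
  bays <- matrix$bays
  ids <- intersect(config$individuals, matrix$individuals)
  if (!length(ids)) abort_config("simulate_study: no configured individual appears in the occurrence matrix")
  probs <- matrix$probs[ids, , drop = FALSE]

  # coverage check before any simulation work
  reachable <- bays[colSums(probs > 0) > 0]
  missing_bud <- setdiff(c(reachable, OUTSIDE), names(budget_dists))
  if (length(missing_bud)) {
    abort_coverage(sprintf("simulate_study: no budget distribution for stratum/strata: %s",
                           paste(missing_bud, collapse = ", ")))
  }
  missing_time <- setdiff(reachable, names(time_dists))
  if (length(missing_time)) {
    abort_coverage(sprintf("simulate_study: no time-inside distribution for bay(s): %s",
                           paste(missing_time, collapse = ", ")))
  }

  days <- config$study_days
  nd <- length(days)
  nb <- length(bays)
  S <- status_codes(acoustic, bays, days)
  if (is.null(presence_probs)) presence_probs <- presence_probabilities(acoustic)
  q <- as.numeric(presence_probs[bays])
  if (anyNA(q)) abort_config("simulate_study: presence probabilities missing for some bay")

  bud_mats <- lapply(budget_dists, unclass)
  time_vecs <- lapply(time_dists, unclass)
  out_mat <- bud_mats[[OUTSIDE]]
  B_by_bay <- vapply(bud_mats, nrow, integer(1))

  set.seed(config$seed)
  cum <- base::matrix(NA_real_, nrow = length(ids), ncol = 3,
                      dimnames = list(NULL, c("rest", "social", "travel")))
  daily_log <- if (keep_daily) vector("list", length(ids)) else NULL

  for (i in seq_along(ids)) {
    bay_idx <- sample.int(nb, nd, replace = TRUE, prob = probs[i, ])
    st <- S[cbind(bay_idx, seq_len(nd))]
    u <- stats::runif(nd)                      # presence imputation, all days
    inside <- st == 1L | (st == 3L & u < q[bay_idx])
    a <- numeric(nd)
    for (b in seq_len(nb)) {
      sel <- which(inside & bay_idx == b)
      if (length(sel)) {
        tv <- time_vecs[[bays[b]]]
        a[sel] <- tv[sample.int(length(tv), length(sel), replace = TRUE)]
      }
    }
    bay_bud <- base::matrix(0, nrow = nd, ncol = 3)
    for (b in seq_len(nb)) {
      sel <- which(inside & bay_idx == b)
      if (length(sel)) {
        m <- bud_mats[[bays[b]]]
        ri <- sample.int(nrow(m), length(sel), replace = TRUE)
        bay_bud[sel, ] <- m[ri, , drop = FALSE]
      }
    }
    ro <- sample.int(nrow(out_mat), nd, replace = TRUE)   # outside draw, all days
    daily <- a * bay_bud + (1 - a) * out_mat[ro, , drop = FALSE]
    cum[i, ] <- colMeans(daily)
    if (keep_daily) {
      daily_log[[i]] <- data.frame(
        individual_id = ids[i], date = days,
        stratum = ifelse(inside, bays[bay_idx], OUTSIDE),
        a = a, p_rest = daily[, 1], p_social = daily[, 2], p_travel = daily[, 3]
      )
    }
  }

  cumulative <- data.frame(
    individual_id = ids,
    p_rest = cum[, "rest"], p_social = cum[, "social"], p_travel = cum[, "travel"],
    total_minutes = nd * config$daytime_minutes
  )
  structure(
    list(cumulative = cumulative,
         daily = if (keep_daily) do.call(rbind, daily_log) else NULL,
         config = config),
    class = "study_simulation"
  )
}

#' @export
print.study_simulation <- function(x, ...) {
  cat(sprintf("Cumulative activity-budget simulation: %d individuals x %d days (seed %d)\n",
              nrow(x$cumulative), length(x$config$study_days), x$config$seed))
  s <- summarize_population(x$cumulative)
  print(s)
  invisible(x)
}

#' Population summary of cumulative budgets
#'
#' Mean, sample standard deviation, minimum and maximum of each activity
#' state's cumulative proportion across individuals, reported as percentages.
#'
#' @param budgets the `cumulative` data.frame of a `study_simulation` (or any
#'   data.frame with `p_rest`, `p_social`, `p_travel`).
#' @return data.frame with one row per state and columns `state`, `mean_pct`,
#'   `sd_pct`, `min_pct`, `max_pct`.
#' @export
summarize_population <- function(budgets) {
  if (inherits(budgets, "study_simulation")) budgets <- budgets$cumulative
  if (nrow(budgets) < 2L) abort_validation("summarize_population: need >= 2 individuals")
  cols <- c(rest = "p_rest", social = "p_social", travel = "p_travel")
  do.call(rbind, lapply(names(cols), function(s) {
    v <- 100 * budgets[[cols[[s]]]]
    data.frame(state = s, mean_pct = mean(v), sd_pct = stats::sd(v),
               min_pct = min(v), max_pct = max(v))
  }))
}
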