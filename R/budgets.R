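# Stratum-specific activity budgets from scan samples.
#
# Every scan stands for one 10-min sampling window, so all "proportion of
# time" quantities are scan-count ratios. Uncertainty in a stratum budget is
# carried as a bootstrap density distribution: states resampled with
# replacement from the stratum's observed states, B times.

#' Construct a three-state activity budget
#'
#' Proportions of time in the rest, social and travel states. Each must lie
#' in `[0, 1]` and they must sum to 1 (tolerance 1e-9).
#'
#' @param p_rest,p_social,p_travel proportions, or `p_rest` may be a numeric
#'   vector of length 3.
#' @param n_scans optional number of scans behind the estimate.
#' @param stratum optional stratum identifier (bay or `OUTSIDE`).
#' @return an `activity_budget`: named numeric vector (rest, social, travel).
#' @export
activity_budget <- function(p_rest, p_social = NULL, p_travel = NULL,
                            n_scans = NA_integer_, stratum = NA_character_) {
  p <- if (is.null(p_social)) as.numeric(p_rest) else c(p_rest, p_social, p_travel)
  if (length(p) != 3L || anyNA(p)) abort_validation("activity_budget: need 3 non-missing proportions")
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    abort_validation("activity_budget: proportions must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    abort_validation(sprintf("activity_budget: proportions sum to %.12f, not 1", sum(p)))
  }
  p <- pmin(pmax(p, 0), 1)
  structure(stats::setNames(p, c("rest", "social", "travel")),
            n_scans = n_scans, stratum = stratum, class = "activity_budget")
}

#' @export
print.activity_budget <- function(x, ...) {
  cat(sprintf("Activity budget%s: rest %.3f, social %.3f, travel %.3f%s\n",
              if (is.na(attr(x, "stratum"))) "" else paste0(" [", attr(x, "stratum"), "]"),
              x[["rest"]], x[["social"]], x[["travel"]],
              if (is.na(attr(x, "n_scans"))) "" else sprintf(" (n = %d scans)", attr(x, "n_scans"))))
  invisible(x)
}

stratum_states <- function(scans, stratum, platform = NULL) {
  sel <- scans$location == stratum
  if (!is.null(platform)) sel <- sel & scans$platform == platform
  scans$activity[sel]
}

#' Point activity budget for a stratum
#'
#' State counts divided by the total number of scans located in the stratum
#' (a bay or `OUTSIDE`). Boat- and land-based scans are pooled unless
#' `platform` restricts them.
#'
#' @param scans a `scan_table`.
#' @param stratum bay identifier or `OUTSIDE`.
#' @param platform optional `"BOAT"` or `"LAND"` filter.
#' @return an `activity_budget`.
#' @export
point_budget <- function(scans, stratum, platform = NULL) {
  st <- stratum_states(scans, stratum, platform)
  if (!length(st)) {
    abort_validation(sprintf("point_budget: no scans in stratum '%s'", stratum))
  }
  counts <- table(factor(st, levels = activity_states()))
  activity_budget(as.numeric(counts) / length(st),
                  n_scans = length(st), stratum = stratum)
}

#' Bootstrap density distribution of a stratum budget
#'
#' Resamples the stratum's n observed activity states with replacement and
#' recomputes the budget, B times (default 1000), yielding an empirical
#' density distribution that carries the sampling uncertainty of the budget
#' into the cumulative simulation. Replicates are kept raw (no smoothing).
#'
#' @inheritParams point_budget
#' @param B number of bootstrap replicates (>= 1).
#' @param seed optional integer; if supplied the RNG is seeded locally so the
#'   replicate set is reproducible.
#' @return a `budget_distribution`: B x 3 matrix of replicate budgets with
#'   attributes `stratum`, `n_scans`, `B`.
#' @export
bootstrap_budget <- function(scans, stratum, B = 1000L, platform = NULL, seed = NULL) {
  if (!is.numeric(B) || B < 1) abort_validation("bootstrap_budget: B must be >= 1")
  B <- as.integer(B)
  st <- stratum_states(scans, stratum, platform)
  n <- length(st)
  if (!n) abort_validation(sprintf("bootstrap_budget: no scans in stratum '%s'", stratum))
  if (!is.null(seed)) set.seed(as.integer(seed))
  states <- match(st, activity_states())
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  resampled <- states[idx]
  dim(resampled) <- dim(idx)
  reps <- cbind(
    rest = rowMeans(resampled == 1L),
    social = rowMeans(resampled == 2L),
    travel = rowMeans(resampled == 3L)
  )
  structure(reps, stratum = stratum, n_scans = n, B = B,
            class = c("budget_distribution", class(reps)))
}

#' Mean budget of a bootstrap distribution
#' @param x a `budget_distribution`.
#' @param ... unused.
#' @return an `activity_budget` of the replicate means.
#' @export
mean.budget_distribution <- function(x, ...) {
  activity_budget(colMeans(unclass(x)) / sum(colMeans(unclass(x))),
                  n_scans = attr(x, "n_scans"), stratum = attr(x, "stratum"))
}

#' @export
print.budget_distribution <- function(x, ...) {
  m <- colMeans(unclass(x))
  cat(sprintf(
    "Bootstrap budget distribution [%s]: B = %d, n = %d scans\n  mean rest %.3f, social %.3f, travel %.3f\n",
    attr(x, "stratum"), attr(x, "B"), attr(x, "n_scans"), m[1], m[2], m[3]))
  invisible(x)
}

#' Empirical distribution of daytime proportion spent inside a bay
#'
#' For every focal follow with at least one scan located inside the bay, the
#' proportion of the 12-h daytime window the follow documented inside:
#' `scan_minutes x (number of inside scans) / daytime_minutes`, clipped to
#' `[0, 1]`. Follows are the observation unit; follows that never touch the
#' bay contribute nothing. The cumulative simulation draws its daily
#' time-inside value `a` uniformly from this sample.
#'
#' @param scans a `scan_table`.
#' @param bay bay identifier.
#' @param daytime_minutes length of the daytime window (default 720, i.e.
#'   06:00-18:00).
#' @param scan_minutes nominal scan cadence (default 10).
#' @return a `time_inside_distribution`: numeric vector of proportions with
#'   attributes `bay` and `follow_ids`.
#' @export
time_inside_distribution <- function(scans, bay, daytime_minutes = 720L, scan_minutes = 10L) {
  inside <- scans$location == bay
  n_in <- tapply(inside, scans$follow_id, sum)
  n_in <- n_in[n_in > 0]
  if (!length(n_in)) {
    abort_coverage(sprintf(
      "time_inside_distribution: no follow has scans inside bay '%s'; supply a configured fallback sample", bay
    ))
  }
  a <- pmin(1, pmax(0, scan_minutes * as.numeric(n_in) / daytime_minutes))
  structure(a, bay = bay, follow_ids = names(n_in),
            class = "time_inside_distribution")
}

#' @export
print.time_inside_distribution <- function(x, ...) {
  cat(sprintf("Time-inside distribution [%s]: %d follows, mean a = %.3f\n",
              attr(x, "bay"), length(x), mean(unclass(x))))
  invisible(x)
}

#' Write stratum budgets and bootstrap replicates to CSV
#'
#' @param budgets named list of `activity_budget`s (by stratum).
#' @param path output CSV (`stratum,p_rest,p_social,p_travel,n_scans`).
#' @return `path`, invisibly.
#' @export
write_budgets <- function(budgets, path) {
  rows <- do.call(rbind, lapply(names(budgets), function(s) {
    b <- budgets[[s]]
    data.frame(stratum = s, p_rest = b[["rest"]], p_social = b[["social"]],
               p_travel = b[["travel"]], n_scans = attr(b, "n_scans"))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write bootstrap replicate sets to CSV
#'
#' @param dists named list of `budget_distribution`s (by stratum).
#' @param path output CSV (`stratum,replicate,p_rest,p_social,p_travel`).
#' @return `path`, invisibly.
#' @export
write_budget_replicates <- function(dists, path) {
  rows <- do.call(rbind, lapply(names(dists), function(s) {
    m <- unclass(dists[[s]])
    data.frame(stratum = s, replicate = seq_len(nrow(m)),
               p_rest = m[, "rest"], p_social = m[, "social"], p_travel = m[, "travel"])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
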