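one_bay_setup <- function(status = "PRESENT", n_days = 5L) {
  days <- seq(as.Date("2011-01-01"), by = "day", length.out = n_days)
  st <- as_sighting_table(data.frame(
    individual_id = "A", date = days[1], bay = "Makako"))
  ac <- as_acoustic_table(data.frame(bay = "Makako", date = days, status = status),
                          bays = kona_bays(), study_days = days)
  list(om = occurrence_matrix(st), acoustic = ac, days = days)
}

test_that("daily allocation follows occurrence probabilities and the acoustic gate", {
  su <- one_bay_setup("PRESENT")
  set.seed(1)
  al <- allocate_day("A", su$days[1], su$om, su$acoustic,
                     presence_probs = c(Makako = 1, Kealakekua = 1, Honaunau = 1, Kauhako = 1))
  expect_equal(al$stratum, "Makako")   # allocation probability 1, PRESENT

  su <- one_bay_setup("ABSENT")
  al <- allocate_day("A", su$days[1], su$om, su$acoustic,
                     presence_probs = c(Makako = 1, Kealakekua = 1, Honaunau = 1, Kauhako = 1))
  expect_equal(al$stratum, OUTSIDE)    # empty bay sends the dolphin outside

  # MISSING day with presence probability 1 is always treated as present
  su <- one_bay_setup("MISSING")
  for (i in 1:10) {
    al <- allocate_day("A", su$days[1], su$om, su$acoustic,
                       presence_probs = c(Makako = 1, Kealakekua = 0, Honaunau = 0, Kauhako = 0))
    expect_equal(al$stratum, "Makako")
  }
  # ... and with probability 0 always outside
  al <- allocate_day("A", su$days[1], su$om, su$acoustic,
                     presence_probs = c(Makako = 0, Kealakekua = 0, Honaunau = 0, Kauhako = 0))
  expect_equal(al$stratum, OUTSIDE)
})

test_that("time-inside draws complete the allocation with b = 1 - a exactly", {
  al <- structure(list(individual_id = "A", date = as.Date("2011-01-01"),
                       stratum = OUTSIDE, a = NA_real_, b = NA_real_),
                  class = "daily_allocation")
  al <- draw_time_inside(al)
  expect_identical(al$a, 0)
  expect_identical(al$b, 1)

  al$stratum <- "Makako"
  td <- constant_time_dist(0.5, "Makako")
  for (i in 1:5) expect_equal(draw_time_inside(al, td)$a, 0.5)

  # uniform resampling expectation: mean of many draws near the sample mean
  td3 <- constant_time_dist(c(0.2, 0.4, 0.6), "Makako")
  set.seed(2)
  draws <- replicate(1e4, draw_time_inside(al, td3)$a)
  se <- sd(c(0.2, 0.4, 0.6)) * sqrt(2 / 3) / sqrt(1e4)  # population s.d. / sqrt(n)
  expect_lt(abs(mean(draws) - 0.4), 3 * se)
  expect_true(all(draws + (1 - draws) == 1))

  al$stratum <- "Honaunau"
  expect_error(draw_time_inside(al, NULL), class = "spinnerbudget_coverage_error")
})

test_that("the daily budget equation respects its boundaries and midpoint", {
  bay <- activity_budget(0.8, 0.15, 0.05)
  out <- activity_budget(0.4, 0.3, 0.3)
  expect_equal(as.numeric(daily_budget(1, bay, out)), as.numeric(bay))
  expect_equal(as.numeric(daily_budget(0, bay, out)), as.numeric(out))
  expect_equal(as.numeric(daily_budget(0.5, bay, out)), c(0.6, 0.225, 0.175))
})

test_that("a fully degenerate chain reproduces the bay budget exactly", {
  days <- seq(as.Date("2011-01-01"), by = "day", length.out = 10L)
  st <- as_sighting_table(data.frame(
    individual_id = c("A", "B"), date = days[1], bay = "Makako"))
  ac <- as_acoustic_table(
    data.frame(bay = "Makako", date = days, status = "PRESENT"),
    bays = "Makako", study_days = days)
  om <- occurrence_matrix(st, bays = "Makako")
  dists <- list(
    Makako = constant_budget_dist(c(0.7, 0.2, 0.1), "Makako"),
    OUTSIDE = constant_budget_dist(c(1, 0, 0), OUTSIDE)
  )
  tds <- list(Makako = constant_time_dist(1, "Makako"))
  sim <- simulate_study(study_config(days, c("A", "B"), seed = 3),
                        om, ac, dists, tds)
  expect_equal(sim$cumulative$p_rest, c(0.7, 0.7))
  expect_equal(sim$cumulative$p_social, c(0.2, 0.2))
  expect_equal(sim$cumulative$p_travel, c(0.1, 0.1))
  expect_equal(sim$cumulative$total_minutes, c(7200, 7200))
})

test_that("simulation is deterministic under a fixed seed and checks coverage", {
  fx <- small_fixture()
  om <- occurrence_matrix(fx$sightings)
  strata <- c(fx$bays, OUTSIDE)
  dists <- lapply(strata, function(s) bootstrap_budget(fx$scans, s, B = 100, seed = 4))
  names(dists) <- strata
  tds <- lapply(fx$bays, function(b) time_inside_distribution(fx$scans, b))
  names(tds) <- fx$bays
  cfg <- study_config(fx$study_days, om$individuals, seed = 99)
  s1 <- simulate_study(cfg, om, fx$acoustic, dists, tds, keep_daily = TRUE)
  s2 <- simulate_study(cfg, om, fx$acoustic, dists, tds, keep_daily = TRUE)
  expect_identical(s1, s2)

  # a missing stratum distribution fails before any simulation work
  expect_error(simulate_study(cfg, om, fx$acoustic, dists[fx$bays], tds),
               class = "spinnerbudget_coverage_error")
  expect_error(simulate_study(cfg, om, fx$acoustic, dists, tds["Makako"]),
               class = "spinnerbudget_coverage_error")
})

test_that("every simulated day is a valid convex budget and cumulates to the mean", {
  fx <- small_fixture()
  om <- occurrence_matrix(fx$sightings)
  strata <- c(fx$bays, OUTSIDE)
  dists <- lapply(strata, function(s) bootstrap_budget(fx$scans, s, B = 100, seed = 6))
  names(dists) <- strata
  tds <- lapply(fx$bays, function(b) time_inside_distribution(fx$scans, b))
  names(tds) <- fx$bays
  sim <- simulate_study(study_config(fx$study_days, om$individuals, seed = 13),
                        om, fx$acoustic, dists, tds, keep_daily = TRUE)
  d <- sim$daily
  p <- as.matrix(d[, c("p_rest", "p_social", "p_travel")])
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(d$a[d$stratum == OUTSIDE] == 0))
  expect_true(all(d$a >= 0 & d$a <= 1))
  # cumulative budget is the unweighted mean of that individual's daily budgets
  for (id in om$individuals) {
    expect_equal(
      unname(colMeans(p[d$individual_id == id, , drop = FALSE])),
      unlist(sim$cumulative[sim$cumulative$individual_id == id,
                            c("p_rest", "p_social", "p_travel")],
             use.names = FALSE)
    )
  }
})

test_that("population means match the closed-form expectation at 1e4 individual-days", {
  cfg <- generator_config(n_individuals = 50L, n_days = 200L, seed = 31)
  syn <- generate_synthetic(cfg)
  pin <- pipeline_inputs(syn, B = 400L)
  days <- syn$truth$study_days
  sim <- simulate_study(study_config(days, pin$om$individuals, seed = 32),
                        pin$om, syn$acoustic, pin$dists, pin$tds,
                        presence_probs = pin$presence)
  E <- closed_form_cumulative(pin$om, syn$acoustic, pin$dists, pin$tds,
                              pin$presence, days)
  sim_m <- as.matrix(sim$cumulative[, c("p_rest", "p_social", "p_travel")])
  for (k in 1:3) {
    diff <- sim_m[, k] - E[, k]
    mc_se <- sd(diff) / sqrt(length(diff))
    expect_lt(abs(mean(diff)), 3 * mc_se)
  }
})

test_that("population summary computes percentage statistics across individuals", {
  b <- data.frame(individual_id = c("A", "B"),
                  p_rest = c(0.6, 0.8), p_social = c(0.3, 0.1),
                  p_travel = c(0.1, 0.1))
  s <- summarize_population(b)
  expect_equal(s$mean_pct[s$state == "rest"], 70)
  expect_equal(s$sd_pct[s$state == "rest"], sd(c(60, 80)))
  expect_equal(s$sd_pct[s$state == "travel"], 0)
  expect_equal(sum(s$mean_pct), 100)
  expect_error(summarize_population(b[1, ]), "2 individuals")
})
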