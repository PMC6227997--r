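# spinnerbudget

Estimation of the **daytime cumulative activity budget** of individually
identified spinner dolphins (*Stenella longirostris*) that use sheltered
resting bays, and of their **exposure to human activities**, from three
field data streams collected by a resting-bay monitoring programme:

1. **Photo-identification sightings** — one record per (individual, day,
   bay), giving each dolphin's relative occurrence across bays;
2. **Passive acoustic monitoring** — one presence/absence call per
   (bay, day), with explicit missing days (recorder malfunction);
3. **Focal-follow scan samples** — the predominant group activity
   (rest / social / travel) and the counts of boats, kayaks and swimmers
   within 100 m, recorded every 10 min during group follows inside and
   outside the bays.

The package is aimed at behavioural ecologists and managers who need
individual-level, study-long activity budgets when no single data stream
observes an individual continuously.

## The model

Stratum activity budgets are scan-count ratios. For a stratum *s* (one of
the bays, or outside all bays), the point budget is
`p̂_k(s) = n_k(s) / n(s)` for each state *k ∈ {rest, social, travel}*, and
its uncertainty is carried as a bootstrap density distribution: the *n(s)*
observed states are resampled with replacement and the budget recomputed
*B* = 1000 times.

For each individual *j* and study day *t* the simulation then draws:

- a bay *i* from *j*'s allocation probabilities (sighting counts normalised
  per individual);
- the acoustic gate: if bay *i* was called absent on day *t*, *j* moves to
  the outside stratum; if the call is missing, presence is imputed as a
  Bernoulli draw at the bay's observed presence rate;
- the proportion of daytime spent inside the bay, *a*, drawn from the bay's
  empirical per-follow time-inside sample (*a* = 0 outside; *b* = 1 − *a*);
- one bootstrap replicate of the bay budget and one of the outside budget.

The daily budget is the convex combination

    daily budget = a × (budget inside bay_i) + b × (budget outside bays)

and the cumulative budget of individual *j* is the mean of its daily
budgets over the study period (601 days × 12 daytime hours by default).

Exposure analysis classifies each scan as **approached** (≥ 1 boat, kayak
or swimmer within 100 m) or **unapproached**, extracts maximal runs of
identical state within each follow (each scan standing for its 10-min
window), and summarises interval durations by state and platform.

A synthetic-data generator (`generate_synthetic()`) produces all three
streams from a known ground truth — Dirichlet bay affinities, per-bay
presence rates, true stratum budgets, Beta time-inside distributions and a
two-state Markov approach chain — so the whole pipeline is testable for
parameter recovery without any field data.

## Worked example

A study-scale synthetic run (235 individuals, 4 bays, 601 days):

```r
library(spinnerbudget)

syn <- generate_synthetic(generator_config(seed = 7))
om  <- occurrence_matrix(syn$sightings)

strata <- c(kona_bays(), OUTSIDE)
dists  <- setNames(lapply(strata, function(s)
            bootstrap_budget(syn$scans, s, B = 1000)), strata)
tds    <- setNames(lapply(kona_bays(), function(b)
            time_inside_distribution(syn$scans, b)), kona_bays())

sim <- simulate_study(study_config(syn$truth$study_days, om$individuals, seed = 8),
                      om, syn$acoustic, dists, tds)
summarize_population(sim$cumulative)
#>    state mean_pct sd_pct min_pct max_pct
#> 1   rest     52.5   5.13    42.7    61.4
#> 2 social     30.0   3.47    23.8    35.6
#> 3 travel     17.5   1.93    14.7    23.1

exposure_proportion(syn$scans)          # 0.840
interval_summary(extract_runs(syn$scans))$medians
#>          state platform   n median_minutes
#> 1   APPROACHED     BOAT 662             70
#> 2 UNAPPROACHED     BOAT 565             10
#> 3   APPROACHED     LAND 234             70
#> 4 UNAPPROACHED     LAND 208             10
```

Individuals here spend on average 52.5% (s.d. 5.1) of the daytime resting:
the population mixes a high-rest bay (true rest 72.6% in the Makako
analogue) with rest-poorer bays and travel-heavy outside time, weighted by
each individual's bay affinity and the bays' acoustic presence rates. The
approached share of scans (84.0%) and the 70-min approached / 10-min
unapproached median intervals recover the generator's approach chain
(stationary fraction 5/6; geometric run-length medians 70 and 10 min).

The same analysis runs end-to-end from CSV files through `run_all()` (see
`?run_all`), which writes per-stratum budgets, bootstrap replicates,
cumulative budgets, exposure intervals, histograms, JSON summaries and a
digest-bearing manifest; `report()` prints a human-readable summary.

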