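---
title: "Methods: cumulative daytime activity budgets from fused monitoring streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative daytime activity budgets from fused monitoring streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinnerbudget)
```

## The estimation problem

Spinner dolphins forage cooperatively offshore at night and retreat to a
handful of sheltered bays to rest and socialise during the day. No single
monitoring method observes an identified individual continuously over a
multi-year study: photo-identification surveys visit each bay a few days a
month, bottom-mounted acoustic recorders tell only whether *some* dolphins
used a bay on a day, and focal follows sample group behaviour for hours at
a time without individual identity. The cumulative activity budget — the
proportion of study-long daytime an individual spent resting, socialising
and travelling — must therefore be assembled by simulation from the three
partial views.

This vignette documents the model as implemented, its assumptions, the
parameters that matter, the synthetic-data generator used for testing, and
the numerical conventions.

## Stratum budgets and their uncertainty

Instantaneous scan samples record the predominant group activity every
10 min; each scan is taken to represent its whole 10-min window, so every
"proportion of time" in the package is a scan-count ratio. `point_budget()`
computes state counts over total scans per stratum (each of the four bays,
plus the pooled outside-bays stratum). Boat- and land-based scans are
pooled within a stratum by default; a `platform` argument restricts them
when a platform-specific budget is wanted.

Sampling uncertainty is carried as a bootstrap density distribution
(`bootstrap_budget()`): the stratum's *n* observed states are resampled
with replacement and the budget recomputed, *B* = 1000 times by default.
Replicates are kept raw — no kernel smoothing — because the simulation only
ever needs to *draw* from the distribution. The resampling treats scans as
exchangeable within a stratum and therefore ignores within-follow
autocorrelation of behaviour; this is a known limitation (see below), and
the generator offers a behavioural-persistence option to probe it.

## Time spent inside a bay

`time_inside_distribution()` builds, per bay, the empirical sample of the
proportion of the 12-h daytime window a follow documented inside the bay:
10 min × (scans inside) / 720 min, clipped to [0, 1]. The follow, not the
day, is the observation unit — follows are the independent realisations of
"a group's visit as sampled" — and follows that never touch the bay
contribute nothing. Clipping matters only for follows longer than the
daytime window. The daily simulation draws its `a` value uniformly with
replacement from this sample, so the empirical shape (including skew) is
propagated without any distributional assumption.

## The daily allocation chain

For each individual and study day, in order:

1. **Allocation.** A bay is drawn from the individual's allocation
   probabilities — sighting counts per bay normalised per individual.
   Every individual is allocated to some bay *before* acoustic gating;
   the outside stratum is reached only through the gate. This is the most
   literal reading of an allocation-then-confirmation design, and it makes
   the occurrence matrix the sole driver of habitat preference.
2. **Acoustic gate.** If the bay's call for the day is ABSENT, the bay was
   empty and the individual is moved outside. If the call is MISSING, the
   day is imputed with a single Bernoulli draw at the bay's observed
   presence rate (#present / #non-missing days).
3. **Time inside.** `a` is drawn from the bay's time-inside sample
   (`a = 0` outside); `b = 1 − a` exactly, i.e. all daytime minutes not
   inside the allocated bay are "outside" — there is no third stratum and
   no travel-time accounting between strata.
4. **Budget draws.** One bootstrap replicate of the bay's budget and one of
   the outside budget are drawn *per individual-day*, so budget
   uncertainty is allocated to dolphins independently rather than shared
   across the population within a day.
5. **Daily budget.** The convex combination
   `a × (bay budget) + b × (outside budget)`; convexity guarantees a valid
   budget (non-negative, unit sum) for every simulated day.

The cumulative budget is the unweighted mean of the individual's daily
budgets (all days share the same 720-min daytime window), reported with
`total_minutes = days × 720`.

Two design points were genuinely open and are resolved as follows. The
ABSENT gate sends dolphins outside rather than re-allocating them to a
second bay: an empty-bay call says nothing about which *other* bay the
group used, and individuals are assumed to visit at most one bay per day,
so outside is the only stratum left. And `a` is drawn per dolphin rather
than once per bay-day: visits of different groups to the same bay differ
in length, and per-dolphin draws propagate that variance into
between-individual spread (a shared draw would push it into day-to-day
variance instead).

## Random-number contract

The whole simulation is reproducible from a single integer seed
(`study_config(seed = ...)`). Draws are made per individual in fixed
blocks over days — all bay allocations, then all presence-imputation
uniforms, then time-inside draws grouped by bay, then bay and outside
replicate indices — and the number of draws per block is fixed (presence
uniforms and outside replicate indices are drawn for every day whether or
not they are consumed), so the stream alignment never depends on the data.
Identical inputs and seed give byte-identical outputs.

## Exposure intervals

A scan is approached when boats + kayaks + swimmers ≥ 1 within 100 m.
`extract_runs()` encodes maximal runs of identical exposure state per
follow; a run of *k* scans lasts 10·*k* min (a single-scan run is 10 min,
matching the cadence's granularity, rather than the degenerate 0 of a
last-minus-first convention). The first and last interval of a follow are
flagged censored. A gap of more than 1.5 × the nominal cadence breaks a
run into two pieces, both flagged censored at the break, so continuity is
never fabricated across an observation dropout — note this means two
consecutive *pieces* may share a state, whereas uninterrupted intervals
strictly alternate. Medians use the conventional mean-of-middle-two rule
for even counts; censored intervals are included by default
(`include_censored = FALSE` excludes them), since the shortest observed
durations are genuinely short rather than truncation artefacts under the
10-min median granularity — both modes are one flag apart.

## The synthetic-data generator

`generate_synthetic()` emulates the monitoring programme's structure with
a known ground truth. Its defaults are fixed once, at the study's printed
scale and rates, and are not tuning knobs:

| parameter | default | basis |
|---|---|---|
| catalogue / days / bays | 235 / 601 / 4 | programme scale |
| presence probability | 0.90 / 0.65 / 0.37 / 0.51 | per-bay documented daily presence rates |
| acoustic missing rate | 0.060 / 0.195 / 0.063 / 0.108 | 1 − recording days ÷ 601, per bay |
| survey cadence | 2 / 4 / 2 / 4 days per month | programme survey design |
| Makako budget | (0.726, 0.190, 0.084) | documented bay-specific budget |
| other bay budgets | (0.60, 0.35, 0.05) | documented qualitative ranges (inside rest > 60%, travel ≈ 5%) |
| outside budget | (0.36, 0.34, 0.30) | documented ranges (outside rest < 40%, travel ≈ 30%) |
| approach chain stay probs | 0.9 approached / 0.5 unapproached | stationary approached fraction 5/6 with geometric run-length medians 70 and 10 min |
| detection probability | 0.45 | calibrated a priori to the documented mean of ≈ 12 sightings per individual |
| bay affinity | Dirichlet, α ∝ documented bay-use prevalence, concentration 1.5 | heterogeneous individuals, Makako-dominant |
| time inside | Beta(7.6, 2.4), mean 0.76 | skewed-long bay visits |
| outside-day probability | 0.25 | individuals spend roughly a quarter of days outside bays |

The generator simulates latent truth first — each individual's
bay-or-outside day from its affinity, bay-day presence as a Bernoulli per
bay — then emits the three observation streams: sightings on surveyed
bay-days with imperfect detection, acoustic calls with missingness, and
follows (one per surveyed present bay-day, plus dedicated outside follows
with log-normal durations) whose activity states are independent draws
from the stratum's true budget and whose exposure states follow the
Markov approach chain.

Two deliberate realism limits matter for interpreting green tests. First,
the latent truth lets individuals stay outside directly, which the
estimator cannot represent (it reaches outside only through the acoustic
gate) — tests use this mismatch to quantify occupancy bias rather than
hide it. Second, default activity states have no within-follow
persistence, matching the bootstrap's exchangeability assumption; real
behavioural data are autocorrelated, so passing recovery tests show
correctness *under the model's own assumptions*, not robustness to their
violation. The generator has no spatial movement, no photographic
distinctiveness structure, and no acoustic waveform model.

## Numerical conventions and degenerate inputs

- Budgets must sum to 1 within 1e-9; occurrence probabilities row-sum to 1
  within 1e-12 (pure count ratios, so this is exact up to float division).
- Reported whole-number percentages round half *up* (`round_half_up()`),
  the convention that reproduces documented integer percentages from their
  counts; base R's round-half-even is avoided for reporting.
- A bay with zero non-missing acoustic days raises a configuration error
  asking for a prior presence probability rather than guessing one.
- Empty strata, bays without follows, and missing distribution coverage
  fail fast with classed errors (`config` / `validation` / `coverage`)
  before any simulation work.
- Duplicate sighting records collapse to one sighting-day with a warning;
  duplicate acoustic (bay, day) records are an error, since the two calls
  could conflict.
- Single-scan follows are retained (they carry one 10-min interval).

## Problem sizes used by the test suite

The suite checks Monte Carlo properties at sizes chosen to keep assertions
sharp while the full run stays fast: the closed-form-expectation oracle at
50 individuals × 200 days (10⁴ individual-days, 3 Monte-Carlo-s.e.
tolerance on the mean difference per state), ground-truth recovery at 30
individuals × 400 days (3 s.e. per recovered parameter, with the Markov
variance-inflation factor (1+ρ)/(1−ρ) applied to exposure), and one full
study-scale run (235 × 601, B = 1000), which completes in seconds on one
CPU. `scripts/acceptance.R` re-runs the study-scale pipeline from scratch
and writes its headline quantities as JSON.

## Known limitations

- Bootstrap resampling of individual scans understates budget uncertainty
  when behaviour is autocorrelated within follows.
- The occurrence matrix conflates preference with survey effort and
  detectability; the per-bay documented-individual percentages are raw
  count ratios, unadjusted for unequal effort between bays.
- The acoustic gate is bay-level: one ABSENT call empties a bay for every
  allocated individual that day.
- Night-time (foraging) behaviour is out of scope; budgets cover the
  06:00–18:00 window only.
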