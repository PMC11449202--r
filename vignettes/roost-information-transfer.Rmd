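---
title: "Testing roost information transfer from movement data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing roost information transfer from movement data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roostinfo)
```

## The scientific problem

Egyptian fruit bats commute nightly from large cave-roosts to fruit
trees, memorise the locations of the trees they use, and revisit them for
weeks. Most of their tree species fruit seasonally and predictably, but a
small fraction (about 7%, mostly *Ficus*) fruit at unpredictable times.
The information-centre question is whether naive bats learn *when* such a
tree has become worth visiting from cues carried into the roost by
informed conspecifics — and, in this system, whether an odour cue alone
suffices, with spatial memory supplying the *where*, so that no
following behaviour is needed.

`roostinfo` implements the three analyses this question requires, driven
either by field data (fix, tree, manifest and roster CSVs) or by a
synthetic colony generator with ground truth:

1. segmentation of high-frequency localization streams into tree visits;
2. a resampling test comparing post-manipulation visitation of focal
   trees against routine movement;
3. dyadic tree-encounter detection and per-lag logistic models of
   new-tree discovery.

## Track filtering and first-passage segmentation

Raw fixes carry a localization covariance. Quality filtering drops fixes
whose larger covariance eigenvalue exceeds `quality_var_max` (default
400 m², i.e. roughly a 20 m standard deviation; the field pre-processing
prescribes covariance-based filtering without a specific statistic, and
the eigenvalue bounds error in the worst direction). A causal speed
filter then removes any fix arriving faster than `speed_max = 20` m/s
relative to the last retained fix.

Visits are found by first-passage segmentation within each bat-night
(nights run noon-to-noon, so one foraging night shares an index and no
dwell can chain across days through the roost). A candidate cloud opens
when `min_fixes = 5` consecutive fixes lie within `fp_radius = 50` m of
their own mean; the centre is refined by alternating mean-recomputation
and membership re-extension until stable. Two boundary conventions
matter numerically:

- **Boundary trim.** At a 0.25 Hz sampling interval and a 10 m/s commute
  speed, the last approach fix falls up to 40 m from the tree — inside
  `fp_radius` — so raw cloud boundaries systematically include commuting
  fixes and inflate durations. After convergence, leading and trailing
  member fixes farther than `boundary_trim_k = 4` times the median
  per-axis localization sd (4 × 5 m = 20 m at the nominal error) are
  trimmed. At these defaults the trim threshold sits at half the
  inter-fix commute displacement, which bounds each endpoint's timing
  error by about half a sampling interval; a genuine dwell fix exceeds
  20 m only with probability ~3e-4.
- **Flyovers.** Straightness is net displacement over cumulative path
  length (0 by convention for a zero-length path). An episode is a
  flyover — a straight pass over a tree rather than a visit — when
  straightness exceeds `straightness_max = 0.9` *and* its duration is
  below `min_duration`. Flyovers are excluded from every downstream
  visitation count.

Visit centroids are attributed to the nearest mapped tree within
`match_radius = 50` m, ties broken toward the smallest `tree_id`;
`min_duration` defaults to 4 s, the shortest visit retained in the field
data. All parameters live in `segmenter_params()`.

## The manipulation test

The observed statistic is the cumulative proportion of the naive cohort
visiting any focal tree within `w` nights of the release (nights
`m + 1 .. m + w`), pooled across release campaigns by summing numerators
and denominators; smeared bats are excluded from the naive cohort and
reported separately.

The null asks how often a same-sized cohort reaches that proportion under
routine movement, when the focal trees bear no fruit. One iteration draws
`w`-night intervals without replacement, in random order, accumulating
each interval's tracked bats and distinct focal visitors until the pooled
count reaches `min_cohort = 70`; the pooled proportion is recorded, and
the procedure repeats for `n_iterations = 215` (the midpoint of the
200–230 range used in the field analysis). Three conventions are worth
stating because the field description leaves them open:

- a bat tracked in several pooled intervals counts once per interval
  (interval-bat exposures), matching the "cumulate the visit counts"
  reading of pooling;
- null cohorts pool bats across roosts;
- the p-value is `(#{null ≥ observed} + 1) / (n_iterations + 1)` — the
  add-one convention avoids a literal zero from a finite null, and
  counting ties against the observation is conservative.

`run_manipulation_test()` assembles the per-window report (windows 1–6,
observed proportion, null mean, empirical 2.5/97.5 percentiles, p) and
excludes the manipulation-response windows from the null automatically;
fruiting periods must be supplied via `exclude_nights`, since phenology
ingestion is out of scope.

## Encounters and new-tree discovery

Two bats meet when non-flyover visits to the same tree overlap in time
with positive length (touching endpoints do not count). For each meeting
night `m`, each member in turn is the focal bat: the partner's trees are
those it visited on nights `m - 3 .. m - 1`; the focal's candidate new
trees at lag `L` are those it visits in the three nights anchored at
`m + L - 1` (i.e. nights `m + L .. m + L + 2`) minus everything it had
visited up to the meeting; the response is whether the two sets
intersect. Lags therefore *shift* a fixed-width post window rather than
expanding it — the lag semantics were open, and shifting keeps per-lag
responses comparable in exposure; both conventions are available through
`pre_window`/`post_window`.

Controls are never-met co-tracked dyads, sampled once overall (not
re-sampled per lag), one per met dyad without replacement, matched on the
meeting's calendar month, with a pseudo-meeting night drawn uniformly
from the dyad's co-tracked nights in that month. Per-lag effects come
from `stats::glm` logistic fits of response on met status; with a single
binary predictor the fitted group probabilities equal the raw response
frequencies, which the tests exploit as an identity check. Single-class
responses and completely separated tables are flagged `degenerate`
instead of reporting diverging coefficients. P-values are reported raw,
one model per lag, without multiplicity correction (mirroring how per-lag
results are conventionally displayed); readers should treat 6 raw tests
accordingly.

## What the generator emulates — and what it does not

`simulate_tracks()` produces, per bat-night, a central-place trip:
straight 10 m/s commutes between 1–5 tree stops drawn from a personal
repertoire (1–5 trees, revisit probability 0.8) with log-normal dwells,
sampled at 4 s intervals with isotropic Gaussian 5 m localization noise
and a matching per-fix covariance. Ground truth for every dwell is
logged, which is what makes segmentation testable to 100% recovery.
Choices made once, on realism grounds:

- dwell durations: log-normal, median 9 min, `sdlog = 0.7`, truncated to
  the reported 4 s–50 min range; the sdlog keeps sub-detection-floor
  dwells (< ~20 s, unresolvable at 5 fixes × 4 s) rare rather than
  impossible;
- consecutive stops (and stops vs the roost) are at least 200 m apart —
  distinct remembered canopies are spatially distinct — which keeps
  distinct dwell clouds separable at `fp_radius = 50` m;
- the sampling grid re-anchors at each behavioural segment, so arrivals
  and departures are themselves sampled; tag schedules in the field are
  not phase-locked to behaviour, but without this the dwell-boundary
  phase alone contributes up to two intervals of irreducible duration
  error;
- one roost at the landscape edge by default (`n_roosts` adds more;
  only manifest bookkeeping changes).

`inject_manipulation()` adds, for each responding bat (naive with
probability `response_prob`, smeared with `manipulated_response_prob`), a
single pre-trip excursion to a focal tree on a night drawn from
`lag_pmf`; the default mass (3, 2, 2, 2, 0, 1)/10 over lags 1–6
reproduces the observed response-lag tally.

For statistical calibration at the study's cohort sizes, trajectory
simulation is needless; the visit-level generators
(`make_interval_roster`, `simulate_routine_visits`,
`simulate_manipulation_cohort`) draw focal visits as Bernoulli
bat-nights, with the per-night rate set to `1 - (1 - r)^(1/6)` so a
six-night window hits with probability exactly `r`.

The generator does **not** emulate: realistic flight tortuosity, wind or
energetics; fruiting phenology and its seasonal visit dynamics; roost
social structure; heavy-tailed or spatially correlated localization
error; tag dropout and gaps. Passing tests therefore demonstrate the
*correctness of the inference machinery* under known ground truth, not
field-data performance: with real tracks, gap handling and the quality
filter will bind, segmentation parameters may need tuning, and the
baseline visit rates are properties of the data, not the code.

## Problem sizes used by the test-suite

The packaged tests run the segmentation oracle on 50 simulated bat-nights
(10 bats × 5 nights, 300 trees, 5 m noise, seed fixed), the power check
on 20 replicate experiments at the reported effect sizes (56 naive bats,
response probability 0.18, routine six-night rate 0.012, 60 routine
cohorts of 72 bats) and the type-I calibration on 500 null replicates —
sizes chosen so the whole suite completes in about a minute while leaving
the binomial acceptance bands meaningful.

## Known limitations

- The first-passage refinement is one reasonable reading of a "cloud of
  fixes" algorithm; other adaptive rules (e.g. different convergence or
  re-entry handling) will place visit boundaries slightly differently.
- `sample_routine_null` treats the supplied visit table as routine; the
  caller must exclude fruiting and manipulation periods.
- Coordinates are local planar metres throughout; ingest lat/lon via a
  local equirectangular projection before use (valid for extents up to
  ~20 km).
- Dyad analyses condition on tagged bats only; encounters with untagged
  individuals are invisible, as in the field data.

## A complete run

```{r, eval = FALSE}
cfg <- system.file("extdata", "demo_config.yaml", package = "roostinfo")
res <- run_pipeline(cfg)
res$manipulation_report
plot_manipulation_test(res$manipulation_report)
```
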