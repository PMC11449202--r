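# roostinfo

Movement-based tests of roost information transfer in wild fruit bats.

Colonial animals may use communal roosts as *information centres*: a
successful forager returns carrying cues about a newly available resource,
and naive roost-mates exploit those cues. For Egyptian fruit bats
(*Rousettus aegyptiacus*) foraging on fruit trees that are spatially fixed
but fruit at unpredictable times, the interesting variant of this
hypothesis is that a naive bat does not need to *follow* an informed one:
an odour cue in the roost, matched against the bat's spatial memory of
where that tree species grows, is enough ("associative recall").
`roostinfo` implements the movement-analysis machinery needed to test this
in the field with high-frequency reverse-GPS tracking:

- **Track pre-processing and segmentation** (`filter_fixes`,
  `segment_visits`): covariance-eigenvalue quality filtering, a causal
  20 m/s speed filter, and first-passage segmentation of each bat-night
  into tree visits — runs of at least `min_fixes` fixes confined within
  `fp_radius` of an iteratively refined cloud centre — annotated with the
  nearest mapped tree and separated from straight *flyovers*.
- **Manipulation inference** (`cumulative_visit_proportion`,
  `sample_routine_null`, `permutation_pvalue`, `run_manipulation_test`):
  the cumulative proportion of a naive cohort visiting focal trees within
  1–6 nights of an odour manipulation, compared against a resampled
  routine-movement null. Each null iteration draws random same-length
  night intervals without replacement, pooling intervals until the tracked
  cohort reaches `min_cohort` (70) bats, for `n_iterations` (215)
  proportions; the one-tailed p-value is the exceedance frequency
  `p = (#{null ≥ observed} + 1) / (n + 1)`.
- **Dyadic encounters and discovery** (`detect_encounters`,
  `build_discovery_records`, `fit_lag_models`): co-occurrence of two bats
  on one tree with positive time overlap; for each meeting, whether the
  focal bat subsequently visits a *new* tree its partner had used in the
  three nights before the meeting; per-lag (1–6 nights) logistic
  regressions of that binary response on met vs matched never-met control
  dyads.
- **Synthetic colony generator** (`generate_landscape`,
  `simulate_tracks`, `inject_manipulation`, plus fast visit-level
  generators): nightly roost–trees–roost trips with memory-driven
  revisitation, Gaussian localization noise and a ground-truth visit log,
  so the whole pipeline is testable end to end without field data.

## Worked example

The three-campaign manipulation fixture shipped with the package encodes
the release bookkeeping (72 tagged bats: 16 odour-smeared, 56 naive) and
the focal-tree visits observed within six nights. Against a simulated
routine-movement background (60 six-night cohorts of 72 bats, six-night
focal-visit rate 0.012):

```r
library(roostinfo)
d <- manipulation_demo()
obs <- pooled_visit_proportion(d$visits, d$manifest,
                               focal_tree_ids = c(1, 2),
                               window_nights = 6, role = "naive")
cat(sprintf("naive: %d/%d = %.3f\n",
            obs$n_visitors, obs$n_cohort, obs$proportion))
#> naive: 10/56 = 0.179

roster  <- make_interval_roster(n_intervals = 60, bats_per_interval = 72)
routine <- simulate_routine_visits(roster, rate_per_window = 0.012,
                                   seed = 1)
null <- sample_routine_null(routine, roster, focal_tree_ids = 1,
                            window_nights = 6, min_cohort = 70,
                            n_iterations = 215, seed = 7,
                            candidate_starts = attr(roster, "interval_starts"))
cat(sprintf("null mean %.4f, 95%% interval [%.4f, %.4f]\n",
            mean(null$proportions),
            quantile(null$proportions, 0.025),
            quantile(null$proportions, 0.975)))
#> null mean 0.0124, 95% interval [0.0000, 0.0417]
permutation_pvalue(obs$proportion, null)
#> [1] 0.00462963
```

About 18% of naive bats visited a focal tree within six nights of the
manipulation, while under routine movement a same-sized cohort almost
never exceeds 4%; the observed proportion beats all 215 null draws, so the
one-tailed p-value is at its resolution floor 1/216 ≈ 0.005.

A full simulated pipeline run (landscape → trajectories → segmentation →
manipulation test → encounter models) is one call:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "roostinfo"))
```

or, from a shell, `Rscript inst/cli/roostinfo-cli.R run-all --config ...`
(subcommands `simulate`, `segment`, `manip-test`, `encounters` wrap the
individual stages).

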