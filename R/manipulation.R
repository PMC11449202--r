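#' Cumulative focal-tree visitation proportion
#'
#' Fraction of a cohort with at least one non-flyover visit to any focal
#' tree during the `window_nights` nights following `start_night`, i.e.
#' nights `start_night + 1 .. start_night + window_nights`. This is the
#' accumulative counting used for the post-manipulation windows: the
#' numerator is distinct visiting bats, the denominator the cohort size.
#'
#' @param visits visit tibble (`bat_id, night_index, tree_id`, optional
#'   `flyover`).
#' @param cohort_ids character vector of cohort bat ids (non-empty).
#' @param focal_tree_ids focal tree ids.
#' @param start_night anchor night (the manipulation night).
#' @param window_nights window length, >= 1.
#' @return list with `proportion`, `n_visitors`, `n_cohort`, `visitors`.
#' @export
cumulative_visit_proportion <- function(visits, cohort_ids, focal_tree_ids,
                                        start_night, window_nights) {
  if (length(cohort_ids) == 0) {
    stop("undefined proportion: empty cohort", call. = FALSE)
  }
  stopifnot(window_nights >= 1)
  visitors <- focal_visitors(visits, focal_tree_ids,
                             start_night + 1, start_night + window_nights)
  visitors <- intersect(visitors, cohort_ids)
  list(
    proportion = length(visitors) / length(cohort_ids),
    n_visitors = length(visitors),
    n_cohort = length(cohort_ids),
    visitors = visitors
  )
}

# distinct bats with a non-flyover focal visit in nights [from, to]
focal_visitors <- function(visits, focal_tree_ids, from, to) {
  if (nrow(visits) == 0) return(character(0))
  fo <- if ("flyover" %in% names(visits)) visits$flyover else FALSE
  sel <- !is.na(visits$tree_id) & visits$tree_id %in% focal_tree_ids &
    visits$night_index >= from & visits$night_index <= to & !fo
  unique(visits$bat_id[sel])
}

#' Pooled visitation proportion across manipulation campaigns
#'
#' Campaigns released on different nights are pooled by counting each
#' campaign's visitors within its own window and summing numerators and
#' denominators.
#'
#' @param visits visit tibble.
#' @param manifest manifest tibble (`bat_id, role, night`).
#' @param focal_tree_ids focal tree ids.
#' @param window_nights window length in nights.
#' @param role which cohort to pool (`"naive"` or `"manipulated"`).
#' @return list with `proportion`, `n_visitors`, `n_cohort`.
#' @export
pooled_visit_proportion <- function(visits, manifest, focal_tree_ids,
                                    window_nights = 6, role = "naive") {
  manifest <- manifest[manifest$role == role, , drop = FALSE]
  if (nrow(manifest) == 0) {
    stop("undefined proportion: empty cohort", call. = FALSE)
  }
  n_vis <- 0L
  for (night in unique(manifest$night)) {
    cohort <- manifest$bat_id[manifest$night == night]
    n_vis <- n_vis + cumulative_visit_proportion(
      visits, cohort, focal_tree_ids, night, window_nights
    )$n_visitors
  }
  list(
    proportion = n_vis / nrow(manifest),
    n_visitors = n_vis,
    n_cohort = nrow(manifest)
  )
}

#' Resample a routine-movement null distribution
#'
#' Builds the null distribution of focal-tree visitation proportions under
#' routine movement. Per iteration, candidate start-nights of
#' `window_nights`-night intervals are drawn without replacement (in random
#' order); each drawn interval contributes its tracked-bat count and its
#' distinct focal-visitor count, and intervals are accumulated until the
#' pooled tracked-bat count reaches `min_cohort` (mimicking the
#' manipulation's cohort size); the pooled proportion is recorded. A bat
#' tracked in several pooled intervals counts once per interval
#' (interval-bat exposures). The caller is responsible for restricting
#' `visits`/`exclude_nights` to periods when the focal trees bore no fruit
#' and no manipulation was running.
#'
#' @param visits visit tibble of routine movement.
#' @param roster roster tibble (`bat_id, start_night, end_night`); a bat is
#'   tracked in an interval when its tracking range overlaps it.
#' @param focal_tree_ids focal tree ids.
#' @param window_nights interval length in nights (1-6 in practice).
#' @param min_cohort minimum pooled tracked-bat count per iteration.
#' @param n_iterations number of resampling iterations (the field analysis
#'   used 200-230; 215 is the midpoint).
#' @param seed optional integer seed.
#' @param exclude_nights nights that may not appear in any sampled interval
#'   (fruiting or manipulation periods).
#' @param candidate_starts optional explicit vector of interval
#'   start-nights (interval = nights `s + 1 .. s + window_nights`); default
#'   all starts within the roster's tracked range.
#' @return an object of class `routine_null`: list with `proportions`,
#'   `window_nights`, `min_cohort`, `n_iterations`, and the per-interval
#'   summary table `intervals`.
#' @export
sample_routine_null <- function(visits, roster, focal_tree_ids,
                                window_nights = 6, min_cohort = 70,
                                n_iterations = 215, seed = NULL,
                                exclude_nights = integer(0),
                                candidate_starts = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(window_nights >= 1, min_cohort >= 1, n_iterations >= 1)
  if (is.null(candidate_starts)) {
    lo <- min(roster$start_night)
    hi <- max(roster$end_night)
    if (hi - lo + 1 < window_nights) {
      stop("infeasible null: tracked range shorter than the window",
           call. = FALSE)
    }
    candidate_starts <- (lo - 1):(hi - window_nights)
  }
  keep <- vapply(candidate_starts, function(s) {
    !any((s + 1):(s + window_nights) %in% exclude_nights)
  }, logical(1))
  candidate_starts <- candidate_starts[keep]

  intervals <- summarise_intervals(visits, roster, focal_tree_ids,
                                   candidate_starts, window_nights)
  intervals <- intervals[intervals$n_tracked > 0, , drop = FALSE]
  if (nrow(intervals) == 0 || sum(intervals$n_tracked) < min_cohort) {
    stop("infeasible null: candidate intervals cannot reach min_cohort",
         call. = FALSE)
  }

  proportions <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    ord <- sample.int(nrow(intervals))
    cum_tracked <- cumsum(intervals$n_tracked[ord])
    take <- seq_len(min(which(cum_tracked >= min_cohort)))
    proportions[it] <- sum(intervals$n_visitors[ord][take]) /
      cum_tracked[length(take)]
  }
  structure(
    list(
      proportions = proportions, window_nights = window_nights,
      min_cohort = min_cohort, n_iterations = n_iterations,
      intervals = intervals
    ),
    class = "routine_null"
  )
}

summarise_intervals <- function(visits, roster, focal_tree_ids,
                                starts, window_nights) {
  n_tracked <- integer(length(starts))
  n_visitors <- integer(length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    tracked <- roster$bat_id[roster$start_night <= s + window_nights &
                               roster$end_night >= s + 1]
    vis <- focal_visitors(visits, focal_tree_ids, s + 1, s + window_nights)
    n_tracked[k] <- length(tracked)
    n_visitors[k] <- length(intersect(vis, tracked))
  }
  tibble(start_night = starts, n_tracked = n_tracked,
         n_visitors = n_visitors)
}

#' One-tailed resampling p-value
#'
#' Probability, under routine movement, of a visitation proportion at least
#' as large as the observed one: `p = (#\{null >= observed\} + 1) /
#' (n_iterations + 1)`. The add-one convention avoids a zero p-value from a
#' finite null; ties count against the observation.
#'
#' @param observed observed proportion.
#' @param null a `routine_null` object (or numeric vector of null
#'   proportions).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null) {
  props <- if (inherits(null, "routine_null")) null$proportions else null
  if (length(props) == 0) stop("empty null distribution", call. = FALSE)
  (sum(props >= observed) + 1) / (length(props) + 1)
}

#' Pre-manipulation baseline visitation proportion
#'
#' Same counting rule as [cumulative_visit_proportion()], applied to a
#' window ending at the manipulation night (e.g. the two preceding weeks).
#'
#' @inheritParams cumulative_visit_proportion
#' @param end_night last night of the baseline window (typically the
#'   manipulation night); the window covers
#'   `end_night - window_nights + 1 .. end_night`.
#' @param window_nights baseline window length (default 14 nights).
#' @return list with `proportion`, `n_visitors`, `n_cohort`.
#' @export
baseline_proportion <- function(visits, cohort_ids, focal_tree_ids,
                                end_night, window_nights = 14) {
  cumulative_visit_proportion(
    visits, cohort_ids, focal_tree_ids,
    start_night = end_night - window_nights, window_nights = window_nights
  )
}

#' Run the manipulation-vs-routine visitation test
#'
#' For each window length 1-6 nights, computes the pooled naive visitation
#' proportion after the manipulation(s), a routine-movement null of the
#' same window length, its empirical 95% interval, and the one-tailed
#' resampling p-value. Smeared (manipulated) bats are excluded from the
#' observed cohort, and all manipulation-response windows are excluded from
#' the null.
#'
#' @param visits visit tibble covering both routine and manipulation
#'   periods.
#' @param manifest manifest tibble (`bat_id, role, night`).
#' @param roster roster tibble for the null cohorts (`bat_id, start_night,
#'   end_night`). Defaults to all non-manipulated bats spanning the visit
#'   table's nights.
#' @param focal_tree_ids focal tree ids.
#' @param windows window lengths to test.
#' @param min_cohort,n_iterations,seed,exclude_nights,candidate_starts
#'   passed to [sample_routine_null()]; manipulation windows are always
#'   excluded in addition to `exclude_nights`.
#' @return a tibble with one row per window: `window, observed, n_visitors,
#'   n_cohort, null_mean, null_lo, null_hi, p`.
#' @export
run_manipulation_test <- function(visits, manifest, roster = NULL,
                                  focal_tree_ids, windows = 1:6,
                                  min_cohort = 70, n_iterations = 215,
                                  seed = NULL,
                                  exclude_nights = integer(0),
                                  candidate_starts = NULL) {
  if (!is.null(seed)) set.seed(seed)
  manip_nights <- unique(manifest$night)
  blocked <- unique(c(
    exclude_nights,
    unlist(lapply(manip_nights, function(m) (m + 1):(m + max(windows))))
  ))
  if (is.null(roster)) {
    naive_only <- !(unique(visits$bat_id) %in%
                      manifest$bat_id[manifest$role == "manipulated"])
    roster <- tibble(
      bat_id = unique(visits$bat_id)[naive_only],
      start_night = min(visits$night_index),
      end_night = max(visits$night_index)
    )
  }
  rows <- lapply(windows, function(w) {
    obs <- pooled_visit_proportion(visits, manifest, focal_tree_ids,
                                   window_nights = w, role = "naive")
    null <- sample_routine_null(
      visits, roster, focal_tree_ids, window_nights = w,
      min_cohort = min_cohort, n_iterations = n_iterations,
      exclude_nights = blocked, candidate_starts = candidate_starts
    )
    tibble(
      window = w, observed = obs$proportion, n_visitors = obs$n_visitors,
      n_cohort = obs$n_cohort, null_mean = mean(null$proportions),
      null_lo = unname(quantile(null$proportions, 0.025)),
      null_hi = unname(quantile(null$proportions, 0.975)),
      p = permutation_pvalue(obs$proportion, null)
    )
  })
  do.call(rbind, rows)
}
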