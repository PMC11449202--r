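#' Roster of disjoint tracking-interval cohorts
#'
#' Builds a roster in which each of `n_intervals` consecutive, disjoint
#' windows of `window_nights` nights carries its own cohort of
#' `bats_per_interval` tagged bats. This mirrors how routine-movement null
#' cohorts are assembled: a bat tracked in two pooled intervals counts once
#' per interval, which distinct per-interval ids make explicit.
#'
#' @param n_intervals number of disjoint windows.
#' @param bats_per_interval cohort size per window.
#' @param window_nights window length in nights.
#' @return a roster tibble (`bat_id, roost, start_night, end_night`) with
#'   attribute `interval_starts`, the window start-nights (a visit window
#'   `(s, s + window_nights]` covers nights `s + 1 .. s + window_nights`).
#' @export
make_interval_roster <- function(n_intervals = 60, bats_per_interval = 72,
                                 window_nights = 6) {
  starts <- (seq_len(n_intervals) - 1L) * window_nights
  roster <- do.call(rbind, lapply(seq_len(n_intervals), function(k) {
    tibble(
      bat_id = sprintf("I%03d_B%03d", k, seq_len(bats_per_interval)),
      roost = "R1",
      start_night = starts[k] + 1L,
      end_night = starts[k] + window_nights
    )
  }))
  roster <- as_tibble(roster)
  attr(roster, "interval_starts") <- starts
  roster
}

#' Simulate routine focal-tree visitation at the visit level
#'
#' For every tracked bat-night in `roster`, draws a focal-tree visit as a
#' Bernoulli event with per-night probability chosen so that the
#' probability of at least one visit over `window_nights` nights equals
#' `rate_per_window`. This is the fast, visit-level counterpart of the full
#' trajectory generator, used for statistical calibration of the
#' routine-movement null at realistic colony sizes.
#'
#' @param roster tibble `bat_id, start_night, end_night`.
#' @param rate_per_window probability that a bat visits a focal tree at
#'   least once in a `window_nights`-night window (0.012 matches the
#'   reported routine six-night rate).
#' @param window_nights window length defining `rate_per_window`.
#' @param focal_tree_id tree id written into the visit rows.
#' @param seed optional integer seed.
#' @return a visit tibble (`bat_id, night_index, tree_id, duration, flyover`).
#' @export
simulate_routine_visits <- function(roster, rate_per_window = 0.012,
                                    window_nights = 6, focal_tree_id = 1L,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_night <- 1 - (1 - rate_per_window)^(1 / window_nights)
  nights_per_bat <- roster$end_night - roster$start_night + 1L
  rows <- lapply(seq_len(nrow(roster)), function(i) {
    nights <- roster$start_night[i]:roster$end_night[i]
    hit <- runif(length(nights)) < p_night
    if (!any(hit)) return(NULL)
    tibble(
      bat_id = roster$bat_id[i], night_index = nights[hit],
      tree_id = focal_tree_id, duration = 540, flyover = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble(
      bat_id = character(), night_index = integer(),
      tree_id = integer(), duration = numeric(), flyover = logical()
    ))
  }
  as_tibble(do.call(rbind, rows))
}

#' Simulate a manipulation cohort at the visit level
#'
#' Draws the post-manipulation focal-tree visits of a cohort of naive and
#' smeared bats over the six nights following a roost odour manipulation.
#' Each naive bat responds with probability `response_prob` (smeared bats
#' with `manipulated_response_prob`), visiting a focal tree once on a night
#' drawn from `lag_pmf`; on top of that every bat retains its routine
#' background visit rate.
#'
#' @param n_naive,n_manipulated cohort sizes (56 and 16 in the field
#'   manipulations).
#' @param response_prob,manipulated_response_prob response probabilities.
#' @param lag_pmf probability mass over response lags 1-6 nights.
#' @param routine_rate_per_window background visit rate per
#'   `window_nights`-night window.
#' @param window_nights response window length.
#' @param manipulation_night night index of the manipulation.
#' @param focal_tree_id tree id written into visit rows.
#' @param seed optional integer seed.
#' @return list with `visits` (visit tibble) and `manifest`
#'   (`bat_id, roost, role, night, responded, response_lag`).
#' @export
simulate_manipulation_cohort <- function(n_naive = 56, n_manipulated = 16,
                                         response_prob = 0.18,
                                         manipulated_response_prob = 0.25,
                                         lag_pmf = c(3, 2, 2, 2, 0, 1) / 10,
                                         routine_rate_per_window = 0.012,
                                         window_nights = 6,
                                         manipulation_night = 0L,
                                         focal_tree_id = 1L,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(response_prob >= 0, response_prob <= 1,
            abs(sum(lag_pmf) - 1) < 1e-8)
  manifest <- tibble(
    bat_id = c(sprintf("N%03d", seq_len(n_naive)),
               sprintf("M%03d", seq_len(n_manipulated))),
    roost = "R1",
    role = rep(c("naive", "manipulated"), c(n_naive, n_manipulated)),
    night = as.integer(manipulation_night)
  )
  p_resp <- ifelse(manifest$role == "naive", response_prob,
                   manipulated_response_prob)
  responded <- runif(nrow(manifest)) < p_resp
  lag <- rep(NA_integer_, nrow(manifest))
  lag[responded] <- sample(seq_along(lag_pmf), sum(responded),
                           replace = TRUE, prob = lag_pmf)
  manifest$responded <- responded
  manifest$response_lag <- lag

  p_night <- 1 - (1 - routine_rate_per_window)^(1 / window_nights)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    nights <- integer(0)
    if (responded[i]) nights <- manipulation_night + lag[i]
    bg <- manipulation_night + which(runif(window_nights) < p_night)
    nights <- sort(unique(c(nights, bg)))
    if (length(nights)) {
      rows[[length(rows) + 1L]] <- tibble(
        bat_id = manifest$bat_id[i], night_index = as.integer(nights),
        tree_id = focal_tree_id, duration = 540, flyover = FALSE
      )
    }
  }
  visits <- if (length(rows)) as_tibble(do.call(rbind, rows)) else tibble(
    bat_id = character(), night_index = integer(), tree_id = integer(),
    duration = numeric(), flyover = logical()
  )
  list(visits = visits, manifest = manifest)
}

#' Manipulation-campaign demo fixture
#'
#' A small deterministic fixture reproducing the bookkeeping of the three
#' 2020 field manipulation campaigns: 72 tagged bats (16 smeared, 56 naive)
#' across two cave-roosts and three release nights, with 10 naive and 4
#' smeared bats visiting a focal tree within six nights of their release.
#' Naive response lags follow the observed tally (three bats on night 1,
#' two each on nights 2, 3 and 4, one on night 6).
#'
#' @return list with `manifest` (`bat_id, roost, role, night`) and `visits`
#'   (visit tibble; focal tree ids 1 and 2).
#' @export
manipulation_demo <- function() {
  campaigns <- tibble(
    campaign = c("jun_G", "jun_Z", "dec_G", "dec_Z", "jul_G"),
    roost = c("Gershom", "Zemer", "Gershom", "Zemer", "Gershom"),
    night = c(0L, 0L, 168L, 168L, 27L),
    n_manipulated = c(3L, 4L, 4L, 1L, 4L),
    n_naive = c(9L, 6L, 15L, 7L, 19L),
    naive_visitors = c(4L, 2L, 2L, 1L, 1L),
    manip_visitors = c(2L, 1L, 1L, 0L, 0L)
  )
  manifest_rows <- list()
  visit_rows <- list()
  naive_lags <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 6L)
  manip_lags <- c(1L, 2L, 3L, 4L)
  n_used <- 0L
  m_used <- 0L
  for (i in seq_len(nrow(campaigns))) {
    cc <- campaigns[i, ]
    ids_m <- sprintf("%s_M%02d", cc$campaign, seq_len(cc$n_manipulated))
    ids_n <- sprintf("%s_N%02d", cc$campaign, seq_len(cc$n_naive))
    manifest_rows[[i]] <- tibble(
      bat_id = c(ids_m, ids_n), roost = cc$roost,
      role = rep(c("manipulated", "naive"), c(cc$n_manipulated, cc$n_naive)),
      night = cc$night
    )
    if (cc$naive_visitors > 0) {
      lags <- naive_lags[n_used + seq_len(cc$naive_visitors)]
      n_used <- n_used + cc$naive_visitors
      visit_rows[[length(visit_rows) + 1L]] <- tibble(
        bat_id = ids_n[seq_len(cc$naive_visitors)],
        night_index = cc$night + lags,
        tree_id = rep_len(c(1L, 2L), cc$naive_visitors),
        duration = 540, flyover = FALSE
      )
    }
    if (cc$manip_visitors > 0) {
      lags <- manip_lags[m_used + seq_len(cc$manip_visitors)]
      m_used <- m_used + cc$manip_visitors
      visit_rows[[length(visit_rows) + 1L]] <- tibble(
        bat_id = ids_m[seq_len(cc$manip_visitors)],
        night_index = cc$night + lags,
        tree_id = rep_len(c(2L, 1L), cc$manip_visitors),
        duration = 540, flyover = FALSE
      )
    }
  }
  list(
    manifest = as_tibble(do.call(rbind, manifest_rows)),
    visits = as_tibble(do.call(rbind, visit_rows))
  )
}
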