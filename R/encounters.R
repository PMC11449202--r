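#' Detect dyadic tree encounters
#'
#' Two bats encounter each other when their non-flyover visits to the same
#' tree overlap in time with positive length (touching endpoints do not
#' count). One encounter is emitted per overlapping visit-interval pair of
#' a dyad on a tree; bat order is normalised so `bat_a < bat_b`.
#'
#' @param visits annotated visit tibble (`bat_id, night_index, tree_id,
#'   t_start, t_end`, optional `flyover`).
#' @return tibble `bat_a, bat_b, tree_id, night_index, overlap_start,
#'   overlap_end`.
#' @export
detect_encounters <- function(visits) {
  empty <- tibble(
    bat_a = character(), bat_b = character(), tree_id = integer(),
    night_index = integer(), overlap_start = numeric(),
    overlap_end = numeric()
  )
  if (nrow(visits) == 0) return(empty)
  fo <- if ("flyover" %in% names(visits)) visits$flyover else
    rep(FALSE, nrow(visits))
  v <- visits[!fo & !is.na(visits$tree_id), , drop = FALSE]
  if (nrow(v) < 2) return(empty)
  rows <- list()
  for (grp in split(v, v$tree_id)) {
    n <- nrow(grp)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (grp$bat_id[i] == grp$bat_id[j]) next
        os <- max(grp$t_start[i], grp$t_start[j])
        oe <- min(grp$t_end[i], grp$t_end[j])
        if (oe <= os) next
        ab <- sort(c(grp$bat_id[i], grp$bat_id[j]))
        rows[[length(rows) + 1L]] <- tibble(
          bat_a = ab[1], bat_b = ab[2], tree_id = grp$tree_id[i],
          night_index = grp$night_index[i], overlap_start = os,
          overlap_end = oe
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- as_tibble(do.call(rbind, rows))
  out[order(out$bat_a, out$bat_b, out$overlap_start), ]
}

#' Dyadic tree-sharing rate
#'
#' Fraction of co-tracked dyads observed sharing a tree (at least one
#' encounter) within a `window_nights`-night window. A dyad enters the
#' denominator when the two tracking periods overlap by at least one night;
#' the window is the first `window_nights` nights of the co-tracked period.
#' When the roster carries a `roost` column, same- and different-roost
#' rates are reported as well.
#'
#' @param visits annotated visit tibble.
#' @param roster roster tibble (`bat_id, start_night, end_night`, optional
#'   `roost`).
#' @param window_nights window length (default 6).
#' @return list with `overall`, `n_dyads`, `n_sharing`, and (with roosts)
#'   `same_roost`, `diff_roost`.
#' @export
dyad_sharing_rate <- function(visits, roster, window_nights = 6) {
  enc <- detect_encounters(visits)
  n <- nrow(roster)
  if (n < 2) stop("undefined sharing rate: fewer than two tracked bats",
                  call. = FALSE)
  pairs <- utils::combn(n, 2)
  shared <- logical(ncol(pairs))
  cotracked <- logical(ncol(pairs))
  same_roost <- rep(NA, ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    co_start <- max(roster$start_night[i], roster$start_night[j])
    co_end <- min(roster$end_night[i], roster$end_night[j])
    if (co_end < co_start) next
    cotracked[k] <- TRUE
    win_end <- co_start + window_nights - 1
    ab <- sort(c(roster$bat_id[i], roster$bat_id[j]))
    hit <- enc$bat_a == ab[1] & enc$bat_b == ab[2] &
      enc$night_index >= co_start & enc$night_index <= min(co_end, win_end)
    shared[k] <- any(hit)
    if ("roost" %in% names(roster)) {
      same_roost[k] <- roster$roost[i] == roster$roost[j]
    }
  }
  if (!any(cotracked)) {
    stop("undefined sharing rate: no co-tracked dyads", call. = FALSE)
  }
  out <- list(
    overall = mean(shared[cotracked]),
    n_dyads = sum(cotracked),
    n_sharing = sum(shared[cotracked])
  )
  if ("roost" %in% names(roster)) {
    same <- cotracked & same_roost
    diff <- cotracked & !same_roost
    out$same_roost <- if (any(same)) mean(shared[same]) else NA_real_
    out$diff_roost <- if (any(diff)) mean(shared[diff]) else NA_real_
  }
  out
}

#' Collapse encounters into one meeting per dyad-night
#'
#' @param encounters output of [detect_encounters()].
#' @return tibble `bat_a, bat_b, night, met` (met = TRUE).
#' @export
meetings_from_encounters <- function(encounters) {
  if (nrow(encounters) == 0) {
    return(tibble(bat_a = character(), bat_b = character(),
                  night = integer(), met = logical()))
  }
  key <- !duplicated(encounters[, c("bat_a", "bat_b", "night_index")])
  tibble(
    bat_a = encounters$bat_a[key], bat_b = encounters$bat_b[key],
    night = encounters$night_index[key], met = TRUE
  )
}

#' Sample never-met control dyads matched by calendar month
#'
#' Draws, without replacement, one control dyad per met dyad from the pool
#' of co-tracked dyads with zero encounters, matched on the calendar month
#' of the meeting. Each control dyad receives a pseudo-meeting night
#' sampled uniformly from its co-tracked nights within the matched month.
#'
#' @param roster roster tibble (`bat_id, start_night, end_night`).
#' @param meetings met-dyad tibble from [meetings_from_encounters()]; only
#'   the first meeting of a dyad is matched.
#' @param seed optional integer seed.
#' @param origin calendar date of night 0, for month matching.
#' @return tibble `bat_a, bat_b, night, met` (met = FALSE).
#' @export
sample_control_dyads <- function(roster, meetings, seed = NULL,
                                 origin = as.Date("2020-01-01")) {
  if (!is.null(seed)) set.seed(seed)
  first <- meetings[!duplicated(meetings[, c("bat_a", "bat_b")]), ,
                    drop = FALSE]
  met_key <- paste(first$bat_a, first$bat_b)
  n <- nrow(roster)
  pairs <- utils::combn(n, 2)
  cand <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    co_start <- max(roster$start_night[i], roster$start_night[j])
    co_end <- min(roster$end_night[i], roster$end_night[j])
    if (co_end < co_start) next
    ab <- sort(c(roster$bat_id[i], roster$bat_id[j]))
    if (paste(ab[1], ab[2]) %in% met_key) next
    cand[[length(cand) + 1L]] <- tibble(
      bat_a = ab[1], bat_b = ab[2],
      co_start = co_start, co_end = co_end
    )
  }
  if (length(cand) == 0 && nrow(first) > 0) {
    stop("insufficient control dyads: no never-met co-tracked dyads",
         call. = FALSE)
  }
  cand <- if (length(cand)) as_tibble(do.call(rbind, cand)) else
    tibble(bat_a = character(), bat_b = character(),
           co_start = integer(), co_end = integer())
  taken <- logical(nrow(cand))
  out <- list()
  months_needed <- night_month(first$night, origin)
  shortfall <- character(0)
  for (m in seq_len(nrow(first))) {
    month_m <- months_needed[m]
    ok <- which(!taken & vapply(seq_len(nrow(cand)), function(k) {
      nights <- cand$co_start[k]:cand$co_end[k]
      any(night_month(nights, origin) == month_m)
    }, logical(1)))
    if (length(ok) == 0) {
      shortfall <- c(shortfall, month_m)
      next
    }
    pick <- if (length(ok) == 1) ok else sample(ok, 1)
    taken[pick] <- TRUE
    nights <- cand$co_start[pick]:cand$co_end[pick]
    nights <- nights[night_month(nights, origin) == month_m]
    out[[length(out) + 1L]] <- tibble(
      bat_a = cand$bat_a[pick], bat_b = cand$bat_b[pick],
      night = sample_one(nights), met = FALSE
    )
  }
  if (length(shortfall) > 0) {
    tab <- table(shortfall)
    stop("insufficient control dyads in month(s): ",
         paste(names(tab), tab, sep = " x ", collapse = ", "),
         call. = FALSE)
  }
  if (length(out) == 0) {
    return(tibble(bat_a = character(), bat_b = character(),
                  night = integer(), met = logical()))
  }
  as_tibble(do.call(rbind, out))
}

#' Calendar month of a night index
#'
#' @param night integer night index (0-based).
#' @param origin calendar date of night 0.
#' @return character `"YYYY-MM"`.
#' @export
night_month <- function(night, origin = as.Date("2020-01-01")) {
  format(origin + night, "%Y-%m")
}

#' Build dyadic new-tree discovery records
#'
#' For every meeting (met or control pseudo-meeting) on night `m`, both
#' members in turn act as the focal bat. The partner's trees are the unique
#' trees it visited in the `pre_window` nights before the meeting (nights
#' `m - pre_window .. m - 1`). For a lag of `L` nights the focal bat's
#' candidate new trees are those it visited during the `post_window` nights
#' anchored at `m + L - 1` (nights `m + L .. m + L - 1 + post_window`),
#' excluding every tree the focal had already visited up to and including
#' the meeting night. The binary response is whether any candidate new tree
#' belongs to the partner's pre-meeting set. With `ficus_only`, partner
#' trees are restricted to temporally unpredictable species (requires
#' `trees`).
#'
#' @param visits annotated visit tibble.
#' @param meetings tibble `bat_a, bat_b, night, met` (met dyads and
#'   controls together).
#' @param lags integer lags in nights (default 1-6).
#' @param pre_window,post_window window lengths in nights (default 3).
#' @param ficus_only restrict partner trees to unpredictable species.
#' @param trees tree table with `predictability`; required for
#'   `ficus_only`.
#' @return tibble `focal_id, partner_id, met, lag_nights, response, night`.
#' @export
build_discovery_records <- function(visits, meetings, lags = 1:6,
                                    pre_window = 3, post_window = 3,
                                    ficus_only = FALSE, trees = NULL) {
  if (ficus_only && is.null(trees)) {
    stop("ficus_only requires a tree table with predictability",
         call. = FALSE)
  }
  fo <- if ("flyover" %in% names(visits)) visits$flyover else
    rep(FALSE, nrow(visits))
  v <- visits[!fo & !is.na(visits$tree_id), c("bat_id", "night_index",
                                              "tree_id")]
  unpred <- if (ficus_only) {
    trees$tree_id[trees$predictability == "unpredictable"]
  } else {
    NULL
  }
  trees_of <- function(bat, from, to) {
    unique(v$tree_id[v$bat_id == bat & v$night_index >= from &
                       v$night_index <= to])
  }
  rows <- list()
  for (r in seq_len(nrow(meetings))) {
    m <- meetings$night[r]
    for (orient in 1:2) {
      focal <- if (orient == 1) meetings$bat_a[r] else meetings$bat_b[r]
      partner <- if (orient == 1) meetings$bat_b[r] else meetings$bat_a[r]
      partner_trees <- trees_of(partner, m - pre_window, m - 1)
      if (ficus_only) partner_trees <- intersect(partner_trees, unpred)
      history <- trees_of(focal, -Inf, m)
      for (L in lags) {
        anchor <- m + L - 1
        new_trees <- setdiff(
          trees_of(focal, anchor + 1, anchor + post_window), history
        )
        rows[[length(rows) + 1L]] <- tibble(
          focal_id = focal, partner_id = partner,
          met = meetings$met[r], lag_nights = as.integer(L),
          response = length(intersect(new_trees, partner_trees)) > 0,
          night = as.integer(m)
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(
      focal_id = character(), partner_id = character(), met = logical(),
      lag_nights = integer(), response = logical(), night = integer()
    ))
  }
  as_tibble(do.call(rbind, rows))
}

#' Per-lag logistic models of new-tree discovery
#'
#' Fits, for each lag, a logistic regression of the binary discovery
#' response on whether the dyad met (maximum likelihood via IRLS). The
#' fitted group probabilities of this saturated two-group model equal the
#' raw response frequencies. Complete separation and single-class responses
#' are flagged instead of reporting unstable coefficients. P-values are
#' reported raw, one model per lag, without multiplicity correction.
#'
#' @param records discovery records from [build_discovery_records()].
#' @return tibble `lag, n_met, n_control, coef, se, z, p, p_met,
#'   p_control, degenerate`.
#' @export
fit_lag_models <- function(records) {
  rows <- lapply(sort(unique(records$lag_nights)), function(L) {
    d <- records[records$lag_nights == L, , drop = FALSE]
    n_met <- sum(d$met)
    n_ctl <- sum(!d$met)
    base <- tibble(
      lag = L, n_met = n_met, n_control = n_ctl,
      coef = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
      p_met = if (n_met) mean(d$response[d$met]) else NA_real_,
      p_control = if (n_ctl) mean(d$response[!d$met]) else NA_real_,
      degenerate = TRUE
    )
    if (n_met == 0 || n_ctl == 0) return(base)
    if (length(unique(d$response)) < 2) return(base)
    # a group with all-0 or all-1 responses is completely separated on the
    # binary predictor: flag rather than report a diverging coefficient
    if (base$p_met %in% c(0, 1) || base$p_control %in% c(0, 1)) return(base)
    d$response <- as.numeric(d$response)
    fit <- glm(response ~ met, family = binomial(), data = d)
    sm <- summary(fit)$coefficients
    base$coef <- sm["metTRUE", "Estimate"]
    base$se <- sm["metTRUE", "Std. Error"]
    base$z <- sm["metTRUE", "z value"]
    base$p <- sm["metTRUE", "Pr(>|z|)"]
    base$degenerate <- FALSE
    base
  })
  do.call(rbind, rows)
}
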