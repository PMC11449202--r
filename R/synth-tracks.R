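#' Simulate nightly bat trajectories with a ground-truth visit log
#'
#' Generates, for every bat and night, a central-place foraging trip:
#' departure from the cave-roost, straight constant-speed commutes between
#' 1-5 tree stops, a log-normal dwell at each stop, and a return to the
#' roost. Fixes are emitted on a regular sampling grid over the whole trip
#' with isotropic Gaussian localization noise and a matching per-fix
#' covariance. Tree choice is memory-driven: each bat owns a small
#' repertoire of remembered trees and draws each stop from it with
#' probability `revisit_prob`, otherwise from the landscape at large.
#'
#' The returned truth log records every dwell episode (bat, night, tree,
#' start, end) and is the oracle against which segmentation is tested.
#'
#' @param trees a tree table from [generate_landscape()].
#' @param config a [sim_config()]. When `config$seed` is non-NULL the
#'   simulation is bit-reproducible.
#' @return a list with elements
#'   \describe{
#'     \item{fixes}{tibble `tag_id, t, x, y, var_x, var_y, cov_xy`, sorted
#'       by tag and time.}
#'     \item{truth}{tibble `bat_id, night_index, tree_id, t_start, t_end`.}
#'     \item{itinerary}{tibble `bat_id, night_index, n_stops` -- the
#'       generator's own per-night stop counter.}
#'     \item{roster}{tibble `bat_id, roost, start_night, end_night`.}
#'   }
#' @export
simulate_tracks <- function(trees, config = sim_config()) {
  force(trees)  # evaluate before seeding: the promise may consume the RNG
  stopifnot(all(c("tree_id", "x", "y") %in% names(trees)))
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  roosts <- roost_table(config)
  n_bats <- config$n_bats

  empty <- list(
    fixes = empty_fix_table(),
    truth = empty_truth_table(),
    itinerary = tibble(bat_id = character(), night_index = integer(),
                       n_stops = integer()),
    roster = tibble(bat_id = character(), roost = character(),
                    start_night = integer(), end_night = integer())
  )
  if (n_bats == 0 || config$n_nights == 0) return(empty)

  bat_ids <- sprintf("B%03d", seq_len(n_bats))
  bat_roost <- roosts[((seq_len(n_bats) - 1) %% nrow(roosts)) + 1, ]

  fix_chunks <- list()
  truth_chunks <- list()
  itin_chunks <- list()

  for (b in seq_len(n_bats)) {
    roost_pos <- c(bat_roost$x[b], bat_roost$y[b])
    repertoire <- draw_repertoire(trees, roost_pos, config)
    for (night in seq_len(config$n_nights) - 1L) {
      stops <- draw_itinerary(trees, repertoire, roost_pos, config)
      itin_chunks[[length(itin_chunks) + 1L]] <- tibble(
        bat_id = bat_ids[b], night_index = night,
        n_stops = length(stops)
      )
      if (length(stops) == 0) next
      start_t <- config$origin + night * 86400 + config$night_start
      dwells <- draw_dwells(length(stops), config)
      trip <- build_trip(start_t, roost_pos, trees[stops, ], dwells,
                         config$commute_speed)
      fix_chunks[[length(fix_chunks) + 1L]] <- emit_fixes(
        bat_ids[b], trip$waypoints, config
      )
      truth_chunks[[length(truth_chunks) + 1L]] <- tibble(
        bat_id = bat_ids[b], night_index = night,
        tree_id = trees$tree_id[stops],
        t_start = trip$t_start, t_end = trip$t_end
      )
    }
  }

  fixes <- if (length(fix_chunks)) do.call(rbind, fix_chunks) else empty$fixes
  fixes <- fixes[order(fixes$tag_id, fixes$t), ]
  truth <- if (length(truth_chunks)) do.call(rbind, truth_chunks) else empty$truth
  list(
    fixes = as_tibble(fixes),
    truth = as_tibble(truth),
    itinerary = as_tibble(do.call(rbind, itin_chunks)),
    roster = tibble(
      bat_id = bat_ids, roost = bat_roost$roost,
      start_night = 0L, end_night = as.integer(config$n_nights - 1L)
    )
  )
}

empty_fix_table <- function() {
  tibble(
    tag_id = character(), t = numeric(), x = numeric(), y = numeric(),
    var_x = numeric(), var_y = numeric(), cov_xy = numeric()
  )
}

empty_truth_table <- function() {
  tibble(
    bat_id = character(), night_index = integer(), tree_id = integer(),
    t_start = numeric(), t_end = numeric()
  )
}

# repertoire trees are mutually separated and away from the roost, so that
# distinct remembered canopies are spatially distinct
draw_repertoire <- function(trees, roost_pos, config) {
  size <- sample_one(config$repertoire_size)
  chosen <- integer(0)
  for (attempt in seq_len(200)) {
    if (length(chosen) >= size) break
    cand <- sample.int(nrow(trees), 1)
    if (tree_gap_ok(trees, cand, chosen, roost_pos, config$min_tree_gap)) {
      chosen <- c(chosen, cand)
    }
  }
  chosen
}

tree_gap_ok <- function(trees, cand, others, roost_pos, gap) {
  dx <- trees$x[cand] - roost_pos[1]
  dy <- trees$y[cand] - roost_pos[2]
  if (dx * dx + dy * dy < gap * gap) return(FALSE)
  if (cand %in% others) return(FALSE)
  if (length(others) == 0) return(TRUE)
  d2 <- (trees$x[others] - trees$x[cand])^2 + (trees$y[others] - trees$y[cand])^2
  all(d2 >= gap * gap)
}

# one night's stop sequence: memory draw with prob revisit_prob, otherwise
# exploration; stops distinct within the night and separated by min_tree_gap
draw_itinerary <- function(trees, repertoire, roost_pos, config) {
  k <- sample_one(config$trees_per_night)
  stops <- integer(0)
  for (slot in seq_len(k)) {
    placed <- FALSE
    for (attempt in seq_len(50)) {
      from_memory <- length(repertoire) > 0 && runif(1) < config$revisit_prob
      cand <- if (from_memory) sample_one(repertoire) else
        sample.int(nrow(trees), 1)
      prev <- if (length(stops)) stops[length(stops)] else integer(0)
      # consecutive-stop spacing: test against previous stop and the roost
      if (cand %in% stops) next
      if (!tree_gap_ok(trees, cand, prev, roost_pos, config$min_tree_gap)) next
      stops <- c(stops, cand)
      placed <- TRUE
      break
    }
    if (!placed) break
  }
  stops
}

sample_one <- function(x) if (length(x) == 1) x else sample(x, 1)

draw_dwells <- function(n, config) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (attempt in seq_len(100)) {
      d <- rlnorm(1, meanlog = log(config$dwell_median),
                  sdlog = config$dwell_sdlog)
      if (d >= config$dwell_min && d <= config$dwell_max) break
    }
    out[i] <- min(max(d, config$dwell_min), config$dwell_max)
  }
  out
}

# piecewise-linear trip: roost -> stops (with dwells) -> roost
build_trip <- function(start_t, roost_pos, stop_trees, dwells, speed) {
  n <- nrow(stop_trees)
  wp_t <- start_t
  wp_x <- roost_pos[1]
  wp_y <- roost_pos[2]
  cur <- roost_pos
  t <- start_t
  t_start <- numeric(n)
  t_end <- numeric(n)
  for (i in seq_len(n)) {
    pos <- c(stop_trees$x[i], stop_trees$y[i])
    t_arr <- t + sqrt(sum((pos - cur)^2)) / speed
    t_dep <- t_arr + dwells[i]
    wp_t <- c(wp_t, t_arr, t_dep)
    wp_x <- c(wp_x, pos[1], pos[1])
    wp_y <- c(wp_y, pos[2], pos[2])
    t_start[i] <- t_arr
    t_end[i] <- t_dep
    cur <- pos
    t <- t_dep
  }
  t_home <- t + sqrt(sum((roost_pos - cur)^2)) / speed
  wp_t <- c(wp_t, t_home)
  wp_x <- c(wp_x, roost_pos[1])
  wp_y <- c(wp_y, roost_pos[2])
  list(
    waypoints = list(t = wp_t, x = wp_x, y = wp_y),
    t_start = t_start, t_end = t_end
  )
}

emit_fixes <- function(tag_id, wp, config) {
  # sampling grid re-anchors at each behavioural segment (commute leg or
  # dwell), so arrivals and departures are themselves sampled
  n_wp <- length(wp$t)
  times <- unique(unlist(lapply(seq_len(n_wp - 1), function(i) {
    seq(wp$t[i], wp$t[i + 1], by = config$sampling_interval)
  })))
  times <- sort(unique(c(times, wp$t[n_wp])))
  x <- approx(wp$t, wp$x, xout = times, ties = "ordered")$y
  y <- approx(wp$t, wp$y, xout = times, ties = "ordered")$y
  n <- length(times)
  if (config$noise_sd > 0) {
    x <- x + rnorm(n, 0, config$noise_sd)
    y <- y + rnorm(n, 0, config$noise_sd)
  }
  tibble(
    tag_id = tag_id, t = times, x = x, y = y,
    var_x = config$noise_sd^2, var_y = config$noise_sd^2, cov_xy = 0
  )
}

#' Inject a roost odour-manipulation into a simulated colony
#'
#' Designates `config$n_manipulated` bats as smeared (odour-carrying) and
#' the remainder as naive, then lets each bat independently respond to the
#' manipulation: a responder makes exactly one extra excursion to a focal
#' tree, on a night drawn from `config$lag_pmf` (1-6 nights after the
#' manipulation). Naive bats respond with probability
#' `config$response_prob`, smeared bats with
#' `config$manipulated_response_prob`. The excursion's fixes and truth
#' episode are appended to the simulation.
#'
#' @param sim output of [simulate_tracks()].
#' @param trees the tree table used for the simulation (must contain at
#'   least one focal tree).
#' @param config the [sim_config()] used for the simulation.
#' @param manipulation_night night index of the manipulation (the release
#'   happens at the end of that night; responses start the following night).
#' @return `sim` with updated `fixes` and `truth`, plus a `manifest` tibble
#'   (`bat_id, roost, role, night, responded, response_lag`).
#' @export
inject_manipulation <- function(sim, trees, config, manipulation_night) {
  validate_sim_config(config)
  if (manipulation_night < 0 || manipulation_night >= config$n_nights) {
    stop("manipulation_night outside the simulated range", call. = FALSE)
  }
  focal <- trees[trees$is_focal, , drop = FALSE]
  if (nrow(focal) == 0) stop("no focal trees in the landscape", call. = FALSE)
  roster <- sim$roster
  n_manip <- min(config$n_manipulated, nrow(roster))
  manip_ids <- sample(roster$bat_id, n_manip)
  role <- ifelse(roster$bat_id %in% manip_ids, "manipulated", "naive")
  p_resp <- ifelse(role == "manipulated",
                   config$manipulated_response_prob, config$response_prob)
  responded <- runif(nrow(roster)) < p_resp
  lag <- ifelse(responded, sample(1:6, nrow(roster), replace = TRUE,
                                  prob = config$lag_pmf), NA_integer_)

  roost_xy <- roost_table(config)
  fix_chunks <- list(sim$fixes)
  truth_chunks <- list(sim$truth)
  for (i in which(responded)) {
    night <- manipulation_night + lag[i]
    tree_row <- focal[sample.int(nrow(focal), 1), ]
    rp <- roost_xy[match(roster$roost[i], roost_xy$roost), ]
    # pre-trip excursion slot, three hours before the regular departure
    start_t <- config$origin + night * 86400 + config$night_start - 3 * 3600
    dwell <- draw_dwells(1, config)
    trip <- build_trip(start_t, c(rp$x, rp$y), tree_row, dwell,
                       config$commute_speed)
    fix_chunks[[length(fix_chunks) + 1L]] <-
      emit_fixes(roster$bat_id[i], trip$waypoints, config)
    truth_chunks[[length(truth_chunks) + 1L]] <- tibble(
      bat_id = roster$bat_id[i], night_index = as.integer(night),
      tree_id = tree_row$tree_id, t_start = trip$t_start, t_end = trip$t_end
    )
  }
  fixes <- do.call(rbind, fix_chunks)
  fixes <- fixes[order(fixes$tag_id, fixes$t), ]
  truth <- do.call(rbind, truth_chunks)
  truth <- truth[order(truth$bat_id, truth$t_start), ]

  sim$fixes <- as_tibble(fixes)
  sim$truth <- as_tibble(truth)
  sim$manifest <- tibble(
    bat_id = roster$bat_id, roost = roster$roost, role = role,
    night = as.integer(manipulation_night),
    responded = responded, response_lag = as.integer(lag)
  )
  sim
}
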