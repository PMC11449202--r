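#' Segment a filtered track into tree visits
#'
#' First-passage segmentation: scanning forward through a bat's fixes, a
#' candidate dwell "cloud" opens when `min_fixes` consecutive fixes all lie
#' within `fp_radius` of their own mean. The cloud centre is then refined
#' iteratively -- recompute the mean of the member fixes, re-extend the
#' membership run from the opening fix against the new centre -- until the
#' membership stabilises; the visit closes at the last consecutive fix
#' within `fp_radius` of the converged centre. Finally the cloud boundary
#' is trimmed: leading and trailing member fixes farther than
#' `boundary_trim_k` times the median per-axis localization sd from the
#' centre belong to the approach/departure flight, not the dwell, and are
#' removed. Clouds with at least `min_fixes` fixes and duration at least
#' `min_duration` are emitted as visits; all other fixes are commuting.
#' Segmentation runs within bat-nights (noon-to-noon, see
#' [assign_nights()]), so a dwell never chains across days through the
#' roost.
#'
#' Visits are annotated with the nearest mapped tree (see
#' [annotate_visits()]) when `trees` is supplied, flagged as flyovers via
#' [classify_flyover()], and given a night index via [assign_nights()].
#'
#' @param fixes filtered fix tibble (one or more tags), sorted by
#'   (tag_id, t).
#' @param trees optional tree table for visit attribution.
#' @param params a [segmenter_params()].
#' @param night_origin epoch seconds of the local midnight starting the
#'   study; defaults to midnight of the first fix's day.
#' @return a visit tibble: `bat_id, night_index, tree_id, centroid_x,
#'   centroid_y, t_start, t_end, duration, n_fixes, flyover`.
#' @export
segment_visits <- function(fixes, trees = NULL, params = segmenter_params(),
                           night_origin = NULL) {
  if (nrow(fixes) == 0) return(empty_visit_table())
  check_sorted(fixes)
  if (is.null(night_origin)) {
    night_origin <- floor(min(fixes$t) / 86400) * 86400
  }
  # segment within bat-nights: foraging trips are nocturnal and a dwell
  # cannot straddle the noon boundary, so clouds never chain across days
  night <- assign_nights(fixes$t, origin = night_origin)
  chunks <- lapply(split(fixes, list(fixes$tag_id, night), drop = TRUE),
                   seg_track, params = params)
  visits <- do.call(rbind, chunks[vapply(chunks, nrow, 0L) > 0])
  if (is.null(visits) || nrow(visits) == 0) return(empty_visit_table())
  visits <- as_tibble(visits)
  visits$night_index <- assign_nights(visits$t_start, origin = night_origin)
  visits <- visits[order(visits$bat_id, visits$t_start), ]
  visits$tree_id <- NA_integer_
  if (!is.null(trees)) visits <- annotate_visits(visits, trees, params)
  visits[, c("bat_id", "night_index", "tree_id", "centroid_x", "centroid_y",
             "t_start", "t_end", "duration", "n_fixes", "flyover")]
}

empty_visit_table <- function() {
  tibble(
    bat_id = character(), night_index = integer(), tree_id = integer(),
    centroid_x = numeric(), centroid_y = numeric(), t_start = numeric(),
    t_end = numeric(), duration = numeric(), n_fixes = integer(),
    flyover = logical()
  )
}

seg_track <- function(track, params) {
  t <- track$t
  x <- track$x
  y <- track$y
  n <- length(t)
  m <- params$min_fixes
  r2 <- params$fp_radius^2
  sd_axis <- sqrt(stats::median((track$var_x + track$var_y) / 2))
  r_trim <- max(params$boundary_trim_k * sd_axis, 1)
  rows <- list()
  i <- 1L
  while (i + m - 1L <= n) {
    idx <- i:(i + m - 1L)
    cx <- mean(x[idx]); cy <- mean(y[idx])
    if (max((x[idx] - cx)^2 + (y[idx] - cy)^2) > r2) {
      i <- i + 1L
      next
    }
    j <- i + m - 1L
    for (iter in seq_len(100)) {
      cx <- mean(x[i:j]); cy <- mean(y[i:j])
      run_end <- i
      while (run_end < n &&
             (x[run_end + 1L] - cx)^2 + (y[run_end + 1L] - cy)^2 <= r2) {
        run_end <- run_end + 1L
      }
      if (run_end == j) break
      j <- run_end
      if (j < i + m - 1L) break
    }
    if (j < i + m - 1L) {
      i <- i + 1L
      next
    }
    # boundary trim against the converged centre
    a <- i; b <- j
    while (a < b && (x[a] - cx)^2 + (y[a] - cy)^2 > r_trim^2) a <- a + 1L
    while (b > a && (x[b] - cx)^2 + (y[b] - cy)^2 > r_trim^2) b <- b - 1L
    dur <- t[b] - t[a]
    if (b - a + 1L >= m && dur >= params$min_duration) {
      fo <- classify_flyover(track[a:b, ], params)
      rows[[length(rows) + 1L]] <- tibble(
        bat_id = track$tag_id[1], centroid_x = mean(x[a:b]),
        centroid_y = mean(y[a:b]), t_start = t[a], t_end = t[b],
        duration = dur, n_fixes = b - a + 1L, flyover = fo
      )
    }
    i <- j + 1L
  }
  if (length(rows) == 0) {
    tibble(
      bat_id = character(), centroid_x = numeric(), centroid_y = numeric(),
      t_start = numeric(), t_end = numeric(), duration = numeric(),
      n_fixes = integer(), flyover = logical()
    )
  } else {
    do.call(rbind, rows)
  }
}

#' Classify a dwell episode as a flyover
#'
#' A visit is only counted when the bat circled around the tree; a straight
#' pass over it is a flyover. Straightness is net displacement divided by
#' cumulative path length (1 for perfectly straight movement, near 0 for a
#' closed loop; 0 by convention for a zero-length path). An episode is a
#' flyover when straightness exceeds `straightness_max` and its duration is
#' below `min_duration`.
#'
#' @param visit_fixes fixes of one candidate episode (`t, x, y`), at least
#'   two rows.
#' @param params a [segmenter_params()].
#' @return logical scalar.
#' @export
classify_flyover <- function(visit_fixes, params = segmenter_params()) {
  stopifnot(nrow(visit_fixes) >= 2)
  dx <- diff(visit_fixes$x)
  dy <- diff(visit_fixes$y)
  path <- sum(sqrt(dx^2 + dy^2))
  net <- sqrt(
    (visit_fixes$x[nrow(visit_fixes)] - visit_fixes$x[1])^2 +
      (visit_fixes$y[nrow(visit_fixes)] - visit_fixes$y[1])^2
  )
  straightness <- if (path > 0) net / path else 0
  duration <- visit_fixes$t[nrow(visit_fixes)] - visit_fixes$t[1]
  straightness > params$straightness_max && duration < params$min_duration
}

#' Attribute visits to mapped trees
#'
#' Sets `tree_id` to the nearest tree within `match_radius` of the visit
#' centroid, or `NA` when no tree is close enough. Exact distance ties are
#' broken toward the smallest `tree_id`.
#'
#' @param visits a visit tibble with `centroid_x`, `centroid_y`.
#' @param trees a tree table (`tree_id, x, y`, ...).
#' @param params a [segmenter_params()].
#' @return `visits` with `tree_id` filled in.
#' @export
annotate_visits <- function(visits, trees, params = segmenter_params()) {
  if (nrow(visits) == 0) return(visits)
  if (is.null(trees) || nrow(trees) == 0) {
    warning("empty tree table: all visits left unmatched")
    visits$tree_id <- NA_integer_
    return(visits)
  }
  trees <- trees[order(trees$tree_id), , drop = FALSE]
  visits$tree_id <- vapply(seq_len(nrow(visits)), function(i) {
    d2 <- (trees$x - visits$centroid_x[i])^2 +
      (trees$y - visits$centroid_y[i])^2
    k <- which.min(d2)  # first index wins ties = smallest tree_id
    if (sqrt(d2[k]) <= params$match_radius) {
      as.integer(trees$tree_id[k])
    } else {
      NA_integer_
    }
  }, integer(1))
  visits
}

#' Assign night indices to timestamps
#'
#' Nights run noon-to-noon so that one whole foraging night (sunset to
#' sunrise) shares an index: `night_index = floor((t - origin - boundary) /
#' 86400)`, counting boundary crossings since the study origin.
#'
#' @param t epoch seconds (numeric vector).
#' @param origin epoch seconds of the local midnight opening the study;
#'   defaults to midnight of the first timestamp's day.
#' @param boundary seconds after midnight of the night boundary
#'   (default 12:00).
#' @return integer vector of night indices.
#' @export
assign_nights <- function(t, origin = NULL, boundary = 12 * 3600) {
  if (length(t) == 0) return(integer(0))
  if (is.null(origin)) origin <- floor(min(t) / 86400) * 86400
  as.integer(floor((t - origin - boundary) / 86400))
}
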