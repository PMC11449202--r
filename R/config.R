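#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the synthetic
#' landscape and trajectory generators. Defaults describe a Hula-valley-like
#' study system: a few dozen tagged bats commuting nightly from a cave-roost
#' at the landscape edge to a handful of remembered fruit trees, tracked by a
#' reverse-GPS system at 0.25 Hz with ~5 m localization error.
#'
#' @param n_bats number of tagged bats.
#' @param n_nights number of simulated nights.
#' @param n_trees number of fruit trees in the landscape.
#' @param n_focal number of focal (manipulation-target) trees; these are
#'   always temporally unpredictable.
#' @param frac_unpredictable expected fraction of trees belonging to
#'   temporally unpredictable (Ficus-like) species.
#' @param extent side length of the square landscape, metres.
#' @param roost_xy roost coordinates, metres; default on the western edge.
#' @param n_roosts number of cave-roosts. With more than one, bats are
#'   assigned round-robin to roosts spaced along the western edge. Only the
#'   manifest bookkeeping changes; the statistics pool roosts.
#' @param sampling_interval tag transmission interval, seconds (4 s = 0.25 Hz,
#'   within the tracking system's 0.125-0.5 Hz band).
#' @param noise_sd isotropic localization error standard deviation, metres.
#' @param commute_speed straight-line commuting flight speed, m/s.
#' @param trees_per_night integer vector of candidate per-night tree counts
#'   (sampled uniformly).
#' @param repertoire_size integer vector of candidate per-bat repertoire
#'   sizes (remembered trees; sampled uniformly).
#' @param revisit_prob probability that a night's tree is drawn from the
#'   bat's personal repertoire rather than at random (spatial memory).
#' @param dwell_median,dwell_sdlog log-normal dwell-duration parameters
#'   (median in seconds; sdlog on the log scale).
#' @param dwell_min,dwell_max truncation bounds for dwell durations, seconds.
#' @param min_tree_gap minimum distance, metres, between consecutive stops
#'   of one night (and between a stop and the roost); keeps distinct visits
#'   spatially separable, as distinct canopies are.
#' @param night_start seconds after local midnight at which the nightly trip
#'   departs (default 20:00).
#' @param origin epoch-seconds origin of night 0 (local midnight).
#' @param n_manipulated number of odour-smeared bats in a manipulation.
#' @param response_prob probability that a naive bat responds to the
#'   manipulation by visiting a focal tree.
#' @param manipulated_response_prob same, for smeared bats themselves.
#' @param lag_pmf probability mass over response lags of 1-6 nights after
#'   the manipulation. The default reproduces the observed lag tally
#'   (3, 2, 2, 2, 0, 1)/10.
#' @param seed integer seed; when non-NULL every stochastic draw of the
#'   generators flows from it.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_bats = 50,
                       n_nights = 10,
                       n_trees = 1000,
                       n_focal = 2,
                       frac_unpredictable = 0.07,
                       extent = 14000,
                       roost_xy = c(0, extent / 2),
                       n_roosts = 1,
                       sampling_interval = 4,
                       noise_sd = 5,
                       commute_speed = 10,
                       trees_per_night = 1:5,
                       repertoire_size = 1:5,
                       revisit_prob = 0.8,
                       dwell_median = 540,
                       dwell_sdlog = 0.7,
                       dwell_min = 4,
                       dwell_max = 3000,
                       min_tree_gap = 200,
                       night_start = 20 * 3600,
                       origin = 0,
                       n_manipulated = 16,
                       response_prob = 0.18,
                       manipulated_response_prob = 0.25,
                       lag_pmf = c(3, 2, 2, 2, 0, 1) / 10,
                       seed = NULL) {
  cfg <- list(
    n_bats = n_bats, n_nights = n_nights, n_trees = n_trees,
    n_focal = n_focal, frac_unpredictable = frac_unpredictable,
    extent = extent, roost_xy = roost_xy, n_roosts = n_roosts,
    sampling_interval = sampling_interval, noise_sd = noise_sd,
    commute_speed = commute_speed, trees_per_night = trees_per_night,
    repertoire_size = repertoire_size, revisit_prob = revisit_prob,
    dwell_median = dwell_median, dwell_sdlog = dwell_sdlog,
    dwell_min = dwell_min, dwell_max = dwell_max,
    min_tree_gap = min_tree_gap, night_start = night_start,
    origin = origin, n_manipulated = n_manipulated,
    response_prob = response_prob,
    manipulated_response_prob = manipulated_response_prob,
    lag_pmf = lag_pmf, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_bats >= 0, cfg$n_nights >= 0, cfg$n_trees >= 0,
    cfg$extent > 0, cfg$sampling_interval > 0,
    cfg$noise_sd >= 0, cfg$commute_speed > 0,
    cfg$dwell_min > 0, cfg$dwell_max >= cfg$dwell_min
  )
  if (cfg$n_focal < 0 || cfg$n_focal > cfg$n_trees) {
    stop("invalid config: n_focal must be between 0 and n_trees", call. = FALSE)
  }
  probs <- c(
    frac_unpredictable = cfg$frac_unpredictable,
    revisit_prob = cfg$revisit_prob,
    response_prob = cfg$response_prob,
    manipulated_response_prob = cfg$manipulated_response_prob
  )
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("invalid config: ", paste(names(probs)[bad], collapse = ", "),
         " must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$lag_pmf < 0) || abs(sum(cfg$lag_pmf) - 1) > 1e-8) {
    stop("invalid config: lag_pmf must be non-negative and sum to 1",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Track segmentation parameters
#'
#' Parameters for fix filtering and first-passage segmentation of tracks
#' into tree visits.
#'
#' @param fp_radius first-passage cloud radius, metres.
#' @param min_fixes minimum consecutive fixes required to open a dwell cloud.
#' @param min_duration minimum emitted visit duration, seconds; 4 s matches
#'   the shortest visit retained in the field data.
#' @param speed_max speed-filter threshold, m/s.
#' @param quality_var_max maximum allowed larger eigenvalue of a fix's
#'   localization covariance matrix, square metres (400 m^2 ~ a 20 m sd).
#' @param match_radius maximum centroid-to-tree distance for attributing a
#'   visit to a mapped tree, metres.
#' @param straightness_max straightness (net displacement over path length)
#'   above which a short pass is classed as a flyover, in (0, 1].
#' @param boundary_trim_k after a cloud converges, leading/trailing member
#'   fixes farther than `boundary_trim_k` times the median per-axis
#'   localization sd from the centre are trimmed; separates the approach and
#'   departure flight from the dwell itself.
#'
#' @return a list of class `segmenter_params`.
#' @export
segmenter_params <- function(fp_radius = 50,
                             min_fixes = 5,
                             min_duration = 4,
                             speed_max = 20,
                             quality_var_max = 400,
                             match_radius = 50,
                             straightness_max = 0.9,
                             boundary_trim_k = 4) {
  p <- list(
    fp_radius = fp_radius, min_fixes = min_fixes,
    min_duration = min_duration, speed_max = speed_max,
    quality_var_max = quality_var_max, match_radius = match_radius,
    straightness_max = straightness_max, boundary_trim_k = boundary_trim_k
  )
  stopifnot(
    p$fp_radius > 0, p$min_fixes >= 2, p$min_duration > 0,
    p$speed_max > 0, p$quality_var_max > 0, p$match_radius > 0,
    p$straightness_max > 0, p$straightness_max <= 1,
    p$boundary_trim_k >= 0
  )
  structure(p, class = "segmenter_params")
}
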