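# shared fixtures: small simulated colonies and hand-built visit tables

small_colony <- function(seed = 11, n_bats = 5, n_nights = 3,
                         n_trees = 200, extent = 8000, ...) {
  cfg <- sim_config(
    n_bats = n_bats, n_nights = n_nights, n_trees = n_trees,
    extent = extent, seed = seed, ...
  )
  trees <- generate_landscape(cfg)
  sim <- simulate_tracks(trees, cfg)
  list(cfg = cfg, trees = trees, sim = sim)
}

# minimal visit table builder; times default to disjoint slots within night
mk_visits <- function(bat_id, night_index, tree_id,
                      t_start = NULL, t_end = NULL, flyover = FALSE) {
  n <- max(length(bat_id), length(night_index), length(tree_id))
  if (is.null(t_start)) t_start <- night_index * 86400 + seq_len(n) * 1000
  if (is.null(t_end)) t_end <- t_start + 600
  tibble::tibble(
    bat_id = rep_len(bat_id, n), night_index = rep_len(night_index, n),
    tree_id = rep_len(tree_id, n), t_start = rep_len(t_start, n),
    t_end = rep_len(t_end, n),
    duration = rep_len(t_end - t_start, n),
    flyover = rep_len(flyover, n)
  )
}

mk_roster <- function(bat_id, start_night = 0L, end_night = 9L,
                      roost = "R1") {
  tibble::tibble(
    bat_id = bat_id,
    roost = rep_len(roost, length(bat_id)),
    start_night = rep_len(start_night, length(bat_id)),
    end_night = rep_len(end_night, length(bat_id))
  )
}

# random raw fix table (unsorted covariates, sorted times) for filter tests
random_fixes <- function(n = 100, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    tag_id = "B1",
    t = cumsum(runif(n, 1, 10)),
    x = cumsum(rnorm(n, 0, 30)),
    y = cumsum(rnorm(n, 0, 30)),
    var_x = runif(n, 1, 600),
    var_y = runif(n, 1, 600),
    cov_xy = runif(n, -20, 20)
  )
}
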