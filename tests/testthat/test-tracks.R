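test_that("speed filter removes fast arrivals and preserves order", {
  p <- segmenter_params()
  fx <- tibble::tibble(
    tag_id = "B1", t = c(0, 30), x = c(0, 750), y = 0,
    var_x = 25, var_y = 25, cov_xy = 0
  )
  out <- filter_fixes(fx, p)  # 25 m/s > 20 m/s
  expect_equal(nrow(out), 1)
  expect_equal(out$t, 0)

  expect_equal(nrow(filter_fixes(fx[0, ], p)), 0)
  expect_error(filter_fixes(fx[2:1, ], p), "sorted")
})

test_that("quality filter drops fixes by covariance eigenvalue", {
  p <- segmenter_params(quality_var_max = 400)
  # plain variance bound; a correlated fix whose larger eigenvalue
  # (390 + 50 = 440) crosses the bound; and one that stays below it
  fx <- tibble::tibble(
    tag_id = "B1", t = 1:4, x = 0, y = 0,
    var_x = c(100, 500, 390, 390), var_y = c(100, 100, 390, 390),
    cov_xy = c(0, 0, 50, 5)
  )
  out <- filter_fixes(fx, p)
  expect_equal(out$t, c(1, 4))
})

test_that("fix filter agrees with a brute-force oracle on random tracks", {
  p <- segmenter_params()
  for (seed in 1:3) {
    fx <- random_fixes(100, seed)
    # independent oracle: eigenvalue bound, then causal speed pass
    eig <- ((fx$var_x + fx$var_y) +
              sqrt((fx$var_x - fx$var_y)^2 + 4 * fx$cov_xy^2)) / 2
    keep1 <- fx[eig <= p$quality_var_max, ]
    kept <- list()
    for (i in seq_len(nrow(keep1))) {
      if (length(kept) == 0) {
        kept[[1]] <- keep1[i, ]
      } else {
        prev <- kept[[length(kept)]]
        v <- sqrt((keep1$x[i] - prev$x)^2 + (keep1$y[i] - prev$y)^2) /
          (keep1$t[i] - prev$t)
        if (v <= p$speed_max) kept[[length(kept) + 1]] <- keep1[i, ]
      }
    }
    oracle <- do.call(rbind, kept)
    got <- filter_fixes(fx, p)
    expect_equal(got$t, oracle$t)
    # invariants: no new fixes, all retained speeds within bound
    expect_lte(nrow(got), nrow(fx))
    v <- sqrt(diff(got$x)^2 + diff(got$y)^2) / diff(got$t)
    expect_true(all(v <= p$speed_max + 1e-9))
  }
})

test_that("segmentation finds no visits on a fast straight track", {
  p <- segmenter_params()
  fx <- tibble::tibble(
    tag_id = "B1", t = seq(0, 400, by = 4), x = seq(0, 6000, by = 60),
    y = 0, var_x = 25, var_y = 25, cov_xy = 0
  )
  expect_equal(nrow(segment_visits(fx, params = p)), 0)
})

test_that("a stationary track yields one visit spanning the whole track", {
  p <- segmenter_params()
  set.seed(4)
  n <- 50
  fx <- tibble::tibble(
    tag_id = "B1", t = seq(0, by = 4, length.out = n),
    x = 100 + rnorm(n, 0, 5), y = -40 + rnorm(n, 0, 5),
    var_x = 25, var_y = 25, cov_xy = 0
  )
  v <- segment_visits(fx, params = p)
  expect_equal(nrow(v), 1)
  expect_equal(v$t_start, fx$t[1])
  expect_equal(v$t_end, fx$t[n])
  expect_equal(v$n_fixes, n)
  expect_false(v$flyover)
})

test_that("segmentation recovers the simulated truth log", {
  col <- small_colony(seed = 21, n_bats = 5, n_nights = 3)
  p <- segmenter_params()
  visits <- segment_visits(filter_fixes(col$sim$fixes, p), col$trees, p)
  truth <- col$sim$truth[order(col$sim$truth$bat_id, col$sim$truth$t_start), ]
  visits <- visits[order(visits$bat_id, visits$t_start), ]
  expect_equal(nrow(visits), nrow(truth))
  expect_equal(visits$bat_id, truth$bat_id)
  expect_equal(visits$tree_id, truth$tree_id)
  expect_equal(visits$night_index, truth$night_index)
  dur_err <- abs(visits$duration - (truth$t_end - truth$t_start))
  expect_lte(max(dur_err), col$cfg$sampling_interval)
})

test_that("segmentation is stable when re-run on visit-phase fixes", {
  col <- small_colony(seed = 22, n_bats = 3, n_nights = 2)
  p <- segmenter_params()
  fixes <- filter_fixes(col$sim$fixes, p)
  visits <- segment_visits(fixes, col$trees, p)
  for (k in seq_len(nrow(visits))) {
    member <- fixes[fixes$tag_id == visits$bat_id[k] &
                      fixes$t >= visits$t_start[k] &
                      fixes$t <= visits$t_end[k], ]
    again <- segment_visits(member, col$trees, p)
    expect_equal(nrow(again), 1)
    expect_equal(again$tree_id, visits$tree_id[k])
    expect_lte(abs(again$t_start - visits$t_start[k]),
               col$cfg$sampling_interval)
    expect_lte(abs(again$t_end - visits$t_end[k]),
               col$cfg$sampling_interval)
  }
  # and no two visits of one bat overlap
  for (vb in split(visits, visits$bat_id)) {
    vb <- vb[order(vb$t_start), ]
    expect_true(all(vb$t_start > head(c(-Inf, vb$t_end), -1)))
  }
})

test_that("flyover classification follows the straightness rule", {
  p <- segmenter_params(straightness_max = 0.9, min_duration = 60)
  straight <- tibble::tibble(t = seq(0, 20, 4), x = seq(0, 200, 40), y = 0)
  expect_true(classify_flyover(straight, p))

  th <- seq(0, 2 * pi, length.out = 20)
  loop <- tibble::tibble(t = seq(0, 76, 4), x = 30 * cos(th),
                         y = 30 * sin(th))
  expect_false(classify_flyover(loop, p))

  # brute-force straightness agreement on random episodes
  set.seed(8)
  for (k in 1:20) {
    n <- sample(3:15, 1)
    ep <- tibble::tibble(t = seq(0, by = 4, length.out = n),
                         x = cumsum(rnorm(n, 2, 10)),
                         y = cumsum(rnorm(n, 0, 10)))
    net <- sqrt((ep$x[n] - ep$x[1])^2 + (ep$y[n] - ep$y[1])^2)
    path <- sum(sqrt(diff(ep$x)^2 + diff(ep$y)^2))
    expected <- (net / path > p$straightness_max) &&
      (ep$t[n] - ep$t[1] < p$min_duration)
    expect_identical(classify_flyover(ep, p), expected)
  }
})

test_that("visit-tree attribution matches nearest tree with tie-breaks", {
  trees <- tibble::tibble(
    tree_id = c(2L, 1L, 3L), x = c(0, 100, 500), y = 0,
    species = "s", predictability = "seasonal", is_focal = FALSE
  )
  p <- segmenter_params(match_radius = 30)
  v <- mk_visits("B1", 0L, NA_integer_)[rep(1, 3), ]
  v$centroid_x <- c(100, 50, 460)  # exact hit; equidistant; 40 m away
  v$centroid_y <- 0
  out <- annotate_visits(v, trees, p)
  expect_equal(out$tree_id, c(1L, NA, NA))  # 50 is 50m from both, > radius

  p2 <- segmenter_params(match_radius = 60)
  out2 <- annotate_visits(v, trees, p2)
  expect_equal(out2$tree_id[2], 1L)  # equidistant from trees 1 and 2
  expect_equal(out2$tree_id[3], 3L)

  expect_warning(annotate_visits(v, trees[0, ], p), "unmatched")
})

test_that("night assignment counts noon boundaries", {
  origin <- 0
  t_2300 <- 23 * 3600
  t_0300 <- 27 * 3600
  expect_equal(assign_nights(c(t_2300, t_0300), origin), c(0L, 0L))
  expect_equal(diff(assign_nights(c(t_2300, t_2300 + 86400), origin)), 1L)
  set.seed(9)
  t <- runif(200, 0, 30 * 86400)
  expect_equal(assign_nights(t, origin),
               as.integer(floor((t - origin - 12 * 3600) / 86400)))
})
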