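test_that("encounters require positive overlap on the same tree", {
  v <- mk_visits(c("a", "b"), 0L, 1L, t_start = c(0, 300),
                 t_end = c(600, 900))
  enc <- detect_encounters(v)
  expect_equal(nrow(enc), 1)
  expect_equal(enc$overlap_start, 300)
  expect_equal(enc$overlap_end, 600)

  touching <- mk_visits(c("a", "b"), 0L, 1L, t_start = c(0, 600),
                        t_end = c(600, 900))
  expect_equal(nrow(detect_encounters(touching)), 0)

  other_tree <- mk_visits(c("a", "b"), 0L, c(1L, 2L), t_start = c(0, 300),
                          t_end = c(600, 900))
  expect_equal(nrow(detect_encounters(other_tree)), 0)

  flyover <- mk_visits(c("a", "b"), 0L, 1L, t_start = c(0, 300),
                       t_end = c(600, 900), flyover = c(FALSE, TRUE))
  expect_equal(nrow(detect_encounters(flyover)), 0)
})

test_that("encounter detection equals the all-pairs oracle and is symmetric", {
  set.seed(12)
  n <- 200
  v <- tibble::tibble(
    bat_id = sample(sprintf("B%02d", 1:8), n, replace = TRUE),
    night_index = sample(0:3, n, replace = TRUE),
    tree_id = sample(1:6, n, replace = TRUE),
    t_start = runif(n, 0, 5000),
    flyover = FALSE
  )
  v$t_end <- v$t_start + runif(n, 10, 2000)
  enc <- detect_encounters(v)

  oracle <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (v$tree_id[i] != v$tree_id[j]) next
      if (v$bat_id[i] == v$bat_id[j]) next
      os <- max(v$t_start[i], v$t_start[j])
      oe <- min(v$t_end[i], v$t_end[j])
      if (oe <= os) next
      ab <- sort(c(v$bat_id[i], v$bat_id[j]))
      oracle[[length(oracle) + 1]] <- paste(ab[1], ab[2], v$tree_id[i],
                                            round(os, 6), round(oe, 6))
    }
  }
  got <- paste(enc$bat_a, enc$bat_b, enc$tree_id,
               round(enc$overlap_start, 6), round(enc$overlap_end, 6))
  expect_setequal(got, unlist(oracle))

  shuffled <- detect_encounters(v[sample.int(n), ])
  expect_setequal(
    paste(shuffled$bat_a, shuffled$bat_b, round(shuffled$overlap_start, 6)),
    paste(enc$bat_a, enc$bat_b, round(enc$overlap_start, 6))
  )
})

test_that("dyad sharing rate counts co-tracked dyads correctly", {
  v <- mk_visits(c("a", "b"), 0L, 1L, t_start = c(0, 100),
                 t_end = c(600, 700))
  roster2 <- mk_roster(c("a", "b"), 0L, 5L)
  expect_equal(dyad_sharing_rate(v, roster2)$overall, 1)

  # disjoint tracking periods leave the denominator
  roster3 <- tibble::tibble(
    bat_id = c("a", "b", "c"), roost = c("R1", "R1", "R2"),
    start_night = c(0L, 0L, 20L), end_night = c(5L, 5L, 30L)
  )
  out <- dyad_sharing_rate(v, roster3)
  expect_equal(out$n_dyads, 1)
  expect_equal(out$overall, 1)

  # five-bat hand enumeration: dyads ab (share), ac, bc co-tracked;
  # d co-tracked but never sharing; e disjoint
  v5 <- rbind(
    mk_visits(c("a", "b"), 0L, 1L, t_start = c(0, 100), t_end = c(600, 700)),
    mk_visits("c", 1L, 2L), mk_visits("d", 2L, 3L)
  )
  roster5 <- tibble::tibble(
    bat_id = c("a", "b", "c", "d", "e"),
    roost = c("R1", "R1", "R2", "R1", "R1"),
    start_night = c(0L, 0L, 0L, 0L, 50L),
    end_night = c(9L, 9L, 9L, 9L, 60L)
  )
  out5 <- dyad_sharing_rate(v5, roster5)
  expect_equal(out5$n_dyads, 6)  # all pairs among a,b,c,d
  expect_equal(out5$n_sharing, 1)
  expect_equal(out5$overall, 1 / 6)
  expect_equal(out5$same_roost, 1 / 3)  # ab of ab, ad, bd
  expect_equal(out5$diff_roost, 0)
})

test_that("discovery records follow the set-algebra definition", {
  # partner p visited tree 10 pre-meeting (night 4); focal f visits it on
  # night +2 -> response at lag 2 only (post windows: lag1 covers 6-8,
  # lag2 covers 7-9, lag3 covers 8-10)
  meeting <- tibble::tibble(bat_a = "f", bat_b = "p", night = 5L, met = TRUE)
  v <- rbind(
    mk_visits("p", 4L, 10L),
    mk_visits("f", 7L, 10L),
    mk_visits("f", 2L, 20L)
  )
  rec <- build_discovery_records(v, meeting, lags = 1:3)
  f_rec <- rec[rec$focal_id == "f", ]
  expect_equal(f_rec$response, c(TRUE, TRUE, FALSE))

  # pre-visited trees are excluded from the candidate set
  v2 <- rbind(v, mk_visits("f", 3L, 10L))
  rec2 <- build_discovery_records(v2, meeting, lags = 1:3)
  expect_false(any(rec2$response[rec2$focal_id == "f"]))

  # both members yield records
  expect_setequal(unique(rec$focal_id), c("f", "p"))
})

test_that("discovery records match an independent oracle on a colony", {
  set.seed(19)
  bats <- sprintf("B%02d", 1:10)
  v <- tibble::tibble(
    bat_id = sample(bats, 150, replace = TRUE),
    night_index = sample(0:14, 150, replace = TRUE),
    tree_id = sample(1:12, 150, replace = TRUE),
    flyover = FALSE
  )
  v$t_start <- v$night_index * 86400 + runif(150, 0, 4000)
  v$t_end <- v$t_start + runif(150, 60, 3000)
  meetings <- tibble::tibble(
    bat_a = c("B01", "B03", "B05"), bat_b = c("B02", "B04", "B06"),
    night = c(5L, 7L, 9L), met = c(TRUE, TRUE, FALSE)
  )
  rec <- build_discovery_records(v, meetings, lags = 1:4)
  expect_equal(nrow(rec), 3 * 2 * 4)
  for (k in seq_len(nrow(rec))) {
    m <- rec$night[k]
    L <- rec$lag_nights[k]
    pt <- unique(v$tree_id[v$bat_id == rec$partner_id[k] &
                             v$night_index >= m - 3 & v$night_index <= m - 1])
    hist <- unique(v$tree_id[v$bat_id == rec$focal_id[k] &
                               v$night_index <= m])
    post <- unique(v$tree_id[v$bat_id == rec$focal_id[k] &
                               v$night_index >= m + L &
                               v$night_index <= m + L + 2])
    expect_identical(rec$response[k],
                     length(intersect(setdiff(post, hist), pt)) > 0)
  }
})

test_that("ficus_only restricts partner trees to unpredictable species", {
  trees <- tibble::tibble(
    tree_id = 1:2, x = 0, y = 0, species = c("a", "b"),
    predictability = c("seasonal", "unpredictable"), is_focal = FALSE
  )
  meeting <- tibble::tibble(bat_a = "f", bat_b = "p", night = 5L, met = TRUE)
  v <- rbind(mk_visits("p", 4L, 1L), mk_visits("f", 6L, 1L))
  rec_all <- build_discovery_records(v, meeting, lags = 1)
  rec_fic <- build_discovery_records(v, meeting, lags = 1, ficus_only = TRUE,
                                     trees = trees)
  expect_true(rec_all$response[rec_all$focal_id == "f"])
  expect_false(rec_fic$response[rec_fic$focal_id == "f"])
  expect_error(build_discovery_records(v, meeting, ficus_only = TRUE),
               "tree table")
})

test_that("control dyads are matched, never-met and reproducible", {
  roster <- mk_roster(sprintf("B%02d", 1:8), 0L, 29L)
  meetings <- tibble::tibble(
    bat_a = c("B01", "B03"), bat_b = c("B02", "B04"),
    night = c(5L, 20L), met = TRUE
  )
  ctl <- sample_control_dyads(roster, meetings, seed = 4)
  expect_equal(nrow(ctl), 2)
  expect_false(any(paste(ctl$bat_a, ctl$bat_b) %in%
                     paste(meetings$bat_a, meetings$bat_b)))
  expect_identical(ctl, sample_control_dyads(roster, meetings, seed = 4))

  # all dyads met -> error
  roster2 <- mk_roster(c("B01", "B02"), 0L, 9L)
  met2 <- tibble::tibble(bat_a = "B01", bat_b = "B02", night = 3L,
                         met = TRUE)
  expect_error(sample_control_dyads(roster2, met2), "insufficient")
})

test_that("two-group logistic fit equals the exact table log odds ratio", {
  rec <- tibble::tibble(
    focal_id = "x", partner_id = "y",
    met = rep(c(TRUE, FALSE), each = 100),
    lag_nights = 1L,
    response = c(rep(c(TRUE, FALSE), c(30, 70)),
                 rep(c(TRUE, FALSE), c(10, 90))),
    night = 0L
  )
  fit <- fit_lag_models(rec)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$coef - log((30 / 70) / (10 / 90))), 1e-6)
  # saturated two-group identity: fitted probabilities = raw frequencies
  expect_equal(fit$p_met, 0.3)
  expect_equal(fit$p_control, 0.1)
})

test_that("degenerate and separated responses are flagged", {
  rec <- tibble::tibble(
    focal_id = "x", partner_id = "y", met = rep(c(TRUE, FALSE), each = 20),
    lag_nights = 1L, response = FALSE, night = 0L
  )
  fit <- fit_lag_models(rec)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$coef))

  rec$response <- rec$met  # complete separation
  fit2 <- fit_lag_models(rec)
  expect_true(fit2$degenerate)
})

test_that("logistic z-statistics are calibrated when groups are equal", {
  set.seed(26)
  reject <- vapply(1:200, function(i) {
    rec <- tibble::tibble(
      focal_id = "x", partner_id = "y",
      met = rep(c(TRUE, FALSE), each = 80), lag_nights = 1L,
      response = runif(160) < 0.25, night = 0L
    )
    fit <- fit_lag_models(rec)
    !fit$degenerate && abs(fit$z) > 1.96
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.05)
})

test_that("stronger copying effects raise the fitted met-group probability", {
  set.seed(27)
  mean_pmet <- vapply(c(0.1, 0.25, 0.45), function(p_met) {
    mean(vapply(1:30, function(i) {
      rec <- tibble::tibble(
        focal_id = "x", partner_id = "y",
        met = rep(c(TRUE, FALSE), each = 120), lag_nights = 1L,
        response = c(runif(120) < p_met, runif(120) < 0.1), night = 0L
      )
      fit_lag_models(rec)$p_met
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_pmet) > 0))
})
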