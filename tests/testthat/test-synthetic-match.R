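test_that("zero-noise players with a pinned ball sit on their anchors", {
  cfg <- tiny_config(seed = 4, period_min = 0.5, n_periods = 1)
  params <- movement_params(noise_sd_m = 0, ball_sd_m = c(0, 0))
  tr <- simulate_trajectories(cfg, params)
  anchors <- cfg$roster
  for (i in seq_len(nrow(anchors))) {
    p <- tr$positions[tr$positions$player_id == anchors$player_id[i], ]
    expect_equal(unique(p$x_m), anchors$anchor_x[i])
    expect_equal(unique(p$y_m), anchors$anchor_y[i])
  }
  ds <- dyad_distance_series(tr, "home")
  expect_true(all(apply(ds$d, 2, function(v) diff(range(v))) == 0))
})

test_that("sample grid matches the configured clock", {
  cfg <- match_config(seed = 1)  # 2 x 25 min at 5 Hz
  n_expected <- 2 * 25 * 60 * 5
  tr <- simulate_trajectories(cfg, movement_params(noise_sd_m = 0,
                                                   ball_sd_m = c(0, 0)))
  counts <- table(tr$positions$player_id)
  expect_true(all(counts == n_expected))
  expect_equal(nrow(tr$ball), n_expected)
  t_one <- tr$positions$time_s[tr$positions$player_id == cfg$roster$player_id[1]]
  expect_equal(diff(sort(unique(round(diff(t_one), 9)))), numeric(0))
})

test_that("trajectories are deterministic in the seed and vary across seeds", {
  cfg <- tiny_config(seed = 7, period_min = 0.5, n_periods = 1)
  a <- simulate_trajectories(cfg)
  b <- simulate_trajectories(cfg)
  expect_identical(a, b)
  cfg2 <- tiny_config(seed = 8, period_min = 0.5, n_periods = 1)
  c <- simulate_trajectories(cfg2)
  expect_false(isTRUE(all.equal(a$positions$x_m, c$positions$x_m)))
})

test_that("generated positions stay inside the pitch rectangle", {
  cfg <- tiny_config(seed = 2, period_min = 0.5, n_periods = 1)
  tr <- simulate_trajectories(cfg, movement_params(noise_sd_m = 4))
  expect_true(all(tr$positions$x_m >= 0 & tr$positions$x_m <= 106))
  expect_true(all(tr$positions$y_m >= 0 & tr$positions$y_m <= 65))
})

test_that("pass simulation respects topology and determinism contracts", {
  cfg <- tiny_config(seed = 5)
  empty <- simulate_passes(cfg, pass_topology(n_passes = 0))
  expect_equal(nrow(empty), 0)

  log <- simulate_passes(cfg, pass_topology(n_passes = 300))
  expect_equal(nrow(log), 300)
  expect_true(all(log$passer_id != log$receiver_id))
  expect_true(all(log$success))
  expect_identical(log, simulate_passes(cfg, pass_topology(n_passes = 300)))

  bad <- matrix(1 / 10, 10, 10)  # rows sum to 1 but nonzero diagonal
  expect_error(pass_topology(transition_matrix = bad), "diagonal")
  bad2 <- matrix(1 / 8, 10, 10); diag(bad2) <- 0
  expect_error(pass_topology(transition_matrix = bad2), "sum to 1")
})

test_that("uniform topology spreads counts evenly over the 90 directed dyads", {
  cfg <- tiny_config(seed = 11)
  log <- simulate_passes(cfg, pass_topology(n_passes = 900))
  roster <- cfg$roster$player_id[cfg$roster$team == "home"]
  net <- build_adjacency(log, roster)
  off_diag <- net$A[row(net$A) != col(net$A)]
  expect_equal(sum(off_diag), 900)
  expect_true(all(abs(off_diag - 10) <= 12))
})

test_that("hub-biased chains concentrate betweenness on the hub", {
  cfg <- tiny_config(seed = 9)
  log <- simulate_passes(cfg, pass_topology(n_passes = 400, hub_bias = 0.9))
  roster <- cfg$roster$player_id[cfg$roster$team == "home"]
  net <- build_adjacency(log, roster)
  sc <- centrality_scores(net, "reciprocal")
  hub_id <- "home_DCM"
  expect_equal(sc$player_id[which.max(sc$betweenness)], hub_id)
})

test_that("fixture validates planted correlation and shot bookkeeping", {
  cfg <- tiny_config(seed = 3, period_min = 0.5, n_periods = 1)
  expect_error(make_match_fixture(cfg, planted_rho = -1.2), "planted_rho")
  expect_error(make_match_fixture(cfg, planted_rho = 0.3), "planted_rho")
  expect_error(make_match_fixture(cfg, shots = c(2, 2), goals = c(3, 0)),
               "goals")

  fx <- make_match_fixture(cfg, topology = pass_topology(n_passes = 120),
                           planted_rho = 0, shots = c(5, 4), goals = c(0, 2))
  expect_equal(nrow(fx$passes), 240)  # n_passes per team
  expect_true(all(fx$passes$passer_id != fx$passes$receiver_id))
  expect_equal(sum(fx$shots$goal[fx$shots$team == "home"]), 0)
  expect_equal(efficacy(0, 5), 0)
  expect_identical(
    make_match_fixture(cfg, topology = pass_topology(n_passes = 120),
                       planted_rho = 0, shots = c(5, 4), goals = c(0, 2)),
    fx)
})

test_that("mean dyad ApEn increases with the positional noise level", {
  ordered <- sapply(1:6, function(s) {
    apens <- sapply(c(0.4, 1.0, 2.2), function(ns) {
      cfg <- match_config(period_min = 1, n_periods = 1, seed = s)
      tr <- simulate_trajectories(cfg, movement_params(noise_sd_m = ns))
      mean(dyad_apen(tr, "home")$apen)
    })
    all(diff(apens) > 0)
  })
  expect_true(mean(ordered) >= 0.95)
})
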