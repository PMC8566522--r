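test_that("config validation rejects invalid worlds", {
  expect_error(simulation_config(post_share = 0), "post_share")
  expect_error(simulation_config(post_share = 1.2), "post_share")
  expect_error(simulation_config(teams_per_league = 1), "teams_per_league")
  expect_error(simulation_config(n_leagues = 0), "n_leagues")
  expect_error(simulation_config(team_sd = -1), "team_sd")
  expect_error(
    simulation_config(baseline_rates = c(corners = -1, shots = 1,
                                         shots_on_target = 1, fouls = 1,
                                         yellows = 1, reds = 1, goals = 1)),
    "baseline_rates")
  expect_error(structural_params(a1_pre = Inf), "non-finite")
})

test_that("same config and seed give byte-identical tables", {
  m1 <- simulate_matches(tiny_config(seed = 99))
  m2 <- simulate_matches(tiny_config(seed = 99))
  expect_identical(m1, m2)
  m3 <- simulate_matches(tiny_config(seed = 100))
  expect_false(identical(m1$home_goals, m3$home_goals))
})

test_that("pairing and scoring identities hold on every simulated match", {
  m <- small_matches()
  tg <- to_game_pairs(m)
  home <- tg[tg$venue == "home", ]
  away <- tg[tg$venue == "away", ]
  away <- away[match(home$match_id, away$match_id), ]
  expect_identical(home$goals_for, away$goals_against)
  expect_identical(home$goals_against, away$goals_for)
  pts <- paste(home$points, away$points)
  expect_true(all(pts %in% c("3 0", "0 3", "1 1")))
})

test_that("realized no-crowd share is close to the configured share", {
  m <- simulate_matches(simulation_config(n_leagues = 4,
                                          teams_per_league = 18, seed = 3))
  expect_gt(nrow(m), 1000)
  expect_lt(abs(mean(m$period == "no_crowd") - 0.26), 0.05)
})

test_that("null world has no home advantage; venue effect has the right sign", {
  null_cfg <- simulation_config(n_leagues = 8, teams_per_league = 18,
                                seed = 21, true_paths = null_structural_params())
  tg <- to_game_pairs(simulate_matches(null_cfg))
  n_match <- nrow(tg) / 2
  expect_gte(n_match, 2000)
  ha <- mean(tg$points[tg$venue == "home"]) - mean(tg$points[tg$venue == "away"])
  # paired comparison; 3 conservative iid-based MC SEs
  se <- sqrt(var(tg$points[tg$venue == "home"]) / n_match +
               var(tg$points[tg$venue == "away"]) / n_match)
  expect_lt(abs(ha), 3 * se)

  # crowd-period-only world with positive venue -> performance -> outcome
  pos <- structural_params(a1_pre = 0.9, a1_post = 0.9, a2_pre = 0,
                           a2_post = 0, d_pre = 0, d_post = 0,
                           b1_pre = 0.5, b1_post = 0.5, b2_pre = 0,
                           b2_post = 0, c_pre = 0, c_post = 0,
                           gamma_rating = 0, gamma_importance = 0)
  cfg <- simulation_config(n_leagues = 3, teams_per_league = 10, seed = 8,
                           true_paths = pos)
  tg <- to_game_pairs(simulate_matches(cfg))
  ha_small <- mean(tg$points[tg$venue == "home"]) -
    mean(tg$points[tg$venue == "away"])
  # oracle: brute-force regeneration at ~10x the matches
  cfg10 <- simulation_config(n_leagues = 10, teams_per_league = 18, seed = 9,
                             true_paths = pos)
  tg10 <- to_game_pairs(simulate_matches(cfg10))
  ha_big <- mean(tg10$points[tg10$venue == "home"]) -
    mean(tg10$points[tg10$venue == "away"])
  expect_gt(ha_big, 0)
  expect_gt(ha_small, 0)
})

test_that("doubling team_sd increases between-team spread of mean performance", {
  spread <- function(team_sd, seed) {
    cfg <- simulation_config(n_leagues = 3, teams_per_league = 10,
                             seed = seed, team_sd = team_sd)
    tg <- to_game_pairs(simulate_matches(cfg))
    team_means <- tapply(tg$latent_tp, tg$team_id, mean)
    stats::var(team_means)
  }
  expect_gt(mean(sapply(1:3, function(s) spread(0.6, s))),
            mean(sapply(1:3, function(s) spread(0.3, s))))
})

test_that("ground_truth_effects matches independent symbolic expansion", {
  # all-zero world
  g0 <- ground_truth_effects(null_structural_params())
  expect_true(all(g0$estimate == 0))

  # published-value check: total on referee = a2 + a1 * d
  p <- structural_params(a1_pre = 0.89, d_pre = -0.14, a2_pre = -0.30)
  g <- ground_truth_effects(p)
  tot_pre <- g$estimate[g$quantity == "total_on_referee" & g$period == "pre"]
  expect_equal(round(tot_pre, 2), -0.42)

  # randomized re-expansion oracle
  set.seed(4)
  for (i in 1:10) {
    vals <- as.list(setNames(round(rnorm(14), 2),
                             names(structural_params())))
    p <- do.call(structural_params, vals)
    g <- ground_truth_effects(p, include_serial_in_total = TRUE)
    pick <- function(q, s) g$estimate[g$quantity == q & g$period == s]
    for (s in c("pre", "post")) {
      a1 <- vals[[paste0("a1_", s)]]; a2 <- vals[[paste0("a2_", s)]]
      d <- vals[[paste0("d_", s)]]; b1 <- vals[[paste0("b1_", s)]]
      b2 <- vals[[paste0("b2_", s)]]; cc <- vals[[paste0("c_", s)]]
      expect_equal(pick("total_on_outcome", s),
                   cc + a1 * b1 + a2 * b2 + a1 * d * b2, tolerance = 1e-12)
      expect_equal(pick("total_on_referee", s), a2 + a1 * d,
                   tolerance = 1e-12)
    }
    expect_equal(pick("direct", "delta"),
                 vals$c_pre - vals$c_post, tolerance = 1e-12)
  }
})
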