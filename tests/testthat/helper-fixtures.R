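# Shared fixtures: small simulated worlds reused across test files.
# Everything is generated in code; no stored data.

small_config <- function(seed = 11, ...) {
  simulation_config(n_leagues = 3, teams_per_league = 8, seed = seed, ...)
}

tiny_config <- function(seed = 11, ...) {
  simulation_config(n_leagues = 2, teams_per_league = 6, seed = seed, ...)
}

# settings sized for unit tests (not for reporting precision)
fast_settings <- function(seed = 1, ...) {
  suppressWarnings(estimation_settings(chains = 2, warmup = 150,
                                       draws_per_chain = 150, seed = seed,
                                       ...))
}

small_matches <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_matches(small_config())
    cache
  }
})

# hand-built 3-match fixture with known values
manual_matches <- function() {
  df <- data.frame(
    league_id = "L1", match_id = c("M1", "M2", "M3"), round = 1:3,
    period = c("crowd", "crowd", "no_crowd"),
    home_team = c("A", "B", "A"), away_team = c("B", "C", "C"),
    home_goals = c(2, 1, 0), away_goals = c(1, 1, 3),
    home_corners = c(6, 4, 3), away_corners = c(3, 5, 7),
    home_shots = c(15, 10, 8), away_shots = c(9, 11, 14),
    home_shots_on_target = c(6, 3, 2), away_shots_on_target = c(3, 4, 6),
    home_fouls = c(10, 12, 14), away_fouls = c(13, 11, 9),
    home_yellows = c(1, 2, 3), away_yellows = c(2, 2, 1),
    home_reds = c(0, 0, 1), away_reds = c(0, 1, 0),
    home_rating = c(0.5, -0.2, 0.5), away_rating = c(-0.2, 0.1, 0.1),
    home_importance = c(60, 40, 70), away_importance = c(55, 45, 30),
    stringsAsFactors = FALSE)
  class(df) <- c("match_table", "data.frame")
  df
}
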