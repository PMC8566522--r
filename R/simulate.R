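#' Structural path coefficients of the home-advantage mediation model
#'
#' Container for the standardized path coefficients of the three linked
#' structural equations (Venue -> Team Performance -> Referees' Decisions ->
#' Outcome), one value per crowd regime. `pre` refers to matches played with
#' spectators, `post` to matches played behind closed doors.
#'
#' Defaults are the headline path values of the crowd/no-crowd natural
#' experiment this package models: venue's effect on team performance more
#' than halves without fans (0.89 vs 0.35), referee bias towards the home
#' team reverses (-0.30 vs +0.19), and the performance -> referee path
#' weakens slightly (-0.14 vs -0.08). The performance -> outcome,
#' referee -> outcome and direct venue -> outcome paths are held constant
#' across periods at values consistent with the reported mediations
#' (0.26/0.12 via performance, 0.03/-0.01 via refereeing, totals 0.57/0.36).
#'
#' @param a1_pre,a1_post Venue -> Team Performance path.
#' @param a2_pre,a2_post Venue -> Referees' Decisions path.
#' @param d_pre,d_post Team Performance -> Referees' Decisions path.
#' @param b1_pre,b1_post Team Performance -> Outcome path.
#' @param b2_pre,b2_post Referees' Decisions -> Outcome path.
#' @param c_pre,c_post Direct Venue -> Outcome path.
#' @param gamma_rating,gamma_importance Control-covariate coefficients
#'   (standardized team rating and match importance), applied in every
#'   equation.
#' @return An object of class `structural_params` (named list).
#' @export
#' @examples
#' structural_params(a1_pre = 0.5, a1_post = 0.2)
structural_params <- function(a1_pre = 0.89, a1_post = 0.35,
                              a2_pre = -0.30, a2_post = 0.19,
                              d_pre = -0.14, d_post = -0.08,
                              b1_pre = 0.30, b1_post = 0.30,
                              b2_pre = -0.08, b2_post = -0.08,
                              c_pre = 0.26, c_post = 0.26,
                              gamma_rating = 0.20, gamma_importance = 0.10) {
  p <- list(a1_pre = a1_pre, a1_post = a1_post,
            a2_pre = a2_pre, a2_post = a2_post,
            d_pre = d_pre, d_post = d_post,
            b1_pre = b1_pre, b1_post = b1_post,
            b2_pre = b2_pre, b2_post = b2_post,
            c_pre = c_pre, c_post = c_post,
            gamma_rating = gamma_rating,
            gamma_importance = gamma_importance)
  bad <- !vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (any(bad))
    stop("structural_params: non-finite or non-scalar value for: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  class(p) <- "structural_params"
  p
}

#' Zeroed structural parameters
#'
#' Convenience constructor for the global null (every path and control
#' coefficient zero), used for calibration checks.
#' @return A `structural_params` object with all entries 0.
#' @export
null_structural_params <- function() {
  do.call(structural_params,
          as.list(setNames(rep(0, 14), names(structural_params()))))
}

# Indicator sets per construct; fixed vocabulary used across the package.
.performance_indicators <- c("corners", "shots", "shots_on_target")
.referee_indicators <- c("fouls", "yellows", "reds")
.outcome_indicators <- c("points", "goals_for")
.count_indicators <- c(.performance_indicators, .referee_indicators)

#' Configuration of the synthetic match generator
#'
#' Describes a season of round-robin league play split chronologically into a
#' crowd period and a no-crowd period, with latent team performance,
#' refereeing and outcome constructs generated from a known structural model
#' and observed only through count indicators.
#'
#' Default sizes emulate a 12-league season of 18-team double round robins
#' with roughly a quarter of matches behind closed doors. Baseline indicator
#' rates are typical per-match magnitudes for top-flight European football
#' (about 5 corners, 12.5 shots, 4.3 on target, 12 fouls, 2 yellow cards,
#' 0.09 red cards and 1.35 goals per team per match).
#'
#' @param n_leagues Number of leagues (>= 1).
#' @param teams_per_league Teams per league (>= 2).
#' @param rounds Schedule length in rounds; default `2 * (teams_per_league - 1)`
#'   (a double round robin).
#' @param post_share Fraction of the schedule played without crowds, assigned
#'   chronologically to the final rounds; must lie strictly in (0, 1).
#' @param seed Integer seed; the generator is fully reproducible.
#' @param true_paths A [structural_params()] object.
#' @param team_sd,league_sd Standard deviations of the team and league random
#'   intercepts (each construct gets independent intercepts).
#' @param latent_cell_sd Residual SD shared by all matches of one
#'   team x venue x period cell (variation that survives aggregation).
#' @param latent_game_sd Match-to-match residual SD (averages away under
#'   aggregation).
#' @param indicator_loadings Named vector: change in each observed count per
#'   1 SD of its latent construct; `goals` acts on the log mean of the
#'   Poisson goal count.
#' @param indicator_noise Named vector of residual SDs for the count
#'   indicators.
#' @param baseline_rates Named vector of per-match baseline counts
#'   (all > 0); `goals` is the Poisson base rate.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_leagues = 12,
                              teams_per_league = 18,
                              rounds = NULL,
                              post_share = 0.26,
                              seed = 1L,
                              true_paths = structural_params(),
                              team_sd = 0.30,
                              league_sd = 0.15,
                              latent_cell_sd = 0.80,
                              latent_game_sd = 0.60,
                              indicator_loadings = c(
                                corners = 2.2, shots = 4.5,
                                shots_on_target = 1.8,
                                fouls = 2.8, yellows = 0.9, reds = 0.15,
                                goals = 0.35),
                              indicator_noise = c(
                                corners = 1.2, shots = 2.2,
                                shots_on_target = 1.0,
                                fouls = 1.8, yellows = 0.7, reds = 0.30),
                              baseline_rates = c(
                                corners = 5.0, shots = 12.5,
                                shots_on_target = 4.3,
                                fouls = 11.9, yellows = 2.0, reds = 0.09,
                                goals = 1.35)) {
  if (is.null(rounds)) rounds <- 2L * (teams_per_league - 1L)
  if (!is.numeric(n_leagues) || n_leagues < 1)
    stop("simulation_config: n_leagues must be >= 1", call. = FALSE)
  if (!is.numeric(teams_per_league) || teams_per_league < 2)
    stop("simulation_config: teams_per_league must be >= 2", call. = FALSE)
  if (!is.numeric(rounds) || rounds < 1)
    stop("simulation_config: rounds must be >= 1", call. = FALSE)
  if (!is.numeric(post_share) || post_share <= 0 || post_share >= 1)
    stop("simulation_config: post_share must lie strictly in (0, 1)",
         call. = FALSE)
  if (!inherits(true_paths, "structural_params"))
    stop("simulation_config: true_paths must be a structural_params object",
         call. = FALSE)
  for (nm in c("team_sd", "league_sd", "latent_cell_sd", "latent_game_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("simulation_config: ", nm, " must be a finite non-negative scalar",
           call. = FALSE)
  }
  need <- c(.count_indicators, "goals")
  if (!all(need %in% names(baseline_rates)) || any(baseline_rates[need] <= 0))
    stop("simulation_config: baseline_rates must be positive and named for ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(need %in% names(indicator_loadings)))
    stop("simulation_config: indicator_loadings must be named for ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(.count_indicators %in% names(indicator_noise)) ||
      any(indicator_noise[.count_indicators] < 0))
    stop("simulation_config: indicator_noise must be non-negative and named for ",
         paste(.count_indicators, collapse = ", "), call. = FALSE)
  structure(list(
    n_leagues = as.integer(n_leagues),
    teams_per_league = as.integer(teams_per_league),
    rounds = as.integer(rounds),
    post_share = post_share,
    seed = as.integer(seed),
    true_paths = true_paths,
    team_sd = team_sd, league_sd = league_sd,
    latent_cell_sd = latent_cell_sd, latent_game_sd = latent_game_sd,
    indicator_loadings = indicator_loadings,
    indicator_noise = indicator_noise,
    baseline_rates = baseline_rates), class = "simulation_config")
}

# Single round-robin pairing by the circle method; returns a data.frame of
# (round, home, away) team indices for rounds 1..n_rounds, cycling through
# repeated round robins with mirrored venues on even cycles.
.schedule_league <- function(n_teams, n_rounds) {
  teams <- seq_len(n_teams)
  odd <- n_teams %% 2L == 1L
  if (odd) teams <- c(teams, NA_integer_)  # bye
  m <- length(teams)
  base_rounds <- m - 1L
  fixed <- teams[1L]
  rot <- teams[-1L]
  out <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    k <- (r - 1L) %% base_rounds
    cycle <- (r - 1L) %/% base_rounds
    cur <- c(fixed, rot[((seq_len(m - 1L) - 1L + k) %% (m - 1L)) + 1L])
    a <- cur[seq_len(m / 2L)]
    b <- rev(cur)[seq_len(m / 2L)]
    # alternate venue by round, mirror on odd cycles for balance
    flip <- xor(r %% 2L == 0L, cycle %% 2L == 1L)
    home <- ifelse(rep(flip, m / 2L), b, a)
    away <- ifelse(rep(flip, m / 2L), a, b)
    keep <- !is.na(home) & !is.na(away)
    out[[r]] <- data.frame(round = r, home = home[keep], away = away[keep])
  }
  do.call(rbind, out)
}

# Period coefficient: pre + (post - pre) * P, vectorized over P in {0,1}
.path_at <- function(params, name, post) {
  pre <- params[[paste0(name, "_pre")]]
  pst <- params[[paste0(name, "_post")]]
  pre + (pst - pre) * post
}

#' Simulate a season of paired home/away matches
#'
#' Generates a match table whose statistical structure follows the mediation
#' model: per side of each match a latent team-performance value responds to
#' venue, controls and team/league intercepts; a latent refereeing value
#' responds to venue and team performance; a latent outcome value responds to
#' venue and both mediators. Every path takes its `pre` value in the crowd
#' period and its `post` value in the no-crowd period. Observed counts are
#' baseline + loading * latent + noise, rounded and truncated at zero; goals
#' are Poisson with log mean shifted by the outcome latent; points follow
#' deterministically from the scoreline.
#'
#' The returned table carries the canonical match schema (see
#' [canonical_match_columns()]) plus hidden ground-truth columns
#' (`home_latent_tp`, ..., `away_latent_out`) used by recovery harnesses;
#' [write_matches()] drops the truth columns unless asked.
#'
#' @param config A [simulation_config()].
#' @return A `data.frame` of matches (class `c("match_table", "data.frame")`),
#'   with attributes `seed` and `config`.
#' @export
#' @examples
#' m <- simulate_matches(simulation_config(n_leagues = 2, teams_per_league = 6,
#'                                         seed = 7))
#' nrow(m)
simulate_matches <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("simulate_matches: config must be a simulation_config", call. = FALSE)
  set.seed(config$seed)
  p <- config$true_paths
  L <- config$n_leagues; Tn <- config$teams_per_league; R <- config$rounds
  n_post_rounds <- min(R - 1L, max(1L, round(config$post_share * R)))
  first_post_round <- R - n_post_rounds + 1L

  leagues <- sprintf("L%02d", seq_len(L))
  all <- vector("list", L)
  match_counter <- 0L
  for (li in seq_len(L)) {
    sched <- .schedule_league(Tn, R)
    team_ids <- sprintf("%s_T%02d", leagues[li], seq_len(Tn))
    # league and team structure
    league_eff <- stats::rnorm(3, 0, config$league_sd)    # tp, rd, out
    league_rating_mean <- stats::rnorm(1, 0, 0.5)
    team_eff <- matrix(stats::rnorm(Tn * 3, 0, config$team_sd), Tn, 3)
    team_rating <- stats::rnorm(Tn, league_rating_mean, 1)
    # cell residuals: team x venue x period per construct
    cell_eps <- array(stats::rnorm(Tn * 2 * 2 * 3, 0, config$latent_cell_sd),
                      dim = c(Tn, 2, 2, 3))  # venue(1=away,2=home), period(1=pre,2=post)

    n_m <- nrow(sched)
    post <- as.integer(sched$round >= first_post_round)
    side <- function(team, venue) {
      # latents for one side of every match in this league
      opp <- if (venue == 1L) sched$away else sched$home
      idx <- if (venue == 1L) sched$home else sched$away
      imp <- stats::runif(n_m, 0, 100)
      z_imp <- (imp - 50) / (100 / sqrt(12))
      z_rat <- team_rating[idx] / sqrt(0.5^2 + 1^2)
      ctrl <- p$gamma_rating * z_rat + p$gamma_importance * z_imp
      ce <- function(k) cell_eps[cbind(idx, venue + 1L, post + 1L, k)]
      tp <- .path_at(p, "a1", post) * venue + ctrl +
        team_eff[idx, 1] + league_eff[1] + ce(1L) +
        stats::rnorm(n_m, 0, config$latent_game_sd)
      rd <- .path_at(p, "a2", post) * venue + .path_at(p, "d", post) * tp +
        ctrl + team_eff[idx, 2] + league_eff[2] + ce(2L) +
        stats::rnorm(n_m, 0, config$latent_game_sd)
      out <- .path_at(p, "c", post) * venue + .path_at(p, "b1", post) * tp +
        .path_at(p, "b2", post) * rd + ctrl +
        team_eff[idx, 3] + league_eff[3] + ce(3L) +
        stats::rnorm(n_m, 0, config$latent_game_sd)
      counts <- lapply(.count_indicators, function(k) {
        lat <- if (k %in% .performance_indicators) tp else rd
        pmax(0, round(config$baseline_rates[[k]] +
                        config$indicator_loadings[[k]] * lat +
                        stats::rnorm(n_m, 0, config$indicator_noise[[k]])))
      })
      names(counts) <- .count_indicators
      lambda <- pmin(25, config$baseline_rates[["goals"]] *
                       exp(config$indicator_loadings[["goals"]] * out))
      goals <- stats::rpois(n_m, lambda)
      list(team = team_ids[idx], rating = team_rating[idx], importance = imp,
           goals = goals, counts = counts, tp = tp, rd = rd, out = out)
    }
    h <- side(NULL, 1L)
    a <- side(NULL, 0L)
    df <- data.frame(
      league_id = leagues[li],
      match_id = sprintf("M%06d", match_counter + seq_len(n_m)),
      round = sched$round,
      period = ifelse(post == 1L, "no_crowd", "crowd"),
      home_team = h$team, away_team = a$team,
      home_goals = h$goals, away_goals = a$goals,
      stringsAsFactors = FALSE)
    for (k in .count_indicators) {
      df[[paste0("home_", k)]] <- h$counts[[k]]
      df[[paste0("away_", k)]] <- a$counts[[k]]
    }
    df$home_rating <- h$rating; df$away_rating <- a$rating
    df$home_importance <- h$importance; df$away_importance <- a$importance
    df$home_latent_tp <- h$tp; df$home_latent_rd <- h$rd; df$home_latent_out <- h$out
    df$away_latent_tp <- a$tp; df$away_latent_rd <- a$rd; df$away_latent_out <- a$out
    match_counter <- match_counter + n_m
    all[[li]] <- df
  }
  res <- do.call(rbind, all)
  rownames(res) <- NULL
  # enforce shots_on_target <= shots (rounding noise can violate it)
  res$home_shots_on_target <- pmin(res$home_shots_on_target, res$home_shots)
  res$away_shots_on_target <- pmin(res$away_shots_on_target, res$away_shots)
  class(res) <- c("match_table", "data.frame")
  attr(res, "seed") <- config$seed
  attr(res, "config") <- config
  res
}

#' Closed-form effects implied by a set of structural parameters
#'
#' Analytic composition of the mediation quantities implied by a
#' [structural_params()] object: the two simple indirect effects on the
#' outcome (`a1*b1` via team performance, `a2*b2` via refereeing), the serial
#' three-path effect (`a1*d*b2`), the indirect effect on refereeing
#' (`a1*d`), the total effect on refereeing (`a2 + a1*d`), the direct effect
#' `c` and the total effect on the outcome, per period, together with their
#' reductions (`pre - post`).
#'
#' This is an independent expansion kept deliberately separate from
#' [compose_effects()] so that the two routes can check each other.
#'
#' @param params A [structural_params()] object.
#' @param include_serial_in_total Whether the serial path is added to the
#'   total effect on the outcome (default `FALSE`; it is always reported
#'   separately).
#' @return A `data.frame` with columns `quantity`, `period`
#'   (`pre`/`post`/`delta`) and `estimate`.
#' @export
#' @examples
#' g <- ground_truth_effects(structural_params())
#' subset(g, quantity == "total_on_referee")
ground_truth_effects <- function(params, include_serial_in_total = FALSE) {
  if (!inherits(params, "structural_params"))
    stop("ground_truth_effects: params must be structural_params", call. = FALSE)
  one <- function(s) {
    a1 <- params[[paste0("a1_", s)]]; a2 <- params[[paste0("a2_", s)]]
    d <- params[[paste0("d_", s)]]; b1 <- params[[paste0("b1_", s)]]
    b2 <- params[[paste0("b2_", s)]]; cc <- params[[paste0("c_", s)]]
    tot <- cc + a1 * b1 + a2 * b2 + if (include_serial_in_total) a1 * d * b2 else 0
    c(indirect_via_TP = a1 * b1,
      indirect_via_RD = a2 * b2,
      serial_indirect = a1 * d * b2,
      direct = cc,
      total_on_outcome = tot,
      indirect_on_referee_via_TP = a1 * d,
      total_on_referee = a2 + a1 * d)
  }
  pre <- one("pre"); post <- one("post")
  data.frame(
    quantity = rep(names(pre), 3L),
    period = rep(c("pre", "post", "delta"), each = length(pre)),
    estimate = c(pre, post, pre - post),
    row.names = NULL, stringsAsFactors = FALSE)
}
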