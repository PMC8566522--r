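#' Home-advantage summary by period
#'
#' Per-game home and away means of a metric, with standard errors
#' (sample SD / sqrt(n)), per crowd period and optionally per league, and
#' the home-minus-away difference: the descriptive home advantage.
#'
#' @param team_games A `team_game_table` from [to_game_pairs()].
#' @param metric Column to summarize (default `"points"`).
#' @param by_league Also return one summary per league (default `FALSE`,
#'   overall only).
#' @return Data.frame with columns `scope`, `metric`, `period`,
#'   `home_mean`, `away_mean`, `difference`, `home_se`, `away_se`,
#'   `n_games`. Empty cells are absent.
#' @export
#' @examples
#' m <- simulate_matches(simulation_config(n_leagues = 2, teams_per_league = 6))
#' ha_summary(to_game_pairs(m), "points")
ha_summary <- function(team_games, metric = "points", by_league = FALSE) {
  df <- as.data.frame(team_games)
  if (!metric %in% names(df))
    stop("ha_summary: unknown metric '", metric, "'", call. = FALSE)
  scopes <- if (by_league) split(df, df$league_id) else list(overall = df)
  rows <- lapply(names(scopes), function(sc) {
    d <- scopes[[sc]]
    per <- lapply(intersect(c("crowd", "no_crowd"), unique(d$period)),
                  function(p) {
      h <- d[[metric]][d$period == p & d$venue == "home"]
      a <- d[[metric]][d$period == p & d$venue == "away"]
      if (!length(h) || !length(a)) return(NULL)
      data.frame(scope = sc, metric = metric, period = p,
                 home_mean = mean(h), away_mean = mean(a),
                 difference = mean(h) - mean(a),
                 home_se = stats::sd(h) / sqrt(length(h)),
                 away_se = stats::sd(a) / sqrt(length(a)),
                 n_games = length(h),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("ha_summary", "data.frame")
  res
}

#' Percentage reduction from a crowd-period to a no-crowd value
#'
#' `(pre - post) / pre * 100`; for reporting the convention of the
#' descriptive analysis is 0 decimal places.
#'
#' @param pre_value Crowd-period value (non-zero).
#' @param post_value No-crowd value.
#' @return Percentage (full precision; round for display).
#' @export
#' @examples
#' round(percent_reduction(0.39, 0.23))  # 41
percent_reduction <- function(pre_value, post_value) {
  if (any(pre_value == 0))
    stop("percent_reduction: undefined for pre_value = 0", call. = FALSE)
  (pre_value - post_value) / pre_value * 100
}

#' Signed period change of a descriptive quantity
#'
#' `post - pre`: the signed drop (negative when the quantity fell without
#' crowds), the convention used when quoting changes such as the drop in the
#' home-advantage in points or goals.
#'
#' @param pre_value,post_value Crowd and no-crowd period values.
#' @return `post_value - pre_value`.
#' @export
#' @examples
#' ha_period_change(0.39, 0.23)  # -0.16
ha_period_change <- function(pre_value, post_value) post_value - pre_value

#' Change in the home-minus-away advantage from per-side changes
#'
#' Given the post-minus-pre change of a metric for home teams and for away
#' teams, returns the reduction in the home-minus-away advantage,
#' `away_change - home_change` (equivalently pre-advantage minus
#' post-advantage). Positive values mean the home advantage in that metric
#' shrank when crowds were absent.
#'
#' @param home_change,away_change Signed post-minus-pre per-side changes.
#' @return Reduction in the advantage (positive = advantage shrank).
#' @export
#' @examples
#' advantage_change(-1.32, 0.15)  # 1.47
advantage_change <- function(home_change, away_change) {
  away_change - home_change
}

#' Bar plot of a home-advantage summary
#'
#' Base-graphics venue x period bar chart with +/- 1 SE whiskers.
#'
#' @param summary One scope of a [ha_summary()] result.
#' @param main Plot title.
#' @return Invisibly, the bar midpoints.
#' @export
plot_ha_summary <- function(summary, main = summary$metric[1]) {
  s <- as.data.frame(summary)
  hts <- rbind(s$home_mean, s$away_mean)
  colnames(hts) <- s$period
  mid <- graphics::barplot(hts, beside = TRUE, main = main,
                           legend.text = c("home", "away"),
                           ylim = range(0, hts + 2 * rbind(s$home_se, s$away_se)))
  se <- rbind(s$home_se, s$away_se)
  graphics::arrows(mid, hts - se, mid, hts + se, angle = 90, code = 3,
                   length = 0.04)
  invisible(mid)
}
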