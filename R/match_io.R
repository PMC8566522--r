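#' Canonical match-table schema
#'
#' Column names of the canonical one-row-per-match CSV used throughout the
#' package. Side-specific columns carry `home_` / `away_` prefixes. Extra
#' columns (for example the generator's hidden `*_latent_*` ground-truth
#' columns) are tolerated on read and preserved.
#'
#' @return Character vector of mandatory column names.
#' @export
canonical_match_columns <- function() {
  side <- c("goals", .count_indicators, "rating", "importance")
  c("league_id", "match_id", "round", "period",
    "home_team", "away_team",
    paste0("home_", side), paste0("away_", side))
}

.model_indicator_columns <- function() {
  side <- c("goals", .count_indicators, "rating", "importance")
  c(paste0("home_", side), paste0("away_", side))
}

.validate_matches <- function(df, where = "match table") {
  missing <- setdiff(canonical_match_columns(), names(df))
  if (length(missing))
    stop(where, ": missing mandatory columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad_period <- !df$period %in% c("crowd", "no_crowd")
  if (any(bad_period))
    stop(where, ": unparseable period value(s): ",
         paste(utils::head(unique(df$period[bad_period]), 5), collapse = ", "),
         call. = FALSE)
  if (any(df$home_team == df$away_team))
    stop(where, ": a team cannot play itself", call. = FALSE)
  cnt <- c(paste0("home_", c("goals", .count_indicators)),
           paste0("away_", c("goals", .count_indicators)))
  for (k in cnt) if (any(df[[k]] < 0, na.rm = TRUE))
    stop(where, ": negative count in column ", k, call. = FALSE)
  if (any(df$home_shots_on_target > df$home_shots, na.rm = TRUE) ||
      any(df$away_shots_on_target > df$away_shots, na.rm = TRUE))
    stop(where, ": shots_on_target exceeds shots", call. = FALSE)
  invisible(df)
}

#' Read a canonical match CSV
#'
#' Reads and validates a one-row-per-match table. `pre`/`post` period labels
#' are accepted as aliases for `crowd`/`no_crowd`. Rows with missing values
#' in any model indicator column are dropped listwise, with the count of
#' deletions reported via `message()`.
#'
#' @param path Path to a CSV file with the [canonical_match_columns()] header.
#' @return A validated `match_table` data.frame.
#' @export
read_matches <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(canonical_match_columns(), names(df))
  if (length(missing))
    stop("read_matches: missing mandatory columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$period[df$period == "pre"] <- "crowd"
  df$period[df$period == "post"] <- "no_crowd"
  ind <- .model_indicator_columns()
  complete <- stats::complete.cases(df[ind])
  if (any(!complete)) {
    message("read_matches: dropped ", sum(!complete),
            " row(s) with missing model indicators (listwise deletion)")
    df <- df[complete, , drop = FALSE]
  }
  .validate_matches(df, "read_matches")
  rownames(df) <- NULL
  class(df) <- c("match_table", "data.frame")
  df
}

#' Write a canonical match CSV
#'
#' @param matches A `match_table` data.frame.
#' @param path Output path.
#' @param include_truth Keep the generator's hidden `*_latent_*` ground-truth
#'   columns (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path, include_truth = FALSE) {
  df <- as.data.frame(matches)
  if (!include_truth)
    df <- df[!grepl("_latent_", names(df))]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' League points implied by a scoreline
#'
#' Standard association-football scoring: 3 points for a win, 1 for a draw,
#' 0 for a loss. Vectorized.
#'
#' @param goals_for,goals_against Non-negative goal counts.
#' @return Integer vector of points in `{0, 1, 3}`.
#' @export
#' @examples
#' derive_points(c(2, 1, 0), c(1, 1, 3))
derive_points <- function(goals_for, goals_against) {
  if (any(goals_for < 0) || any(goals_against < 0))
    stop("derive_points: goal counts must be non-negative", call. = FALSE)
  ifelse(goals_for > goals_against, 3L,
         ifelse(goals_for == goals_against, 1L, 0L))
}

#' Expand matches into the game-pairs representation
#'
#' Each match contributes two rows, one per team, with a `venue` factor and
#' the opponent's covariates attached. This is the granularity at which the
#' latent constructs are scored and, after aggregation, modelled.
#'
#' @param matches A validated `match_table`.
#' @return A `team_game_table` data.frame with exactly `2 * nrow(matches)`
#'   rows. Ground-truth latent columns, when present, are carried along as
#'   `latent_tp`, `latent_rd`, `latent_out`.
#' @export
to_game_pairs <- function(matches) {
  .validate_matches(matches, "to_game_pairs")
  df <- as.data.frame(matches)
  side_cols <- c(.count_indicators, "rating", "importance")
  one <- function(venue) {
    me <- if (venue == "home") "home_" else "away_"
    op <- if (venue == "home") "away_" else "home_"
    out <- data.frame(
      team_id = df[[paste0(me, "team")]],
      opponent_id = df[[paste0(op, "team")]],
      league_id = df$league_id,
      match_id = df$match_id,
      round = df$round,
      period = df$period,
      venue = venue,
      goals_for = df[[paste0(me, "goals")]],
      goals_against = df[[paste0(op, "goals")]],
      stringsAsFactors = FALSE)
    for (k in side_cols) out[[k]] <- df[[paste0(me, k)]]
    out$opp_rating <- df[[paste0(op, "rating")]]
    out$opp_importance <- df[[paste0(op, "importance")]]
    for (k in c("tp", "rd", "out")) {
      col <- paste0(me, "latent_", k)
      if (col %in% names(df)) out[[paste0("latent_", k)]] <- df[[col]]
    }
    out
  }
  res <- rbind(one("home"), one("away"))
  res$points <- derive_points(res$goals_for, res$goals_against)
  res <- res[order(res$match_id, res$venue == "home", decreasing = FALSE), ]
  rownames(res) <- NULL
  class(res) <- c("team_game_table", "data.frame")
  res
}

#' Aggregate team-game rows to team x venue x period cells
#'
#' Unweighted per-game means of every indicator within each
#' team x venue x period cell present in the data, the granularity of the
#' main (aggregated) model variant. Cells absent from the data are absent
#' from the output.
#'
#' @param team_games A `team_game_table` from [to_game_pairs()].
#' @return An `aggregate_table` data.frame with one row per populated cell,
#'   mean columns named as in the input, and `n_games`.
#' @export
aggregate_team_venue_period <- function(team_games) {
  df <- as.data.frame(team_games)
  if (nrow(df) == 0L) {
    out <- df[c("team_id", "league_id", "venue", "period")]
    out$n_games <- integer(0)
    class(out) <- c("aggregate_table", "data.frame")
    return(out)
  }
  num_cols <- intersect(
    c("points", "goals_for", "goals_against", .count_indicators,
      "rating", "importance", "opp_rating", "opp_importance",
      "latent_tp", "latent_rd", "latent_out"),
    names(df))
  key <- interaction(df$team_id, df$venue, df$period, drop = TRUE)
  idx <- split(seq_len(nrow(df)), key)
  rows <- lapply(idx, function(i) {
    cell <- df[i, , drop = FALSE]
    out <- data.frame(team_id = cell$team_id[1],
                      league_id = cell$league_id[1],
                      venue = cell$venue[1],
                      period = cell$period[1],
                      n_games = length(i),
                      stringsAsFactors = FALSE)
    for (k in num_cols) out[[k]] <- mean(cell[[k]])
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$team_id, res$venue, res$period), ]
  rownames(res) <- NULL
  class(res) <- c("aggregate_table", "data.frame")
  res
}

#' Assign crowd periods by a round threshold
#'
#' Helper for data where the crowd/no-crowd split is known only as a cutoff
#' round per league rather than an explicit column.
#'
#' @param matches A `match_table`.
#' @param cutoff Named vector (by league) or scalar: first round played
#'   without crowds.
#' @return The table with its `period` column re-derived.
#' @export
assign_period_by_round <- function(matches, cutoff) {
  df <- as.data.frame(matches)
  cut <- if (is.null(names(cutoff))) rep(cutoff[1], nrow(df)) else {
    if (!all(df$league_id %in% names(cutoff)))
      stop("assign_period_by_round: cutoff missing for some leagues",
           call. = FALSE)
    unname(cutoff[df$league_id])
  }
  df$period <- ifelse(df$round >= cut, "no_crowd", "crowd")
  class(df) <- c("match_table", "data.frame")
  df
}
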