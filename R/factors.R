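#' Indicator sets of the three latent constructs
#'
#' @return Named list mapping construct name (`performance`, `referee`,
#'   `outcome`) to its indicator columns.
#' @export
construct_indicators <- function() {
  list(performance = .performance_indicators,
       referee = .referee_indicators,
       outcome = .outcome_indicators)
}

# Iterative principal-axis fallback for when the ML fit fails to converge.
.principal_axis <- function(R, max_iter = 200, tol = 1e-8) {
  h <- 1 - 1 / diag(solve(R))  # squared multiple correlations
  for (i in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h
    e <- eigen(Rr, symmetric = TRUE)
    l <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
    h_new <- pmin(l^2, 0.995)
    if (max(abs(h_new - h)) < tol) break
    h <- h_new
  }
  l
}

#' Fit a single-factor model to a set of indicators
#'
#' Indicators are z-scored, a one-factor model is extracted (maximum
#' likelihood via [stats::factanal()] for three or more indicators, with an
#' iterative principal-axis fallback if the ML fit fails; the first principal
#' component of the z-scored pair for exactly two indicators, which is not
#' ML-identifiable), and the solution is sign-oriented so the mean loading is
#' positive. Factor scores use the regression (Thomson) method and are
#' re-standardized to mean 0, SD 1 on the training rows.
#'
#' @param rows A data.frame containing the indicator columns.
#' @param indicators Character vector of at least two column names.
#' @param construct Optional label stored in the model.
#' @return An object of class `factor_model` with elements `loadings`,
#'   `uniquenesses`, `variance_explained` (mean squared loading),
#'   `score_weights`, and the standardization used (`center`, `scale`,
#'   `score_center`, `score_scale`).
#' @export
#' @examples
#' m <- simulate_matches(simulation_config(n_leagues = 2, teams_per_league = 6))
#' tg <- to_game_pairs(m)
#' fm <- fit_single_factor(tg, c("corners", "shots", "shots_on_target"))
#' fm$variance_explained
fit_single_factor <- function(rows, indicators, construct = NULL) {
  if (length(indicators) < 2L)
    stop("fit_single_factor: need at least 2 indicators", call. = FALSE)
  if (!all(indicators %in% names(rows)))
    stop("fit_single_factor: missing indicator column(s): ",
         paste(setdiff(indicators, names(rows)), collapse = ", "),
         call. = FALSE)
  X <- as.matrix(rows[indicators])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L)
    stop("fit_single_factor: need at least 3 complete rows", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv < 1e-12))
    stop("fit_single_factor: constant indicator(s): ",
         paste(indicators[sdv < 1e-12], collapse = ", "), call. = FALSE)
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  R <- stats::cor(Z)
  pc_weights <- NULL
  if (length(indicators) == 2L) {
    e <- eigen(R, symmetric = TRUE)
    loadings <- e$vectors[, 1] * sqrt(e$values[1])
    pc_weights <- e$vectors[, 1]   # PC scores; robust when |r| = 1
  } else {
    fa <- tryCatch(
      stats::factanal(covmat = R, factors = 1, n.obs = nrow(X)),
      error = function(e) NULL)
    loadings <- if (is.null(fa)) {
      warning("fit_single_factor: ML fit failed; using principal-axis fallback")
      .principal_axis(R)
    } else as.numeric(fa$loadings[, 1])
  }
  if (mean(loadings) < 0) loadings <- -loadings
  names(loadings) <- indicators
  loadings <- pmin(pmax(loadings, -1), 1)
  # regression (Thomson) score weights on the z-scored indicators;
  # the 2-indicator principal component uses its eigenvector directly
  w <- if (!is.null(pc_weights)) {
    if (mean(pc_weights) < 0) -pc_weights else pc_weights
  } else solve(R, loadings)
  raw <- drop(Z %*% w)
  model <- structure(list(
    construct = construct %||% paste(indicators, collapse = "+"),
    indicators = indicators,
    loadings = loadings,
    uniquenesses = stats::setNames(1 - loadings^2, indicators),
    variance_explained = mean(loadings^2),
    score_weights = stats::setNames(as.numeric(w), indicators),
    center = mu, scale = sdv,
    score_center = mean(raw),
    score_scale = stats::sd(raw)),
    class = "factor_model")
  if (model$score_scale < 1e-12)
    stop("fit_single_factor: degenerate factor (zero score variance)",
         call. = FALSE)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score rows with a fitted factor model
#'
#' New rows are z-scored with the model's stored standardization, combined
#' with the stored regression weights, and shifted/scaled by the training
#' score moments, so training rows score to mean 0, SD 1 exactly.
#'
#' @param model A `factor_model`.
#' @param rows Data.frame containing the model's indicator columns.
#' @return Numeric vector of standardized factor scores.
#' @export
score_factor <- function(model, rows) {
  if (!inherits(model, "factor_model"))
    stop("score_factor: model must be a factor_model", call. = FALSE)
  miss <- setdiff(model$indicators, names(rows))
  if (length(miss))
    stop("score_factor: rows are missing indicator(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(rows[model$indicators])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  (drop(Z %*% model$score_weights) - model$score_center) / model$score_scale
}

#' Fit and attach all three latent construct scores
#'
#' Fits one single-factor model per construct (team performance from
#' corners/shots/shots on target; refereeing decisions from
#' fouls/yellows/reds; outcome from points/goals) on the supplied rows,
#' pooled across leagues, and appends the standardized scores as columns
#' `tp`, `rd`, `out`.
#'
#' @param rows A `team_game_table` or `aggregate_table` (any data.frame with
#'   the indicator columns).
#' @return A list with `data` (rows plus score columns) and `models` (named
#'   list of `factor_model` objects).
#' @export
build_latents <- function(rows) {
  sets <- construct_indicators()
  models <- list(
    performance = fit_single_factor(rows, sets$performance, "performance"),
    referee = fit_single_factor(rows, sets$referee, "referee"),
    outcome = fit_single_factor(rows, sets$outcome, "outcome"))
  out <- as.data.frame(rows)
  out$tp <- score_factor(models$performance, rows)
  out$rd <- score_factor(models$referee, rows)
  out$out <- score_factor(models$outcome, rows)
  list(data = out, models = models)
}

#' Serialize a factor model to JSON
#'
#' @param model A `factor_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
factor_model_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Restore a factor model from JSON
#'
#' @param json JSON string or path to a file produced by
#'   [factor_model_to_json()].
#' @return A `factor_model`.
#' @export
factor_model_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  x <- jsonlite::fromJSON(paste(json, collapse = ""))
  for (k in c("loadings", "uniquenesses", "score_weights", "center", "scale"))
    x[[k]] <- stats::setNames(as.numeric(x[[k]]), x$indicators)
  structure(x, class = "factor_model")
}
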