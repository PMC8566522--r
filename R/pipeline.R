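#' Run the full analysis pipeline on a match table
#'
#' Game-pairs expansion, (optional) team x venue x period aggregation,
#' latent-construct scoring, path-model fit and effect composition — the end
#' to end analysis applied to one match table.
#'
#' @param matches A `match_table`.
#' @param spec A [ham_model_spec()]; `granularity` selects between the main
#'   aggregated analysis and the per-game variant.
#' @param settings An [estimation_settings()].
#' @param include_serial_in_total Passed to [compose_effects()].
#' @return A list of class `ham_pipeline`: `data` (analysis rows with latent
#'   scores), `factors` (the three `factor_model`s), `fit` (`ham_draws`),
#'   `effects` (`effect_report`), `r2` (per-equation Bayesian R-squared).
#' @export
ham_pipeline <- function(matches, spec = ham_model_spec(),
                         settings = estimation_settings(),
                         include_serial_in_total = FALSE) {
  tg <- to_game_pairs(matches)
  rows <- if (spec$granularity == "team_aggregate")
    aggregate_team_venue_period(tg) else tg
  lat <- build_latents(rows)
  fit <- fit_ham(lat$data, spec, settings)
  structure(list(data = lat$data, factors = lat$models, fit = fit,
                 effects = compose_effects(fit, include_serial_in_total),
                 r2 = bayes_r2(fit)),
            class = "ham_pipeline")
}
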