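# REML mixed-model point fit of the three equations (lme4) — the
# non-Bayesian analog of the model, used as an independent oracle for the
# population projection of the structural paths onto the score metric.
.lmer_path_fit <- function(dat) {
  d <- data.frame(tp = dat$tp, rd = dat$rd, out = dat$out,
                  v = .as01(dat$venue, "home", "away", "venue"),
                  p = .as01(dat$period, "no_crowd", "crowd", "period"),
                  zr = as.numeric(scale(dat$rating)),
                  zi = as.numeric(scale(dat$importance)),
                  team = dat$team_id, league = dat$league_id)
  ctl <- lme4::lmerControl(check.conv.singular = "ignore",
                           check.conv.grad = "ignore",
                           check.conv.hess = "ignore")
  fit <- function(f) suppressWarnings(suppressMessages(
    lme4::lmer(f, data = d, REML = TRUE, control = ctl)))
  pull <- function(fit, nm) {
    co <- lme4::fixef(fit)
    inter <- co[paste0(nm, ":p")]
    if (is.na(inter)) inter <- co[paste0("p:", nm)]
    c(pre = unname(co[nm]), post = unname(co[nm] + inter))
  }
  f1 <- fit(tp ~ v * p + zr * p + zi * p + (1 | team) + (1 | league))
  f2 <- fit(rd ~ v * p + tp * p + zr * p + zi * p + (1 | team) + (1 | league))
  f3 <- fit(out ~ v * p + tp * p + rd * p + zr * p + zi * p +
              (1 | team) + (1 | league))
  c(a1_pre = pull(f1, "v")[[1]], a1_post = pull(f1, "v")[[2]],
    a2_pre = pull(f2, "v")[[1]], a2_post = pull(f2, "v")[[2]],
    d_pre = pull(f2, "tp")[[1]], d_post = pull(f2, "tp")[[2]],
    b1_pre = pull(f3, "tp")[[1]], b1_post = pull(f3, "tp")[[2]],
    b2_pre = pull(f3, "rd")[[1]], b2_post = pull(f3, "rd")[[2]],
    c_pre = pull(f3, "v")[[1]], c_post = pull(f3, "v")[[2]])
}

#' Population projection of the structural paths onto the score metric
#'
#' Factor scores are standardized on the analysis rows, and the count /
#' points / goals measurement layer is mildly non-linear, so the
#' coefficients the model estimates live on the score metric, not on the
#' generator's latent metric. This oracle computes where the generative
#' paths land on that metric: it simulates `n_oracle` independent datasets
#' from `config`, scores them through the identical pipeline, fits each
#' equation by REML ([lme4::lmer()] — the non-Bayesian analog, independent
#' of the package's own sampler), and averages the path estimates.
#'
#' @param config A [simulation_config()].
#' @param spec A [ham_model_spec()].
#' @param n_oracle Number of independent oracle datasets.
#' @param seed Base seed for the oracle simulations.
#' @return Named numeric vector of effective path values
#'   (`a1_pre`, ..., `c_post`).
#' @export
score_metric_truths <- function(config, spec = ham_model_spec(),
                                n_oracle = 6L, seed = 777L) {
  acc <- NULL
  for (i in seq_len(n_oracle)) {
    cfg <- config
    cfg$seed <- as.integer(seed + 131L * i)
    tg <- to_game_pairs(simulate_matches(cfg))
    rows <- if (spec$granularity == "team_aggregate")
      aggregate_team_venue_period(tg) else tg
    est <- .lmer_path_fit(build_latents(rows)$data)
    acc <- if (is.null(acc)) est else acc + est
  }
  acc / n_oracle
}

#' Seeded parameter-recovery harness
#'
#' Simulates data with known structural parameters, runs the full pipeline,
#' and checks per replicate whether each true path lies inside its credible
#' interval and whether the sign of each non-zero true reduction
#' (`pre - post`) is recovered by the posterior median.
#'
#' Coverage is assessed against the paths' population projection on the
#' score metric ([score_metric_truths()]), computed once from independent
#' oracle datasets; delta signs are assessed against the raw generative
#' deltas (projection preserves signs). Set `project_truth = FALSE` to
#' compare directly against the latent-metric values (appropriate under the
#' global null, where the projection is exactly zero).
#'
#' @param config A [simulation_config()] (its `seed` is overridden per
#'   replicate).
#' @param spec A [ham_model_spec()].
#' @param settings An [estimation_settings()].
#' @param n_reps Number of seeded replicates.
#' @param seed Base seed; replicate r uses `seed + 1000 * r`.
#' @param project_truth Compute effective truths with
#'   [score_metric_truths()] (default) or use the raw parameter values.
#' @param n_oracle Oracle datasets for the projection.
#' @return A list of class `recovery_report`: `coverage` (one row per path:
#'   effective truth, mean posterior median, coverage fraction),
#'   `delta_signs` (per non-zero true delta, the fraction of replicates
#'   whose posterior median delta has the true sign), and `replicates`
#'   (per-replicate detail).
#' @export
recovery_harness <- function(config = simulation_config(),
                             spec = ham_model_spec(),
                             settings = estimation_settings(),
                             n_reps = 20L, seed = 1L,
                             project_truth = TRUE, n_oracle = 6L) {
  p <- config$true_paths
  paths <- c("a1", "a2", "d", "b1", "b2", "c")
  path_cols <- paste0(rep(paths, each = 2), c("_pre", "_post"))
  truths <- if (project_truth)
    score_metric_truths(config, spec, n_oracle, seed = seed + 500000L)
  else
    vapply(path_cols, function(pc) p[[pc]], numeric(1))
  lv <- settings$interval_level
  a <- (1 - lv) / 2
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + 1000L * r)
    st <- settings
    st$seed <- cfg$seed
    tg <- to_game_pairs(simulate_matches(cfg))
    rows <- if (spec$granularity == "team_aggregate")
      aggregate_team_venue_period(tg) else tg
    lat <- build_latents(rows)
    fit <- suppressWarnings(fit_ham(lat$data, spec, st))
    detail <- do.call(rbind, lapply(path_cols, function(pc) {
      dr <- fit$draws[[pc]]
      data.frame(rep = r, path = pc, truth = unname(truths[[pc]]),
                 estimate = stats::median(dr),
                 lower = unname(stats::quantile(dr, a)),
                 upper = unname(stats::quantile(dr, 1 - a)),
                 stringsAsFactors = FALSE)
    }))
    detail$covered <- detail$truth >= detail$lower & detail$truth <= detail$upper
    deltas <- do.call(rbind, lapply(paths, function(pp) {
      true_delta <- p[[paste0(pp, "_pre")]] - p[[paste0(pp, "_post")]]
      est_delta <- stats::median(fit$draws[[paste0(pp, "_pre")]] -
                                   fit$draws[[paste0(pp, "_post")]])
      data.frame(rep = r, path = pp, true_delta = true_delta,
                 est_delta = est_delta,
                 sign_ok = sign(true_delta) == sign(est_delta),
                 stringsAsFactors = FALSE)
    }))
    reps[[r]] <- list(detail = detail, deltas = deltas)
  }
  detail <- do.call(rbind, lapply(reps, `[[`, "detail"))
  deltas <- do.call(rbind, lapply(reps, `[[`, "deltas"))
  coverage <- do.call(rbind, lapply(split(detail, detail$path), function(d)
    data.frame(path = d$path[1], truth = d$truth[1],
               mean_estimate = mean(d$estimate),
               coverage = mean(d$covered), stringsAsFactors = FALSE)))
  coverage <- coverage[match(path_cols, coverage$path), ]
  rownames(coverage) <- NULL
  nz <- deltas[deltas$true_delta != 0, ]
  delta_signs <- if (nrow(nz)) do.call(rbind, lapply(split(nz, nz$path),
    function(d) data.frame(path = d$path[1], true_delta = d$true_delta[1],
                           sign_rate = mean(d$sign_ok),
                           stringsAsFactors = FALSE))) else
    data.frame(path = character(0), true_delta = numeric(0),
               sign_rate = numeric(0))
  rownames(delta_signs) <- NULL
  structure(list(coverage = coverage, delta_signs = delta_signs,
                 replicates = list(detail = detail, deltas = deltas),
                 n_reps = n_reps, seed = seed),
            class = "recovery_report")
}

#' Null-calibration harness
#'
#' Simulates under the global null (all structural paths and control
#' coefficients zero) and records, per path, the fraction of replicates
#' whose credible interval covers zero. Under the null the score-metric
#' projection of every path is exactly zero, so no oracle is needed.
#'
#' @param config A [simulation_config()]; its `true_paths` are replaced by
#'   [null_structural_params()].
#' @param spec,settings,n_reps,seed As in [recovery_harness()].
#' @return Data.frame with one row per path: `coverage_of_zero`.
#' @export
null_calibration <- function(config = simulation_config(),
                             spec = ham_model_spec(),
                             settings = estimation_settings(),
                             n_reps = 40L, seed = 1L) {
  config$true_paths <- null_structural_params()
  rec <- recovery_harness(config, spec, settings, n_reps, seed,
                          project_truth = FALSE)
  d <- rec$replicates$detail
  cov0 <- do.call(rbind, lapply(split(d, d$path), function(x)
    data.frame(path = x$path[1],
               coverage_of_zero = mean(x$lower <= 0 & x$upper >= 0),
               stringsAsFactors = FALSE)))
  rownames(cov0) <- NULL
  cov0
}
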