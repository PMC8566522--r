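# Construct a small analysis table directly (latents + design columns),
# bypassing the indicator/measurement layer, so model behavior can be
# checked against known linear structure.
make_analysis_data <- function(n_leagues = 3, teams_per_league = 8,
                               rows_per_cell = 2, seed = 1,
                               a1 = 0.8, d = -0.2, b1 = 0.3, b2 = -0.1,
                               cc = 0.25, sd_res = 0.5, team_sd = 0.3) {
  set.seed(seed)
  grid <- expand.grid(team = seq_len(n_leagues * teams_per_league),
                      venue = c(0, 1), post = c(0, 1),
                      rep = seq_len(rows_per_cell))
  league <- ((grid$team - 1) %/% teams_per_league) + 1
  u <- rnorm(n_leagues * teams_per_league, 0, team_sd)
  tp <- a1 * grid$venue + u[grid$team] + rnorm(nrow(grid), 0, sd_res)
  rd <- -0.3 * grid$venue + d * tp + rnorm(nrow(grid), 0, sd_res)
  out <- cc * grid$venue + b1 * tp + b2 * rd + rnorm(nrow(grid), 0, sd_res)
  data.frame(tp = tp, rd = rd, out = out, venue = grid$venue,
             period = grid$post, rating = rnorm(nrow(grid)),
             importance = runif(nrow(grid), 0, 100),
             team_id = paste0("T", grid$team),
             league_id = paste0("L", league))
}

test_that("fits are deterministic under a fixed seed and input checks fire", {
  d <- make_analysis_data()
  f1 <- fit_ham(d, settings = fast_settings(seed = 3))
  f2 <- fit_ham(d, settings = fast_settings(seed = 3))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_ham(d, settings = fast_settings(seed = 4))
  expect_false(identical(f1$draws$a1_pre, f3$draws$a1_pre))
  expect_error(fit_ham(d[, -1]), "missing column")
  d0 <- d; d0$out <- 1
  expect_error(fit_ham(d0, settings = fast_settings()), "zero variance")
  expect_output(print(f1), "engine: mcmc")
})

test_that("per-period coefficients are base plus interaction, exactly", {
  d <- make_analysis_data(seed = 2)
  fit <- fit_ham(d, settings = fast_settings(seed = 5))
  b <- fit$equations$perf$beta
  expect_equal(fit$draws$a1_pre, unname(b[, "venue"]))
  expect_equal(fit$draws$a1_post,
               unname(b[, "venue"] + b[, "venue_post"]))
  b3 <- fit$equations$out$beta
  expect_equal(fit$draws$b2_post, unname(b3[, "rd"] + b3[, "rd_post"]))
  # diagnostics cover every path and are finite
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$ess > 50))
})

test_that("the model recovers known linear structure on clean latents", {
  d <- make_analysis_data(n_leagues = 4, teams_per_league = 10,
                          rows_per_cell = 4, seed = 7)
  fit <- fit_ham(d, settings = fast_settings(seed = 8))
  expect_equal(median(fit$draws$a1_pre), 0.8, tolerance = 0.12)
  expect_equal(median(fit$draws$d_pre), -0.2, tolerance = 0.12)
  expect_equal(median(fit$draws$b1_pre), 0.3, tolerance = 0.12)
  expect_equal(median(fit$draws$c_pre), 0.25, tolerance = 0.12)
})

test_that("rescaling the latent scores rescales paths as dictated", {
  d <- make_analysis_data(n_leagues = 4, teams_per_league = 10,
                          rows_per_cell = 4, seed = 9)
  fit1 <- fit_ham(d, settings = fast_settings(seed = 10))
  d2 <- d
  k <- 2
  d2$tp <- k * d2$tp; d2$rd <- k * d2$rd; d2$out <- k * d2$out
  fit2 <- fit_ham(d2, settings = fast_settings(seed = 10))
  # venue -> latent paths scale by k; latent -> latent paths are invariant
  expect_equal(median(fit2$draws$a1_pre), k * median(fit1$draws$a1_pre),
               tolerance = 0.05)
  expect_equal(median(fit2$draws$c_pre), k * median(fit1$draws$c_pre),
               tolerance = 0.05)
  expect_equal(median(fit2$draws$d_pre), median(fit1$draws$d_pre),
               tolerance = 0.05)
  expect_equal(median(fit2$draws$b1_pre), median(fit1$draws$b1_pre),
               tolerance = 0.05)
})

test_that("small team cells are shrunk toward the population (partial pooling)", {
  d <- make_analysis_data(n_leagues = 3, teams_per_league = 8,
                          rows_per_cell = 3, seed = 11, team_sd = 0.2)
  # give one team only two rows, with an extreme performance level
  d1 <- d[d$team_id != "T1" | seq_len(nrow(d)) %in%
            head(which(d$team_id == "T1"), 2), ]
  shift <- 3
  d1$tp[d1$team_id == "T1"] <- d1$tp[d1$team_id == "T1"] + shift
  fit <- fit_ham(d1, settings = fast_settings(seed = 12))
  co <- fit$equations$perf$coefs
  ucol <- grep("T1$", colnames(co), value = TRUE)
  expect_length(ucol, 1L)
  u_post <- mean(co[, ucol])
  # raw deviation of the two doped rows from the model's fixed-effect fit
  raw <- shift  # they were shifted by 3 beyond their generating structure
  expect_lt(abs(u_post), raw)
  expect_gt(u_post, 0.5)  # but clearly positive, not shrunk to nothing
})

test_that("single-league data drops the league term with a warning", {
  d <- make_analysis_data(n_leagues = 1, teams_per_league = 10, seed = 13)
  expect_warning(fit <- fit_ham(d, settings = fast_settings(seed = 14)),
                 "single league")
  expect_true(all(is.na(fit$draws$tau_league_perf)))
  expect_true(all(is.finite(fit$draws$tau_team_perf)))
})

test_that("bayes_r2 behaves at the extremes and matches recomputation", {
  # near-noiseless outcome -> R2 ~ 1
  d <- make_analysis_data(n_leagues = 3, teams_per_league = 8, seed = 15)
  d$out <- 0.5 * d$venue + 0.4 * d$tp - 0.2 * d$rd + 1e-4 * rnorm(nrow(d))
  fit <- fit_ham(d, settings = fast_settings(seed = 16))
  r2 <- bayes_r2(fit)
  expect_gt(r2$median[r2$equation == "out"], 0.98)

  # pure-noise outcome -> R2 near 0
  set.seed(17)
  d2 <- make_analysis_data(n_leagues = 4, teams_per_league = 16,
                           rows_per_cell = 2, seed = 17,
                           a1 = 0, d = 0, b1 = 0, b2 = 0, cc = 0,
                           team_sd = 0)
  expect_gte(nrow(d2), 500)
  fit2 <- fit_ham(d2, settings = fast_settings(seed = 18))
  r22 <- bayes_r2(fit2)
  expect_lt(r22$median[r22$equation == "out"], 0.1)

  # independent per-draw recomputation of the variance ratio
  f <- fit$equations$out
  idx <- c(1, 25, 100)
  r2_manual <- sapply(idx, function(i) {
    fitted <- drop(f$W %*% f$coefs[i, ])
    var(fitted) / (var(fitted) + f$sigma[i]^2)
  })
  all_r2 <- {
    fitted <- f$coefs %*% t(f$W)
    vf <- apply(fitted, 1, var)
    vf / (vf + f$sigma^2)
  }
  expect_equal(all_r2[idx], r2_manual, tolerance = 1e-10)
  expect_equal(bayes_r2(fit)$median[3], median(all_r2), tolerance = 1e-10)
})

test_that("the bootstrap engine mirrors the mcmc interface", {
  d <- make_analysis_data(n_leagues = 3, teams_per_league = 8, seed = 19)
  st <- suppressWarnings(estimation_settings(engine = "bootstrap",
                                             bootstrap_reps = 25, seed = 20))
  fit <- fit_ham(d, settings = st)
  expect_equal(nrow(fit$draws), 25L)
  expect_true(all(is.na(fit$diagnostics$rhat)))
  r <- compose_effects(fit)
  expect_s3_class(r, "effect_report")
  # the two engines must agree on the same data (within sampling error)
  mc <- fit_ham(d, settings = fast_settings(seed = 20))
  expect_equal(median(fit$draws$a1_pre), median(mc$draws$a1_pre),
               tolerance = 0.1)
  r2 <- bayes_r2(fit)
  expect_true(all(r2$median > 0 & r2$median < 1))
  fit2 <- fit_ham(d, settings = st)
  expect_identical(fit$draws, fit2$draws)
})

test_that("draw persistence and settings validation work", {
  d <- make_analysis_data(seed = 21)
  fit <- fit_ham(d, settings = fast_settings(seed = 22))
  f <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(fit$draws))
  expect_equal(back$a1_pre, fit$draws$a1_pre, tolerance = 1e-9)
  expect_warning(estimation_settings(chains = 1, draws_per_chain = 100),
                 "fewer than 500")
  expect_error(estimation_settings(interval_level = 0.4), "interval_level")
  expect_error(estimation_settings(chains = 0), "iteration counts")
})
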