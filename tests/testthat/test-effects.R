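# The closed-form expansion (ground_truth_effects) and the draw-wise
# composition (compose_effects) are independent routes; several tests here
# check one against the other.

test_that("published arithmetic identities are reproduced from point inputs", {
  p <- structural_params(a1_pre = 0.89, a1_post = 0.35,
                         a2_pre = -0.30, a2_post = 0.19,
                         d_pre = -0.14, d_post = -0.08)
  r <- compose_effects(path_point_draws(p))
  pick <- function(q, s) r$estimate[r$quantity == q & r$period == s]
  expect_equal(round(pick("total_on_referee", "pre"), 2), -0.42)
  expect_equal(round(pick("total_on_referee", "post"), 2), 0.16)
  expect_equal(round(pick("indirect_on_referee_via_TP", "pre"), 2), -0.12)
  expect_equal(round(pick("indirect_on_referee_via_TP", "post"), 2), -0.03)
})

test_that("zero paths null their composed effects exactly", {
  p <- structural_params(b1_pre = 0, b1_post = 0)
  r <- compose_effects(path_point_draws(p))
  iv <- r$estimate[r$quantity == "indirect_via_TP"]
  expect_identical(iv, c(0, 0, 0))
  # ground-truth route agrees exactly on any point input
  g <- ground_truth_effects(p)
  merged <- merge(as.data.frame(r), g, by = c("quantity", "period"))
  expect_equal(merged$estimate.x, merged$estimate.y, tolerance = 1e-14)
})

test_that("per-draw composition identities hold to 1e-12 on random draws", {
  set.seed(6)
  n <- 500
  draws <- as.data.frame(matrix(rnorm(12 * n), n, 12))
  names(draws) <- paste0(rep(c("a1", "a2", "d", "b1", "b2", "c"), each = 2),
                         c("_pre", "_post"))
  fit <- path_point_draws(structural_params())
  fit$draws <- draws
  r <- compose_effects(fit, include_serial_in_total = TRUE)
  # independent re-expansion, draw by draw, then summary
  for (s in c("pre", "post")) {
    tot <- draws[[paste0("c_", s)]] +
      draws[[paste0("a1_", s)]] * draws[[paste0("b1_", s)]] +
      draws[[paste0("a2_", s)]] * draws[[paste0("b2_", s)]] +
      draws[[paste0("a1_", s)]] * draws[[paste0("d_", s)]] *
        draws[[paste0("b2_", s)]]
    got <- r[r$quantity == "total_on_outcome" & r$period == s, ]
    expect_equal(got$estimate, median(tot), tolerance = 1e-12)
    expect_equal(got$lower, unname(quantile(tot, 0.025)), tolerance = 1e-12)
    ref <- draws[[paste0("a2_", s)]] + draws[[paste0("a1_", s)]] *
      draws[[paste0("d_", s)]]
    expect_equal(r$estimate[r$quantity == "total_on_referee" & r$period == s],
                 median(ref), tolerance = 1e-12)
  }
  # deltas are paired per draw, not differences of summaries
  tot_pre <- draws$c_pre + draws$a1_pre * draws$b1_pre +
    draws$a2_pre * draws$b2_pre + draws$a1_pre * draws$d_pre * draws$b2_pre
  tot_post <- draws$c_post + draws$a1_post * draws$b1_post +
    draws$a2_post * draws$b2_post +
    draws$a1_post * draws$d_post * draws$b2_post
  got <- r[r$quantity == "total_on_outcome" & r$period == "delta", ]
  expect_equal(got$estimate, median(tot_pre - tot_post), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(median(tot_pre - tot_post),
                                median(tot_pre) - median(tot_post))))
})

test_that("delta reproduces published reductions and trivial cases", {
  # printed mediation values as point inputs: via-referee indirect
  # 0.03 -> -0.01 gives a reduction of 0.04; totals 0.57 -> 0.36 give 0.21
  p <- structural_params(a1_pre = 0.26, a1_post = 0.12, b1_pre = 1,
                         b1_post = 1, a2_pre = 0.03, a2_post = -0.01,
                         b2_pre = 1, b2_post = 1, c_pre = 0.28,
                         c_post = 0.25, d_pre = 0, d_post = 0)
  fit <- path_point_draws(p)
  r <- compose_effects(fit)
  pick <- function(q, s) r$estimate[r$quantity == q & r$period == s]
  expect_equal(round(pick("indirect_via_RD", "delta"), 2), 0.04)
  expect_equal(round(pick("total_on_outcome", "pre"), 2), 0.57)
  expect_equal(round(pick("total_on_outcome", "post"), 2), 0.36)
  expect_equal(round(pick("total_on_outcome", "delta"), 2), 0.21)
  expect_equal(effect_delta(fit, "indirect_via_RD")$estimate, 0.04,
               tolerance = 1e-12)
  expect_error(effect_delta(fit, "nonsense"), "unknown quantity")

  # identical pre/post draws -> delta 0 with interval containing 0
  set.seed(7)
  draws <- as.data.frame(matrix(rnorm(6 * 200), 200, 6))
  names(draws) <- paste0(c("a1", "a2", "d", "b1", "b2", "c"), "_pre")
  for (k in c("a1", "a2", "d", "b1", "b2", "c"))
    draws[[paste0(k, "_post")]] <- draws[[paste0(k, "_pre")]]
  fit$draws <- draws
  d0 <- effect_delta(fit, "a1")
  expect_equal(d0$estimate, 0)
  expect_true(d0$lower <= 0 && d0$upper >= 0)
  # simulated draws: delta summary equals brute-force subtract-then-summarize
  draws$a1_post <- rnorm(200)
  fit$draws <- draws
  d1 <- effect_delta(fit, "a1", level = 0.9)
  diff <- draws$a1_pre - draws$a1_post
  expect_equal(d1$estimate, median(diff), tolerance = 1e-12)
  expect_equal(d1$lower, unname(quantile(diff, 0.05)), tolerance = 1e-12)
})

test_that("significance flags are monotone in the interval level", {
  set.seed(8)
  draws <- as.data.frame(matrix(rnorm(12 * 400, mean = 0.15, sd = 0.4),
                                400, 12))
  names(draws) <- paste0(rep(c("a1", "a2", "d", "b1", "b2", "c"), each = 2),
                         c("_pre", "_post"))
  fit <- path_point_draws(structural_params())
  fit$draws <- draws
  r95 <- compose_effects(fit, level = 0.95)
  r80 <- compose_effects(fit, level = 0.80)
  key <- paste(r95$quantity, r95$period)
  stopifnot(identical(key, paste(r80$quantity, r80$period)))
  expect_true(all(!r95$significant | r80$significant))
})

test_that("mismatched draw lengths are an integrity error", {
  fit <- path_point_draws(structural_params())
  fit$draws <- as.list(fit$draws)
  fit$draws$a1_pre <- c(1, 2)
  expect_error(compose_effects(fit), "mismatched")
})

test_that("effect reports export to CSV and JSON", {
  r <- compose_effects(path_point_draws(structural_params()))
  f <- withr::local_tempfile(fileext = ".csv")
  write_effect_report(r, f, "csv")
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(r))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_effect_report(r, f2, "json")
  expect_silent(jsonlite::fromJSON(f2))
  expect_output(print(r), "total_on_referee")
})
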