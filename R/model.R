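#' Specification of the mediation path model
#'
#' Describes the three linked linear equations fitted by [fit_ham()]:
#' team performance on venue, refereeing on venue + team performance, and
#' outcome on venue + both mediators, every path interacted with the
#' crowd-absence indicator, with standardized rating/importance controls
#' (also interacted) and team-within-league random intercepts. The DAG is
#' fixed and acyclic by construction: the performance equation contains no
#' latent predictors, the refereeing equation contains team performance only,
#' and the outcome equation contains both mediators.
#'
#' @param granularity `"team_aggregate"` (default; one row per
#'   team x venue x period cell, the main analysis) or `"per_game"` (one row
#'   per team per match).
#' @param controls Subset of `c("rating", "importance")`.
#' @return An object of class `ham_model_spec`.
#' @export
ham_model_spec <- function(granularity = c("team_aggregate", "per_game"),
                           controls = c("rating", "importance")) {
  granularity <- match.arg(granularity)
  if (!all(controls %in% c("rating", "importance")))
    stop("ham_model_spec: unknown control(s)", call. = FALSE)
  structure(list(granularity = granularity, controls = controls),
            class = "ham_model_spec")
}

#' Estimation settings for the path model
#'
#' @param engine `"mcmc"` (own blocked Gibbs sampler; default) or
#'   `"bootstrap"` (lme4 point fits with a cluster bootstrap over teams).
#' @param chains Number of MCMC chains.
#' @param draws_per_chain Kept draws per chain after warmup.
#' @param warmup Warmup iterations per chain (discarded).
#' @param bootstrap_reps Bootstrap resamples for the bootstrap engine.
#' @param seed Integer seed controlling all engine randomness.
#' @param prior_scale SD of the zero-mean normal prior on standardized
#'   coefficients (default 2.5, weakly informative).
#' @param sd_prior_scale Scale of the half-normal priors on the residual and
#'   random-intercept SDs (default 1; the latents are standardized).
#' @param interval_level Credible/confidence level for reporting
#'   (default 0.95).
#' @return An object of class `estimation_settings`.
#' @export
estimation_settings <- function(engine = c("mcmc", "bootstrap"),
                                chains = 2L, draws_per_chain = 500L,
                                warmup = 500L, bootstrap_reps = 200L,
                                seed = 1L, prior_scale = 2.5,
                                sd_prior_scale = 1,
                                interval_level = 0.95) {
  engine <- match.arg(engine)
  if (interval_level <= 0.5 || interval_level >= 1)
    stop("estimation_settings: interval_level must lie in (0.5, 1)",
         call. = FALSE)
  if (chains < 1 || draws_per_chain < 1 || warmup < 0 || bootstrap_reps < 1)
    stop("estimation_settings: invalid iteration counts", call. = FALSE)
  total <- if (engine == "mcmc") chains * draws_per_chain else bootstrap_reps
  if (total < 500)
    warning("estimation_settings: fewer than 500 total draws; ",
            "interval summaries will be coarse")
  structure(list(engine = engine, chains = as.integer(chains),
                 draws_per_chain = as.integer(draws_per_chain),
                 warmup = as.integer(warmup),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), prior_scale = prior_scale,
                 sd_prior_scale = sd_prior_scale,
                 interval_level = interval_level),
            class = "estimation_settings")
}

# --- univariate slice sampler (stepping out + shrinkage), used for log-SDs --
.slice1 <- function(x0, logf, w = 1, max_steps = 50L) {
  y <- logf(x0) - stats::rexp(1)
  u <- stats::runif(1)
  lo <- x0 - w * u
  hi <- lo + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1L - j
  while (j > 0L && y < logf(lo)) { lo <- lo - w; j <- j - 1L }
  while (k > 0L && y < logf(hi)) { hi <- hi + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (y <= logf(x1)) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# Blocked Gibbs sampler for y = X beta + Z_t u + Z_l v + e with
# beta ~ N(0, prior_scale^2), u ~ N(0, tau_t^2), v ~ N(0, tau_l^2),
# half-normal(sd_prior_scale) priors on sigma, tau_t, tau_l.
# (beta, u, v) are updated jointly from their multivariate-normal full
# conditional; the three SDs by slice sampling on the log scale.
.gibbs_lmm <- function(y, X, team, league, settings, base_seed) {
  n <- length(y)
  Tf <- factor(team)
  qt <- nlevels(Tf)
  Zt <- stats::model.matrix(~ Tf - 1)
  use_league <- !is.null(league)
  if (use_league) {
    Lf <- factor(league)
    ql <- nlevels(Lf)
    Zl <- stats::model.matrix(~ Lf - 1)
    W <- cbind(X, Zt, Zl)
  } else {
    ql <- 0L
    W <- cbind(X, Zt)
  }
  px <- ncol(X)
  p <- ncol(W)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  ix_b <- seq_len(px)
  ix_t <- px + seq_len(qt)
  ix_l <- if (ql > 0) px + qt + seq_len(ql) else integer(0)
  sps <- settings$sd_prior_scale
  n_keep <- settings$draws_per_chain
  n_iter <- settings$warmup + n_keep
  chains <- settings$chains
  sd_logpost <- function(t, q, ss) -(q - 1) * t - ss / (2 * exp(2 * t)) -
    exp(2 * t) / (2 * sps^2)
  coefs <- matrix(NA_real_, chains * n_keep, p)
  sds <- matrix(NA_real_, chains * n_keep, 3)  # sigma, tau_t, tau_l
  sy <- stats::sd(y)
  for (ch in seq_len(chains)) {
    set.seed(base_seed + 7919L * ch)
    sigma <- sy * stats::runif(1, 0.5, 1.5)
    tau_t <- sy * stats::runif(1, 0.2, 0.8)
    tau_l <- sy * stats::runif(1, 0.2, 0.8)
    for (it in seq_len(n_iter)) {
      prec <- c(rep(1 / settings$prior_scale^2, px), rep(1 / tau_t^2, qt),
                if (ql > 0) rep(1 / tau_l^2, ql))
      A <- WtW / sigma^2
      diag(A) <- diag(A) + prec
      U <- chol(A)
      b <- Wty / sigma^2
      mhat <- backsolve(U, backsolve(U, b, transpose = TRUE))
      theta <- drop(mhat + backsolve(U, stats::rnorm(p)))
      r <- y - drop(W %*% theta)
      # joint rescaling move along the (u, tau) ridge: propose u' = k u,
      # tau' = k tau; SSR(k) is quadratic in k so the move is O(n)
      for (blk in list(list(ix = ix_t, q = qt, tau = "tau_t"),
                       if (ql > 0) list(ix = ix_l, q = ql, tau = "tau_l"))) {
        if (is.null(blk)) next
        zu <- drop(W[, blk$ix, drop = FALSE] %*% theta[blk$ix])
        r_base <- r + zu
        k <- exp(stats::rnorm(1, 0, 0.15))
        tau_cur <- get(blk$tau)
        ssr_new <- sum((r_base - k * zu)^2)
        ssr_old <- sum(r^2)
        log_acc <- -(ssr_new - ssr_old) / (2 * sigma^2) + log(k) -
          (k^2 - 1) * tau_cur^2 / (2 * sps^2)
        if (log(stats::runif(1)) < log_acc) {
          theta[blk$ix] <- k * theta[blk$ix]
          assign(blk$tau, k * tau_cur)
          r <- r_base - k * zu
        }
      }
      ssr <- sum(r^2)
      ss_t <- sum(theta[ix_t]^2)
      ss_l <- if (ql > 0) sum(theta[ix_l]^2) else 0
      for (pass in 1:3) {
        sigma <- exp(.slice1(log(sigma), function(t) sd_logpost(t, n, ssr)))
        tau_t <- exp(.slice1(log(tau_t), function(t)
          sd_logpost(t, qt, ss_t)))
        if (ql > 0)
          tau_l <- exp(.slice1(log(tau_l), function(t)
            sd_logpost(t, ql, ss_l)))
      }
      if (it > settings$warmup) {
        row <- (ch - 1L) * n_keep + (it - settings$warmup)
        coefs[row, ] <- theta
        sds[row, ] <- c(sigma, tau_t, if (ql > 0) tau_l else NA_real_)
      }
    }
  }
  colnames(coefs) <- colnames(W)
  list(beta = coefs[, ix_b, drop = FALSE], coefs = coefs,
       sigma = sds[, 1], tau_team = sds[, 2], tau_league = sds[, 3],
       W = W, px = px, qt = qt, ql = ql,
       chain = rep(seq_len(chains), each = n_keep))
}

# --- convergence diagnostics ------------------------------------------------
# Split-chain potential scale reduction factor.
.split_rhat <- function(x, chain) {
  sp <- split(x, chain)
  halves <- unlist(lapply(sp, function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  Wv <- mean(vars)
  Bv <- n * stats::var(means)
  if (Wv < 1e-300) return(1)
  sqrt(((n - 1) / n * Wv + Bv / n) / Wv)
}

# Effective sample size with Geyer initial-monotone truncation.
.ess <- function(x, chain) {
  sp <- split(x, chain)
  n <- min(lengths(sp))
  m <- length(sp)
  if (n < 4L) return(NA_real_)
  acors <- vapply(sp, function(v) {
    v <- v[seq_len(n)]
    if (stats::sd(v) < 1e-300) return(rep(0, n))
    a <- stats::acf(v, lag.max = n - 1L, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(n))
  rho <- rowMeans(acors)
  # sum over initial positive pairs
  s <- 0
  k <- 1L
  while (k + 1L < n) {
    pair <- rho[k + 1L] + ifelse(k + 2L <= n, rho[k + 2L], 0)
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(m * n / (1 + 2 * s), 1)
}

.eq_design <- function(dat, extra = NULL) {
  X <- cbind(`(Intercept)` = 1, venue = dat$venue, post = dat$post,
             venue_post = dat$venue * dat$post)
  for (e in extra) {
    X <- cbind(X, dat[[e]], dat[[e]] * dat$post)
    colnames(X)[ncol(X) - 1:0] <- c(e, paste0(e, "_post"))
  }
  for (ct in attr(dat, "controls")) {
    X <- cbind(X, dat[[paste0("z_", ct)]], dat[[paste0("z_", ct)]] * dat$post)
    colnames(X)[ncol(X) - 1:0] <- c(ct, paste0(ct, "_post"))
  }
  X
}

.as01 <- function(x, one, zero, what) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("fit_ham: ", what, " must be 0/1 or ",
                                   one, "/", zero, call. = FALSE)
    return(as.numeric(x))
  }
  if (!all(x %in% c(one, zero)))
    stop("fit_ham: ", what, " must be 0/1 or ", one, "/", zero, call. = FALSE)
  as.numeric(x == one)
}

#' Fit the hierarchical moderated-mediation path model
#'
#' Fits the three structural equations jointly (the likelihood factorizes
#' over the recursive equations, so the joint posterior is the product of
#' the three equation posteriors; draws are concatenated row-wise and are
#' therefore joint) and materializes per-period path coefficients:
#' `pre` = base coefficient, `post` = base + crowd interaction.
#'
#' With the `mcmc` engine each equation is sampled by a blocked Gibbs
#' sampler (joint normal update of all fixed and random effects given the
#' variance components; slice updates of the three SDs under half-normal
#' priors). With the `bootstrap` engine each equation is fitted by
#' [lme4::lmer()] and draws are obtained by resampling teams with
#' replacement within leagues and refitting.
#'
#' @param data Data.frame with columns `tp`, `rd`, `out` (latent scores,
#'   e.g. from [build_latents()]), `venue` (`home`/`away` or 1/0), `period`
#'   (`crowd`/`no_crowd` or 0/1), `rating`, `importance`, `team_id`,
#'   `league_id`.
#' @param spec A [ham_model_spec()].
#' @param settings An [estimation_settings()].
#' @return An object of class `ham_draws`: a list with `draws` (data.frame,
#'   one row per joint draw, columns `a1_pre`, ..., `c_post`, control
#'   coefficients, `tau_team_*`, `tau_league_*`, `sigma_*`), `diagnostics`
#'   (split-chain Rhat and effective sample size per path), `converged`
#'   flag (all Rhat < 1.01), and internal state for [bayes_r2()].
#' @export
fit_ham <- function(data, spec = ham_model_spec(),
                    settings = estimation_settings()) {
  need <- c("tp", "rd", "out", "venue", "period", "rating", "importance",
            "team_id", "league_id")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("fit_ham: data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dat <- data.frame(
    tp = data$tp, rd = data$rd, out = data$out,
    venue = .as01(data$venue, "home", "away", "venue"),
    post = .as01(data$period, "no_crowd", "crowd", "period"),
    team_id = as.character(data$team_id),
    league_id = as.character(data$league_id),
    stringsAsFactors = FALSE)
  for (ct in spec$controls)
    dat[[paste0("z_", ct)]] <- as.numeric(scale(data[[ct]]))
  attr(dat, "controls") <- spec$controls
  for (k in c("tp", "rd", "out"))
    if (stats::sd(dat[[k]]) < 1e-12)
      stop("fit_ham: degenerate input, zero variance in ", k, call. = FALSE)
  league <- dat$league_id
  if (length(unique(league)) < 2L) {
    warning("fit_ham: single league; league random term dropped")
    league <- NULL
  }
  designs <- list(
    perf = list(y = dat$tp, X = .eq_design(dat)),
    ref = list(y = dat$rd, X = .eq_design(dat, "tp")),
    out = list(y = dat$out, X = .eq_design(dat, c("tp", "rd"))))
  if (settings$engine == "mcmc")
    fits <- lapply(seq_along(designs), function(i)
      .gibbs_lmm(designs[[i]]$y, designs[[i]]$X, dat$team_id, league,
                 settings, settings$seed + 1000L * i))
  else
    fits <- .bootstrap_engine(designs, dat, league, settings)
  names(fits) <- names(designs)

  path_map <- list(
    a1 = c("perf", "venue"), a2 = c("ref", "venue"), d = c("ref", "tp"),
    b1 = c("out", "tp"), b2 = c("out", "rd"), c = c("out", "venue"))
  draws <- data.frame(row.names = seq_len(nrow(fits[[1]]$beta)))
  for (nm in names(path_map)) {
    eq <- path_map[[nm]][1]; col <- path_map[[nm]][2]
    base <- fits[[eq]]$beta[, col]
    inter <- fits[[eq]]$beta[, paste0(col, "_post")]
    draws[[paste0(nm, "_pre")]] <- base
    draws[[paste0(nm, "_post")]] <- base + inter
  }
  for (eq in names(fits)) {
    for (ct in spec$controls) {
      draws[[paste0("gamma_", ct, "_", eq)]] <- fits[[eq]]$beta[, ct]
      draws[[paste0("gamma_", ct, "_", eq, "_post")]] <-
        fits[[eq]]$beta[, ct] + fits[[eq]]$beta[, paste0(ct, "_post")]
    }
    draws[[paste0("tau_team_", eq)]] <- fits[[eq]]$tau_team
    draws[[paste0("tau_league_", eq)]] <- fits[[eq]]$tau_league
    draws[[paste0("sigma_", eq)]] <- fits[[eq]]$sigma
  }
  chain <- fits[[1]]$chain
  diag_cols <- c(paste0(rep(names(path_map), each = 2), c("_pre", "_post")),
                 paste0("sigma_", names(fits)))
  diagnostics <- data.frame(
    coefficient = diag_cols,
    rhat = vapply(diag_cols, function(k)
      if (settings$engine == "mcmc") .split_rhat(draws[[k]], chain)
      else NA_real_, numeric(1)),
    ess = vapply(diag_cols, function(k)
      if (settings$engine == "mcmc") .ess(draws[[k]], chain)
      else length(chain), numeric(1)),
    row.names = NULL)
  converged <- settings$engine != "mcmc" ||
    all(diagnostics$rhat < 1.01, na.rm = TRUE)
  if (!converged)
    warning("fit_ham: convergence diagnostic exceeds 1.01 for: ",
            paste(diagnostics$coefficient[diagnostics$rhat >= 1.01],
                  collapse = ", "))
  structure(list(draws = draws, diagnostics = diagnostics,
                 converged = converged, chain = chain,
                 equations = fits, spec = spec, settings = settings,
                 n_obs = nrow(dat)),
            class = "ham_draws")
}

# Cluster bootstrap over teams (within league) around lme4 point fits.
.bootstrap_engine <- function(designs, dat, league, settings) {
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("bootstrap engine requires lme4", call. = FALSE)
  use_league <- !is.null(league)
  fit_one <- function(y, X, team_lab, league_lab) {
    fd <- as.data.frame(X[, -1, drop = FALSE])
    names(fd) <- make.names(names(fd))
    preds <- names(fd)
    fd$.y <- y
    fd$.team <- team_lab
    fd$.league <- league_lab
    re <- if (use_league) " + (1 | .team) + (1 | .league)" else " + (1 | .team)"
    f <- stats::as.formula(paste(".y ~", paste(preds, collapse = " + "), re))
    suppressWarnings(suppressMessages(
      lme4::lmer(f, data = fd, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             check.conv.grad = "ignore",
                                             check.conv.hess = "ignore"))))
  }
  extract <- function(fit, Xnames) {
    fe <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau_t <- sqrt(vc$vcov[vc$grp == ".team"][1])
    tau_l <- if (use_league) sqrt(vc$vcov[vc$grp == ".league"][1]) else NA_real_
    # match by (syntactically valid) name; predictors dropped by lmer for
    # rank deficiency come back as NA
    key <- c("(Intercept)", make.names(Xnames[-1]))
    c(unname(fe[key]), stats::sigma(fit), tau_t, tau_l,
      stats::var(stats::fitted(fit)))
  }
  teams <- split(unique(dat$team_id), dat$league_id[!duplicated(dat$team_id)])
  rows_by_team <- split(seq_len(nrow(dat)), dat$team_id)
  # draw all resampling indices once so the three equations share them
  set.seed(settings$seed)
  B <- settings$bootstrap_reps
  resamples <- lapply(seq_len(B), function(b) {
    idx <- integer(0); lab <- character(0)
    copy <- 0L
    for (lg in names(teams)) {
      pick <- sample(teams[[lg]], length(teams[[lg]]), replace = TRUE)
      for (tm in pick) {
        copy <- copy + 1L
        r <- rows_by_team[[tm]]
        idx <- c(idx, r)
        lab <- c(lab, rep(sprintf("%s#%d", tm, copy), length(r)))
      }
    }
    list(idx = idx, lab = lab)
  })
  out <- lapply(names(designs), function(nm) {
    d <- designs[[nm]]
    Xn <- colnames(d$X)
    reps <- matrix(NA_real_, B, length(Xn) + 4L,
                   dimnames = list(NULL, c(Xn, "sigma", "tau_team",
                                           "tau_league", "var_fit")))
    for (b in seq_len(B)) {
      rs <- resamples[[b]]
      fb <- fit_one(d$y[rs$idx], d$X[rs$idx, , drop = FALSE], rs$lab,
                    dat$league_id[rs$idx])
      reps[b, ] <- extract(fb, Xn)
    }
    list(beta = reps[, Xn, drop = FALSE],
         sigma = reps[, "sigma"], tau_team = reps[, "tau_team"],
         tau_league = reps[, "tau_league"],
         var_fit = reps[, "var_fit"],
         chain = rep(1L, B))
  })
  names(out) <- names(designs)
  out
}

#' Bayesian R-squared per equation
#'
#' Per draw, the ratio `var(fitted) / (var(fitted) + sigma^2)` where the
#' fitted values include the fixed effects and the team/league random
#' intercepts, summarized by the median and a central credible interval.
#'
#' @param fit A `ham_draws` object from [fit_ham()].
#' @param level Interval level (defaults to the fit's setting).
#' @return Data.frame with one row per equation (`perf`, `ref`, `out`):
#'   `median`, `lower`, `upper`.
#' @export
bayes_r2 <- function(fit, level = NULL) {
  if (!inherits(fit, "ham_draws"))
    stop("bayes_r2: fit must be a ham_draws object", call. = FALSE)
  level <- level %||% fit$settings$interval_level
  a <- (1 - level) / 2
  rows <- lapply(names(fit$equations), function(eq) {
    f <- fit$equations[[eq]]
    if (!is.null(f$var_fit)) {
      vf <- f$var_fit
    } else {
      fitted <- f$coefs %*% t(f$W)    # draws x n
      vf <- apply(fitted, 1, stats::var)
    }
    r2 <- vf / (vf + f$sigma^2)
    data.frame(equation = eq, median = stats::median(r2),
               lower = unname(stats::quantile(r2, a)),
               upper = unname(stats::quantile(r2, 1 - a)))
  })
  do.call(rbind, rows)
}

#' @export
print.ham_draws <- function(x, ...) {
  cat("Hierarchical moderated-mediation path model fit\n")
  cat(sprintf("  engine: %s, joint draws: %d, observations: %d\n",
              x$settings$engine, nrow(x$draws), x$n_obs))
  if (x$settings$engine == "mcmc")
    cat(sprintf("  max split-chain Rhat: %.3f (converged: %s)\n",
                max(x$diagnostics$rhat, na.rm = TRUE), x$converged))
  paths <- c("a1", "a2", "d", "b1", "b2", "c")
  for (p in paths) {
    cat(sprintf("  %-3s pre % .3f  post % .3f\n", p,
                stats::median(x$draws[[paste0(p, "_pre")]]),
                stats::median(x$draws[[paste0(p, "_post")]])))
  }
  invisible(x)
}

#' Persist path-model draws as CSV
#'
#' @param fit A `ham_draws` object.
#' @param path Output CSV path (one column per coefficient, one row per
#'   draw, plus a `chain` column).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  df <- cbind(chain = fit$chain, fit$draws)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
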