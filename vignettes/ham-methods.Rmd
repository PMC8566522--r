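---
title: "The home-advantage mediation model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The home-advantage mediation model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hamr)
```

## The problem

Football teams win more, score more and are punished less when they play at
their own ground. The standing explanation is the crowd: home support lifts
the home side's in-game performance and leans on the referee. Seasons in
which part of the schedule was played behind closed doors act as a natural
experiment: the same teams, the same season, with and without spectators.

`hamr` implements the full analysis pipeline for this question on paired
home/away match tables: a synthetic-data generator with a known structural
model, latent-construct scoring, a hierarchical Bayesian moderated-mediation
path model, effect decomposition, descriptive home-advantage summaries, and
robustness harnesses.

## The structural model

Three latent constructs are scored per analysis row (a team's side of a
match, or its aggregate over one venue x period cell):

* **Team Performance (TP)** — corners, shots, shots on target;
* **Referees' Decisions (RD)** — fouls, yellow cards, red cards (high =
  punished more);
* **Outcome (OUT)** — points and goals scored.

The structural equations, with venue $V$ (home = 1) and crowd-absence
indicator $P$ (no crowd = 1), are

$$
\begin{aligned}
TP &= a_1(P)\,V + \gamma' X + u^{tp}_{team} + w^{tp}_{league} + \varepsilon_1\\
RD &= a_2(P)\,V + d(P)\,TP + \gamma' X + u^{rd}_{team} + w^{rd}_{league} + \varepsilon_2\\
OUT &= c(P)\,V + b_1(P)\,TP + b_2(P)\,RD + \gamma' X + u^{out}_{team} + w^{out}_{league} + \varepsilon_3
\end{aligned}
$$

where every path is period-specific, parameterized as base + interaction
(`pre` = crowd, `post` = base + crowd-absence increment), $X$ are the
standardized team-rating and match-importance controls (also interacted with
$P$), and $u, w$ are team and league random intercepts. The DAG is recursive,
so the likelihood factorizes over the three equations and the joint posterior
is the product of the equation posteriors; concatenating the equation draws
row-wise gives joint draws, which is what the product-of-coefficients
mediation quantities require.

Composed quantities, per draw and period: indirect effect via performance
$a_1 b_1$, via refereeing $a_2 b_2$, serial three-path effect $a_1 d\, b_2$,
direct effect $c$, the total effect on the outcome, and the indirect
($a_1 d$) and total ($a_2 + a_1 d$) effects on refereeing. A quantity is
"significant" when its central 95% interval excludes zero.

**Sign conventions.** The effect deltas are *reductions*, `pre - post`:
positive means the effect shrank when crowds were absent. The descriptive
module separately reports signed `post - pre` changes (`ha_period_change()`),
because both conventions appear in the applied literature on this question.
The default total on the outcome excludes the serial three-path term, which
is always reported separately (`include_serial_in_total = TRUE` adds it);
published referee totals (-0.42 / +0.16) pin down the referee composition,
but no printed value pins down the serial term's allocation in the outcome
total, so the choice is explicit rather than silent.

## Estimation

No Stan-style sampler is assumed. The `mcmc` engine is a blocked Gibbs
sampler written for exactly this model class: given the variance components,
all fixed and random effects are updated *jointly* from their
multivariate-normal full conditional (one Cholesky per iteration), which
eliminates the slow mixing of one-at-a-time updates; the residual SD and the
two random-intercept SDs are then updated by univariate slice sampling on
the log scale. Priors: zero-mean normal with SD `prior_scale` (default 2.5)
on standardized coefficients; half-normal with scale `sd_prior_scale`
(default 1) on all SDs — weakly informative on the standardized scale.
Defaults run 2 chains of 500 warmup + 500 kept draws; split-chain
$\widehat R$ and an autocorrelation-based effective sample size are reported
per path, and any $\widehat R \ge 1.01$ flags the fit with a warning, never
silently.

The `bootstrap` engine mirrors the non-Bayesian variant: `lme4::lmer()`
point fits, with draws obtained by resampling teams with replacement within
leagues (resampled copies of a team act as distinct clusters) and refitting;
the same resampled indices are shared across the three equations so the
draws remain joint.

Bayesian $R^2$ is computed per draw as
$\mathrm{var}(\hat y)/(\mathrm{var}(\hat y) + \sigma^2)$ with fitted values
including the random intercepts.

## The synthetic-data generator

The generator emulates the structure of a 12-league European season of
double round robins (18 teams, 34 rounds, ~3700 matches) whose final ~26% of
rounds are played without crowds — the published split is 74/26 over 4356
matches, and 26% is the generator's default `post_share`. Ground truth
defaults are the published path values: $a_1$ 0.89/0.35, $a_2$ -0.30/+0.19,
$d$ -0.14/-0.08; $b_1 = 0.30$, $b_2 = -0.08$, $c = 0.26$ constant across
periods, consistent with the published mediations (0.26/0.12 and 0.03/-0.01)
and totals (0.57/0.36) and with the reported finding that the
mediator-to-outcome and direct paths did not change significantly.

Latents are Gaussian structural equations on a standardized scale. Residual
variation is split into a cell-level component (`latent_cell_sd = 0.8`,
shared by all matches of one team x venue x period cell, so it survives
aggregation) and a match-level component (`latent_game_sd = 0.6`, which
averages away); together with the venue, control and random-intercept
contributions this puts the cell-level latent variance near 1, so the
generator's paths are approximately on the standardized scale the model
reports. Team and league intercepts default to SDs 0.30 and 0.15.

Observed counts are `max(0, round(baseline + loading * latent + noise))`.
Baselines are typical per-team-per-match magnitudes (5 corners, 12.5 shots,
4.3 on target, 11.9 fouls, 2 yellows, 0.09 reds); loadings and noises give
standardized loadings around 0.8–0.9, in line with single-factor constructs
that explain roughly 50–85% of indicator variance. Red cards are effectively
a threshold-crossing indicator (a 0/1 event in ~9% of team-games) — the
noise scale 0.30 was set so that rate is realistic; an early value made reds
so rare that the column was constant in league subsets. Goals are Poisson
with log-mean shifted by the outcome latent (`goals` loading 0.35 on the log
scale); points follow deterministically (3/1/0), which preserves the exact
pairing constraints real tables obey ({3,0}, {0,3} or {1,1} per match).
Ratings are drawn per team from a league-centered normal; importance per
match uniform on (0, 100), matching the published covariates' style; no
distributions for these are published, so these are package choices.

What the generator does *not* emulate: real fixture calendars, bookmaker or
SPI rating dynamics, within-game event ordering, referee identities, travel.
A green test therefore establishes that the pipeline recovers a known
structural world of the right shape and size — not that the published
coefficients are correct.

## Latent construct scoring

Each construct is fitted separately on z-scored indicators, pooled across
leagues. Three-indicator constructs use a maximum-likelihood single-factor
fit (`stats::factanal`), with an iterative principal-axis fallback if ML
fails; the two-indicator outcome pair is not ML-identifiable, so it uses the
first principal component (equal weights when the correlation is positive).
Solutions are sign-oriented so the mean loading is positive, which makes TP
load positively on chance creation, RD on punishments, OUT on success.
Factor scores use the regression (Thomson) method and are re-standardized to
mean 0, SD 1 on the training rows; `variance_explained` is the mean squared
loading. A one-factor ML fit on mutually *independent* indicators is
degenerate by construction (boundary solutions), which the tests assert as a
bound rather than a point value.

## Recovery on the estimated metric

Because scores are standardized per analysis set and the measurement layer
(rounding, truncation at zero, Poisson goals, win/draw/loss points) is
mildly non-linear, the coefficients the model estimates live on the *score*
metric and differ from the generator's latent-metric paths by a
construct-specific scale — and, for the direct path, by a small leakage term
the linear model cannot remove. Parameter recovery is therefore assessed
against the population projection of the paths onto the score metric,
computed by an independent oracle (`score_metric_truths()`): several
independent datasets are simulated at the same design size, scored through
the identical pipeline, and fitted by REML (`lme4`), and the path estimates
are averaged. Delta *signs* are assessed against the raw generative deltas,
which the projection preserves. Under the global null every projection is
exactly zero, so null calibration needs no oracle.

A caveat the recovery harness itself exposes: the score-metric projection is
not a single constant across datasets. Because the measurement layer is
non-linear, each simulated season's league and team draws shift its
effective projection slightly, most visibly for the weakly identified
no-crowd-period paths and the direct venue → outcome path (points and goals
are the most non-linear indicators). The model's intervals are calibrated
for each dataset's own estimand, but their coverage of a *common* reference
value is capped below nominal for those paths — a property of the stated
generator + model pair, not of the sampler, and the reason the recovery
harness reports coverage per path rather than a single pass/fail scalar.

## Numerical and design choices

* Aggregation uses unweighted per-game means within each
  team x venue x period cell; weighting by games is not pinned down by any
  published statement, and per-game figures match the published "per game"
  descriptive captions. Game-weighted grand means are recovered exactly by
  re-expansion, which the tests assert.
* `shots_on_target` is clamped to `shots` after rounding noise; reads reject
  tables violating the constraint.
* The period column is an input (`crowd` / `no_crowd`, with `pre`/`post`
  accepted as aliases); `assign_period_by_round()` derives it from a cutoff
  round when only a date threshold is known.
* Listwise deletion: rows missing any model indicator are dropped on read
  with a logged count, mirroring the published missing-data handling.
* The leave-one-league-out harness reuses the main fit's seed and settings
  per variant for comparability, and flags any variant that reverses the
  sign of a delta that is significant on the full data.
* The home-minus-away difference specification drops the venue factor; each
  equation's intercept (and its crowd interaction) then carries the venue
  path, so the same effect composition applies unchanged.
* Config files are JSON (no YAML parser is assumed offline). All commands
  log the seed and a config hash; identical config + seed gives
  byte-identical artifacts.

## Known limitations

* The three-equation factorization assumes independent residuals across
  equations given the predictors; a correlated-residual (seemingly
  unrelated) extension is out of scope.
* Mediation identification rests on the assumed causal ordering
  (performance precedes refereeing); the reversed ordering and
  possession-first orderings are not implemented.
* The bootstrap engine resamples teams, not leagues; with 12 leagues a
  league-level bootstrap would be too coarse to be useful.
* Bayesian $R^2$ for the bootstrap engine uses each refit's own fitted
  values, which is the closest non-Bayesian analog, not a posterior
  quantity.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_leagues = 3, teams_per_league = 10, seed = 1)
matches <- simulate_matches(cfg)
pl <- ham_pipeline(matches,
                   ham_model_spec("team_aggregate"),
                   estimation_settings(seed = 1))
pl$effects
bayes_r2(pl$fit)
```

See the README for the printed output of this example and
`scripts/acceptance.R` for the acceptance report.
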