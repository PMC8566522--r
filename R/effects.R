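.effect_quantities <- c("indirect_via_TP", "indirect_via_RD",
                        "serial_indirect", "direct", "total_on_outcome",
                        "indirect_on_referee_via_TP", "total_on_referee")

#' Wrap point parameter values as a single-draw fit
#'
#' Builds a minimal `ham_draws` object from one set of structural
#' parameters, so that the draw-wise effect composition can be applied to
#' point inputs (for example the printed coefficients of a published model).
#'
#' @param params A [structural_params()] object.
#' @return A `ham_draws` object with one draw.
#' @export
#' @examples
#' compose_effects(path_point_draws(structural_params()))
path_point_draws <- function(params) {
  if (!inherits(params, "structural_params"))
    stop("path_point_draws: params must be structural_params", call. = FALSE)
  draws <- as.data.frame(params[c(
    "a1_pre", "a1_post", "a2_pre", "a2_post", "d_pre", "d_post",
    "b1_pre", "b1_post", "b2_pre", "b2_post", "c_pre", "c_post")])
  structure(list(draws = draws, diagnostics = NULL, converged = TRUE,
                 chain = 1L, equations = NULL, spec = NULL,
                 settings = estimation_settings(draws_per_chain = 1L,
                                                warmup = 0L) |>
                   suppressWarnings(),
                 n_obs = NA_integer_),
            class = "ham_draws")
}

.compose_period <- function(d, s, include_serial_in_total) {
  a1 <- d[[paste0("a1_", s)]]; a2 <- d[[paste0("a2_", s)]]
  dd <- d[[paste0("d_", s)]]; b1 <- d[[paste0("b1_", s)]]
  b2 <- d[[paste0("b2_", s)]]; cc <- d[[paste0("c_", s)]]
  serial <- a1 * dd * b2
  tot <- cc + a1 * b1 + a2 * b2 + if (include_serial_in_total) serial else 0
  list(indirect_via_TP = a1 * b1,
       indirect_via_RD = a2 * b2,
       serial_indirect = serial,
       direct = cc,
       total_on_outcome = tot,
       indirect_on_referee_via_TP = a1 * dd,
       total_on_referee = a2 + a1 * dd)
}

.summarize_draws <- function(x, level) {
  a <- (1 - level) / 2
  est <- stats::median(x)
  if (length(x) == 1L)
    return(data.frame(estimate = est, lower = est, upper = est,
                      significant = NA))
  lo <- unname(stats::quantile(x, a))
  hi <- unname(stats::quantile(x, 1 - a))
  data.frame(estimate = est, lower = lo, upper = hi,
             significant = lo > 0 | hi < 0)
}

#' Compose path draws into mediation effect summaries
#'
#' Computes, per joint draw and per crowd regime, the indirect effect of
#' venue on the outcome via team performance (`a1*b1`) and via refereeing
#' (`a2*b2`), the serial three-path effect (`a1*d*b2`), the direct effect
#' (`c`), the total effect on the outcome, the indirect (`a1*d`) and total
#' (`a2 + a1*d`) effects of venue on refereeing, then summarizes each
#' quantity by its posterior median and central interval. Deltas are the
#' paired per-draw reductions `pre - post` (positive = the effect shrank
#' without crowds). A quantity is flagged significant when its interval
#' excludes zero.
#'
#' By default the serial three-path term is reported separately and not
#' added into `total_on_outcome` (set `include_serial_in_total = TRUE` to
#' add it); the referee total always includes its single indirect component.
#'
#' @param fit A `ham_draws` object ([fit_ham()] or [path_point_draws()]).
#' @param include_serial_in_total Add `a1*d*b2` to the outcome total.
#' @param level Interval level; defaults to the fit's
#'   `settings$interval_level`.
#' @return An `effect_report` data.frame: `quantity`, `period`
#'   (`pre`/`post`/`delta`), `estimate`, `lower`, `upper`, `significant`.
#' @export
#' @examples
#' p <- structural_params(a2_pre = -0.30, a1_pre = 0.89, d_pre = -0.14)
#' r <- compose_effects(path_point_draws(p))
#' round(subset(r, quantity == "total_on_referee" & period == "pre")$estimate, 2)
compose_effects <- function(fit, include_serial_in_total = FALSE,
                            level = NULL) {
  if (!inherits(fit, "ham_draws"))
    stop("compose_effects: fit must be a ham_draws object", call. = FALSE)
  d <- fit$draws
  lens <- lengths(d)
  if (length(unique(lens)) != 1L)
    stop("compose_effects: draws have mismatched lengths", call. = FALSE)
  level <- level %||% fit$settings$interval_level
  pre <- .compose_period(d, "pre", include_serial_in_total)
  post <- .compose_period(d, "post", include_serial_in_total)
  rows <- lapply(.effect_quantities, function(q) {
    rbind(
      cbind(quantity = q, period = "pre", .summarize_draws(pre[[q]], level)),
      cbind(quantity = q, period = "post", .summarize_draws(post[[q]], level)),
      cbind(quantity = q, period = "delta",
            .summarize_draws(pre[[q]] - post[[q]], level)))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "level") <- level
  attr(res, "include_serial_in_total") <- include_serial_in_total
  class(res) <- c("effect_report", "data.frame")
  res
}

#' Summarized reduction of one effect quantity
#'
#' Paired per-draw `pre - post` difference of a single effect quantity (or
#' raw path), with interval and significance flag. Positive values mean the
#' quantity shrank when crowds were absent.
#'
#' @param fit A `ham_draws` object.
#' @param quantity One of the composed effect quantities (see
#'   [compose_effects()]) or a raw path name (`a1`, `a2`, `d`, `b1`, `b2`,
#'   `c`).
#' @param level Interval level.
#' @return One-row data.frame: `quantity`, `estimate`, `lower`, `upper`,
#'   `significant`.
#' @export
effect_delta <- function(fit, quantity, level = NULL) {
  if (!inherits(fit, "ham_draws"))
    stop("effect_delta: fit must be a ham_draws object", call. = FALSE)
  level <- level %||% fit$settings$interval_level
  d <- fit$draws
  if (quantity %in% .effect_quantities) {
    diff <- .compose_period(d, "pre", FALSE)[[quantity]] -
      .compose_period(d, "post", FALSE)[[quantity]]
  } else if (paste0(quantity, "_pre") %in% names(d)) {
    diff <- d[[paste0(quantity, "_pre")]] - d[[paste0(quantity, "_post")]]
  } else {
    stop("effect_delta: unknown quantity '", quantity, "'", call. = FALSE)
  }
  cbind(quantity = quantity, .summarize_draws(diff, level))
}

#' @export
print.effect_report <- function(x, digits = 2, ...) {
  lv <- attr(x, "level")
  cat(sprintf("Venue effect decomposition (%d%% intervals; delta = pre - post)\n",
              round(100 * lv)))
  wide <- function(p) {
    s <- x[x$period == p, ]
    stats::setNames(sprintf("% .2f [% .2f, % .2f]%s", s$estimate, s$lower,
                            s$upper,
                            ifelse(is.na(s$significant), "",
                                   ifelse(s$significant, " *", ""))),
                    s$quantity)
  }
  tab <- cbind(pre = wide("pre"), post = wide("post"), delta = wide("delta"))
  print(tab, quote = FALSE)
  invisible(x)
}

#' Export an effect report
#'
#' @param report An `effect_report`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_effect_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv")
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  else
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
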