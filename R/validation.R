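#' Leave-one-out cross-validation of a proton RBE model
#'
#' Holds out each paired experiment (one cell line/LET combination) in
#' turn, refits the model on the remainder (warm-started from the full-data
#' fit, which makes the procedure fast and deterministic), and records the
#' percent deviation of the predicted from the measured RBE at each dose
#' level.
#'
#' @param data a filtered survival table with at least 10 records.
#' @param dose_levels proton doses (Gy) at which RBE deviations are
#'   evaluated.
#' @param objective fitting objective passed to [rbe_fit()].
#' @param settings an [rbe_settings].
#' @return A `data.frame` of class `"loocv_deviations"`, one row per
#'   (held-out experiment, dose level): `id`, `let_d`, `dose_level`,
#'   `predicted_rbe`, `measured_rbe`, `percent_deviation`
#'   (\eqn{100 (pred - meas)/meas}). Non-converged folds are dropped with a
#'   warning.
#' @export
loocv <- function(data, dose_levels = c(0.5, 1, 2, 5),
                  objective = c("l2", "rbe2gy"), settings = rbe_settings()) {
  objective <- match.arg(objective)
  n <- nrow(data)
  if (n < 10) stop("LOOCV requires at least 10 records")
  full <- rbe_fit(data, objective = objective, se = "none",
                  settings = settings)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(n)) {
    fit <- tryCatch(
      rbe_fit(data[-i, , drop = FALSE], objective = objective,
              start = unname(full$coefficients), se = "none",
              settings = settings),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { skipped <- skipped + 1L; next }
    held <- data[i, , drop = FALSE]
    pred <- vapply(dose_levels, function(d)
      predict(fit, newdata = held, type = "rbe", dose = d), 0)
    meas <- vapply(dose_levels, function(d)
      rbe_at_dose_vec(held$alpha_x, held$beta_x, held$alpha_p, held$beta_p, d),
      0)
    rows[[length(rows) + 1L]] <- data.frame(
      id = held$cell_line, let_d = held$let_d_kev_um,
      dose_level = dose_levels, predicted_rbe = pred, measured_rbe = meas,
      percent_deviation = 100 * (pred - meas) / meas)
  }
  if (skipped > 0)
    warning(skipped, " fold(s) did not converge and were skipped")
  out <- do.call(rbind, rows)
  class(out) <- c("loocv_deviations", "data.frame")
  out
}

#' Bootstrap prediction interval of a deviation distribution
#'
#' Percentile bootstrap of the central interval of the empirical deviation
#' distribution: each resample contributes the
#' \eqn{(1 \mp level)/2} quantiles, and the interval estimate is their
#' bootstrap mean. Asymmetric by construction; reproducible given `seed`.
#'
#' @param devs numeric vector of percent deviations (at least 20).
#' @param level coverage of the central interval (0.683 or 0.95,
#'   typically).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed (mandatory).
#' @return A list of class `"interval_estimate"`: `level`, `lower`,
#'   `upper`.
#' @export
bootstrap_intervals <- function(devs, level = 0.683, n_boot = 10000, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  devs <- devs[is.finite(devs)]
  if (length(devs) < 20) stop("need at least 20 deviations")
  probs <- c((1 - level) / 2, (1 + level) / 2)
  ends <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(b)
      stats::quantile(sample(devs, replace = TRUE), probs, names = FALSE,
                      type = 7),
      numeric(2))
  })
  structure(list(level = level, lower = mean(ends[1, ]),
                 upper = mean(ends[2, ]), n = length(devs),
                 n_boot = n_boot),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.1f%% prediction interval: [%.2f, %.2f]%% (n = %d)\n",
              100 * x$level, x$lower, x$upper, x$n))
  invisible(x)
}

#' Prediction intervals per dose level
#'
#' Tabulates bootstrap prediction intervals of the LOOCV percent deviations
#' separately for each dose level, and flags whether the interval width is
#' non-increasing in dose (the accuracy pattern the model shows: tighter
#' intervals at higher doses).
#'
#' @param devs a `"loocv_deviations"` data.frame from [loocv()].
#' @param levels interval coverages.
#' @param n_boot,seed bootstrap parameters (see [bootstrap_intervals()]).
#' @return A `data.frame` with one row per (dose level, coverage):
#'   `dose_level`, `level`, `lower`, `upper`, `width`; attribute
#'   `"width_nonincreasing"` is `TRUE` when every coverage's width does not
#'   increase with dose. Levels with no records are omitted with a warning.
#' @export
accuracy_by_dose_level <- function(devs, levels = c(0.683, 0.95),
                                   n_boot = 10000, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  dl <- sort(unique(devs$dose_level))
  rows <- list()
  for (d in dl) {
    x <- devs$percent_deviation[devs$dose_level == d]
    x <- x[is.finite(x)]
    if (!length(x)) {
      warning("dose level ", d, " has no records; omitted")
      next
    }
    for (lv in levels) {
      ci <- bootstrap_intervals(x, lv, n_boot, seed)
      rows[[length(rows) + 1L]] <- data.frame(
        dose_level = d, level = lv, lower = ci$lower, upper = ci$upper,
        width = ci$upper - ci$lower)
    }
  }
  out <- do.call(rbind, rows)
  noninc <- all(vapply(levels, function(lv) {
    w <- out$width[out$level == lv][order(out$dose_level[out$level == lv])]
    all(diff(w) <= 1e-9)
  }, TRUE))
  attr(out, "width_nonincreasing") <- noninc
  out
}
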