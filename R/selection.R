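# Candidate LET-function families for the slope and intercept of the
# photon-proton endpoint correlation. Slope families decay (or are
# exponentially suppressed) at high LET; intercept families are
# non-decreasing options plus non-monotone variants.

#' Candidate LET-function families
#'
#' Registry of the seven slope and seven intercept families assessed in the
#' BIC grid search. Each entry has a `form_id`, the free-parameter names
#' (drawn from c, f, g, h, k, m, p, q, s), an evaluator `fn(let, par)`, and
#' a default start vector.
#'
#' @param role `"slope"` or `"intercept"`.
#' @return A named list of family definitions.
#' @export
candidate_families <- function(role = c("slope", "intercept")) {
  role <- match.arg(role)
  if (role == "slope") list(
    exp = list(form_id = "c*exp(-f*L)", pars = c("c", "f"),
               fn = function(L, p) p[1] * exp(-p[2] * L),
               start = c(1, 0.03), nested_in = NULL),
    exp_offset = list(form_id = "c*exp(-f*L)+g", pars = c("c", "f", "g"),
                      fn = function(L, p) p[1] * exp(-p[2] * L) + p[3],
                      start = c(1, 0.03, 0), nested = "exp"),
    gauss = list(form_id = "c*exp(-f*L-h*L^2)+g", pars = c("c", "f", "h", "g"),
                 fn = function(L, p) p[1] * exp(-p[2] * L - p[3] * L^2) + p[4],
                 start = c(1, 0.03, 0.0005, 0), nested = "exp"),
    # parameter order (c, f, h, g) so the nested exponential solution pads
    # positionally with zeros
    lin_exp = list(form_id = "(c+h*L)*exp(-f*L)+g", pars = c("c", "f", "h", "g"),
                   fn = function(L, p) (p[1] + p[3] * L) * exp(-p[2] * L) + p[4],
                   start = c(1, 0.03, 0.005, 0), nested = "exp"),
    log_exp = list(form_id = "c*log(L-h)*exp(-f*L)+g",
                   pars = c("c", "h", "f", "g"),
                   fn = function(L, p) {
                     z <- L - p[2]
                     out <- rep(NaN, length(L))
                     ok <- z > 0
                     out[ok] <- p[1] * log(z[ok]) * exp(-p[3] * L[ok]) + p[4]
                     out
                   },
                   start = c(0.5, -2, 0.02, 0.5), multistart = TRUE),
    inv_gamma = list(form_id = "c/gamma(f*L+h+1)+g", pars = c("c", "f", "h", "g"),
                     fn = function(L, p) {
                       z <- p[2] * L + p[3] + 1
                       out <- rep(NaN, length(L))
                       ok <- z > 0
                       out[ok] <- p[1] * exp(-lgamma(z[ok])) + p[4]
                       out
                     },
                     start = c(1, 0.05, 0, 0), multistart = TRUE),
    poisson = list(form_id = "c*k^(f*(L-h))*exp(-k)/gamma(f*(L-h)+1)+g",
                   pars = c("c", "f", "h", "k", "g"),
                   fn = function(L, p) {
                     x <- p[2] * (L - p[3])
                     ifelse(x > -1,
                            p[1] * exp(x * log(abs(p[4]) + 1e-12) - abs(p[4]) -
                                         lgamma(x + 1)) + p[5],
                            NaN)
                   },
                   start = c(1, 0.05, -1, 0.1, 0), multistart = TRUE))
  else list(
    constant = list(form_id = "m", pars = "m",
                    fn = function(L, p) rep(p[1], length(L)),
                    start = 0.02, dose_pars = 1L),
    linear = list(form_id = "p*L", pars = "p",
                  fn = function(L, p) p[1] * L, start = 0.02,
                  dose_pars = 1L),
    # parameter orders (p, m) and (p, m, q): nested solutions pad with zeros
    linear_offset = list(form_id = "m+p*L", pars = c("p", "m"),
                         fn = function(L, p) p[1] * L + p[2],
                         start = c(0.02, 0.01), nested = "linear",
                         dose_pars = 1:2),
    quadratic = list(form_id = "m+p*L+q*L^2", pars = c("p", "m", "q"),
                     fn = function(L, p) p[1] * L + p[2] + p[3] * L^2,
                     start = c(0.02, 0.01, 0), nested = "linear_offset",
                     dose_pars = 1:3),
    exponential = list(form_id = "q*exp(s*L)", pars = c("q", "s"),
                       fn = function(L, p) p[1] * exp(p[2] * L),
                       start = c(0.02, 0.05), multistart = TRUE,
                       dose_pars = 1L),
    exp_offset = list(form_id = "q*exp(s*L)+m", pars = c("q", "s", "m"),
                      fn = function(L, p) p[1] * exp(p[2] * L) + p[3],
                      start = c(0.02, 0.05, 0), multistart = TRUE,
                      dose_pars = c(1L, 3L)),
    exp_linear = list(form_id = "q*exp(-s*L)+p*L+m",
                      pars = c("q", "s", "p", "m"),
                      fn = function(L, p) p[1] * exp(-p[2] * L) + p[3] * L + p[4],
                      start = c(0.02, 0.05, 0.02, 0), multistart = TRUE,
                      dose_pars = c(1L, 3L, 4L)))
}

# Endpoint values (photon, measured proton) for a single metric across a
# survival table. For dose metrics the value is D_sf; for SF2Gy it is the
# surviving fraction at 2 Gy.
endpoint_values <- function(data, endpoint) {
  if (identical(endpoint, "SF2Gy")) {
    x <- exp(-data$alpha_x * 2 - data$beta_x * 4)
    y <- exp(-data$alpha_p * 2 - data$beta_p * 4)
  } else {
    x <- lq_dose_root(data$alpha_x, data$beta_x, endpoint)
    y <- lq_dose_root(data$alpha_p, data$beta_p, endpoint)
  }
  list(x = x, y = y, let = data$let_d_kev_um)
}

# Deterministic multistart list: base start plus log-uniform/normal jitter
# drawn under the settings seed.
make_starts <- function(start, n_extra, seed) {
  if (n_extra < 1) return(list(start))
  jitters <- with_preserved_seed(seed, {
    lapply(seq_len(n_extra), function(i)
      start * stats::rlnorm(length(start), 0, 0.7) +
        stats::rnorm(length(start), 0, 0.02))
  })
  c(list(start), jitters)
}

#' Fit one endpoint's slope/intercept LET functions
#'
#' Nonlinear least squares of the predictive law
#' \eqn{pred = slope(L)\,v_x + intercept(L)} against the measured proton
#' endpoint, minimising the relative squared distance
#' \eqn{\sum_i ((pred_i - meas_i)/meas_i)^2}. Multi-modal families are fit
#' from a fixed list of multi-starts; the exponential-slope family gets a
#' single analytic-seed start. Families nesting a simpler one also start
#' from the simpler family's solution (zero-padded), which guarantees the
#' nested-objective monotonicity property.
#'
#' @param data a filtered survival table.
#' @param endpoint survival level in (0,1) or `"SF2Gy"`.
#' @param slope_family,intercept_family names from [candidate_families()].
#' @param settings an [rbe_settings].
#' @return A list of class `"fit_report"`: `params`, `objective_value`,
#'   `n`, `k`, `bic`, `converged`.
#' @export
fit_endpoint_function <- function(data, endpoint = 0.10,
                                  slope_family = "exp",
                                  intercept_family = "linear",
                                  settings = rbe_settings()) {
  sl <- candidate_families("slope")[[slope_family]]
  ic <- candidate_families("intercept")[[intercept_family]]
  if (is.null(sl) || is.null(ic)) stop("unknown family name")
  ev <- endpoint_values(data, endpoint)
  # the fit runs in units of the median proton endpoint so that a uniform
  # rescaling of all doses leaves the optimization (and hence the BIC
  # ranking) exactly invariant; dose-dimensioned intercept parameters are
  # scaled back on exit
  dscale <- stats::median(ev$y)
  evs <- list(x = ev$x / dscale, y = ev$y / dscale, let = ev$let)
  ks <- length(sl$pars); ki <- length(ic$pars)
  objfun <- function(th) {
    pred <- sl$fn(evs$let, th[seq_len(ks)]) * evs$x +
      ic$fn(evs$let, th[ks + seq_len(ki)])
    r <- (pred - evs$y) / evs$y
    if (any(!is.finite(r))) return(1e12)
    sum(r^2)
  }
  starts <- list(c(sl$start, ic$start))
  # analytic seed for the exponential slope: log-linear regression of the
  # endpoint ratio on LET
  ratio <- pmax(evs$y / evs$x, 1e-6)
  lmfit <- stats::lm(log(ratio) ~ evs$let)
  exp_seed <- c(exp(stats::coef(lmfit)[1]), -stats::coef(lmfit)[2])
  if (slope_family == "exp") starts <- c(starts, list(c(exp_seed, ic$start)))
  needs_ms <- isTRUE(sl$multistart) || isTRUE(ic$multistart)
  if (needs_ms)
    starts <- unique(c(starts,
                       make_starts(starts[[1]], settings$multistart_n,
                                   settings$multistart_seed)))
  # nested warm starts: solution of the nested family padded with zeros
  nest_start <- function(fit_sl, fit_ic) {
    th <- numeric(ks + ki)
    th[seq_along(fit_sl)] <- fit_sl
    th[ks + seq_along(fit_ic)] <- fit_ic
    th
  }
  if (!is.null(sl$nested) || !is.null(ic$nested)) {
    base_sl <- if (!is.null(sl$nested)) sl$nested else slope_family
    base_ic <- if (!is.null(ic$nested)) ic$nested else intercept_family
    base <- fit_endpoint_function(data, endpoint, base_sl, base_ic, settings)
    nsl <- length(candidate_families("slope")[[base_sl]]$pars)
    base_icfam <- candidate_families("intercept")[[base_ic]]
    base_icpar <- base$params[nsl + seq_len(length(base$params) - nsl)]
    # base params are reported unscaled; bring dose-dimensioned intercept
    # parameters back into the scaled fitting space
    base_icpar[base_icfam$dose_pars] <-
      base_icpar[base_icfam$dose_pars] / dscale
    starts <- c(starts, list(nest_start(base$params[seq_len(nsl)],
                                        base_icpar)))
  }
  # screening pass: when many starts are in play, run each briefly and
  # polish only the two most promising basins
  if (length(starts) > 3) {
    screened <- lapply(starts, function(s)
      stats::optim(s, objfun, method = "Nelder-Mead",
                   control = list(maxit = 200)))
    ord <- order(vapply(screened, `[[`, 0, "value"))
    starts <- lapply(screened[ord[1:2]], `[[`, "par")
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, objfun, method = "Nelder-Mead",
                      control = list(maxit = 600,
                                     reltol = settings$optim_reltol))
    o2 <- tryCatch(stats::optim(o$par, objfun, method = "BFGS",
                                control = list(maxit = 120)),
                   error = function(e) o)
    if (o2$value > o$value) o2 <- o
    if (is.null(best) || o2$value < best$value) best <- o2
  }
  k <- ks + ki
  n <- length(ev$y)
  params <- best$par
  params[ks + ic$dose_pars] <- params[ks + ic$dose_pars] * dscale
  names(params) <- c(sl$pars, ic$pars)
  structure(list(params = params, objective = "relative_sq_endpoint",
                 objective_value = best$value, n = n, k = k,
                 bic = bic(best$value, n, k, settings),
                 converged = is.finite(best$value) && best$value < 1e11,
                 slope_family = slope_family,
                 intercept_family = intercept_family, endpoint = endpoint),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Endpoint-function fit [%s slope x %s intercept]\n",
              x$slope_family, x$intercept_family))
  print(round(x$params, 6))
  cat(sprintf("objective (%s) = %.6g, n = %d, k = %d, BIC = %.2f%s\n",
              x$objective, x$objective_value, x$n, x$k, x$bic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' BIC grid over all slope x intercept family combinations
#'
#' Fits every combination of the seven candidate slope and seven candidate
#' intercept families for one endpoint and tabulates the BIC of each fit.
#' Reproducible bit-for-bit for a fixed multistart seed.
#'
#' @inheritParams fit_endpoint_function
#' @return A list of class `"bic_grid"`: `bic` (7x7 matrix, slope families
#'   in rows), `best` (names of the argmin combination), `fits` (all
#'   fit reports), `converged` (logical matrix).
#' @export
function_grid_search <- function(data, endpoint = 0.10,
                                 settings = rbe_settings()) {
  sl_names <- names(candidate_families("slope"))
  ic_names <- names(candidate_families("intercept"))
  bicm <- matrix(NA_real_, length(sl_names), length(ic_names),
                 dimnames = list(sl_names, ic_names))
  conv <- bicm == 0
  fits <- list()
  for (s in sl_names) for (i in ic_names) {
    f <- fit_endpoint_function(data, endpoint, s, i, settings)
    bicm[s, i] <- f$bic
    conv[s, i] <- f$converged
    fits[[paste(s, i, sep = ".")]] <- f
  }
  amin <- arrayInd(which.min(bicm), dim(bicm))
  structure(list(bic = bicm,
                 best = c(slope = sl_names[amin[1]],
                          intercept = ic_names[amin[2]]),
                 fits = fits, converged = conv, endpoint = endpoint),
            class = "bic_grid")
}

#' @export
print.bic_grid <- function(x, ...) {
  cat("BIC grid (rows: slope families, cols: intercept families)\n")
  print(round(x$bic, 1))
  cat(sprintf("best: %s slope x %s intercept\n",
              x$best["slope"], x$best["intercept"]))
  invisible(x)
}

#' Endpoint-combination search
#'
#' For every subset of 2 to 6 of the standard endpoints (\eqn{D_{5\%}},
#' \eqn{D_{10\%}}, \eqn{D_{20\%}}, \eqn{D_{37\%}}, \eqn{D_{50\%}},
#' \eqn{SF_{2Gy}}), jointly fits per-endpoint exponential slopes plus the
#' chosen intercept family by minimising the summed normalised curve L2
#' distance (the proton curve being reconstructed from the predicted
#' endpoint set), and computes the BIC. Reports the per-size minima, the
#' pattern behind the final two-endpoint model choice.
#'
#' @param data a filtered survival table.
#' @param intercept intercept family name (see [rbe_fit()]).
#' @param sizes subset sizes to scan (default 2:6).
#' @param settings an [rbe_settings].
#' @return A list of class `"combination_search"`: `table` (one row per
#'   subset: endpoints, k, objective, bic, converged), `best_by_size`.
#' @export
endpoint_combination_search <- function(data,
                                        intercept = c("linear", "constant",
                                                      "linear_offset",
                                                      "exponential"),
                                        sizes = 2:6,
                                        settings = rbe_settings()) {
  intercept <- match.arg(intercept)
  all_eps <- list(D5 = 0.05, D10 = 0.10, D20 = 0.20, D37 = 0.37,
                  D50 = 0.50, SF2Gy = "SF2Gy")
  rows <- list()
  for (size in sizes) {
    for (sel in utils::combn(names(all_eps), size, simplify = FALSE)) {
      sf_levels <- unname(all_eps[sel])
      # warm start each endpoint from its own scalar-endpoint fit
      start <- unlist(lapply(sf_levels, function(ep) {
        f <- tryCatch(fit_endpoint_function(data, ep, "exp", intercept,
                                            settings),
                      error = function(e) NULL)
        if (is.null(f)) flint_default_start(list(ep), intercept)
        else unname(f$params)
      }))
      fit <- tryCatch(
        rbe_fit(data, sf_levels = sf_levels, intercept = intercept,
                objective = "l2", start = start, se = "none",
                settings = settings),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        endpoints = paste(sel, collapse = "+"), size = size,
        k = if (is.null(fit)) NA_integer_ else fit$k,
        objective = if (is.null(fit)) NA_real_ else fit$objective_value,
        bic = if (is.null(fit)) NA_real_ else fit$bic,
        converged = !is.null(fit) && fit$converged)
    }
  }
  tab <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(tab, tab$size), function(d)
    d[which.min(d$bic), , drop = FALSE]))
  structure(list(table = tab, best_by_size = best, intercept = intercept),
            class = "combination_search")
}

#' @export
print.combination_search <- function(x, ...) {
  cat(sprintf("Endpoint-combination search (%s intercept)\n", x$intercept))
  cat("minimum BIC per number of endpoints:\n")
  print(x$best_by_size[, c("size", "endpoints", "k", "bic")],
        row.names = FALSE)
  invisible(x)
}

#' Fit the final six-parameter model
#'
#' Convenience wrapper: [rbe_fit()] at the canonical endpoints
#' (\eqn{e^{-1}}, \eqn{e^{-3}}) with the linear intercept, under either
#' objective.
#'
#' @inheritParams rbe_fit
#' @return An [rbe_fit].
#' @export
fit_full_model <- function(data, objective = c("l2", "rbe2gy"),
                           settings = rbe_settings()) {
  rbe_fit(data, objective = match.arg(objective), settings = settings)
}
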