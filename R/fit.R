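# Fitting engine shared by rbe_fit(), the endpoint-combination search and
# model retraining. An "endpoint set" is a list of survival levels (numbers
# in (0,1)) and/or the literal "SF2Gy"; each endpoint carries its own slope
# parameters (c, f) and its own intercept parameters for the chosen family.

intercept_families <- list(
  constant = list(npar = 1L, names = "m",
                  fn = function(L, par) rep(par[1], length(L)),
                  start = 0.02),
  linear = list(npar = 1L, names = "p",
                fn = function(L, par) par[1] * L,
                start = 0.02),
  linear_offset = list(npar = 2L, names = c("m", "p"),
                       fn = function(L, par) par[1] + par[2] * L,
                       start = c(0.01, 0.02)),
  exponential = list(npar = 2L, names = c("q", "s"),
                     fn = function(L, par) par[1] * exp(par[2] * L),
                     start = c(0.02, 0.02)))

# Precompute everything theta-independent from a survival table.
prepare_fit_data <- function(data, sf_levels) {
  ax <- data$alpha_x; bx <- data$beta_x
  ap <- data$alpha_p; bp <- data$beta_p
  L <- data$let_d_kev_um
  n <- nrow(data)
  m <- length(sf_levels)
  vx <- matrix(0, n, m)     # photon endpoint value (dose, or SF for SF2Gy)
  for (j in seq_len(m)) {
    if (identical(sf_levels[[j]], "SF2Gy"))
      vx[, j] <- exp(-ax * 2 - bx * 4)
    else vx[, j] <- lq_dose_root(ax, bx, sf_levels[[j]])
  }
  list(n = n, m = m, let = L, alpha_x = ax, beta_x = bx,
       alpha_p = ap, beta_p = bp, vx = vx, sf_levels = sf_levels)
}

# Iso-effect RBE at dose d of curves (ap, bp) against photons (ax, bx),
# vectorised over records.
rbe_at_dose_vec <- function(ax, bx, ap, bp, d) {
  E <- ap * d + bp * d^2
  Dx <- 2 * E / (ax + sqrt(ax^2 + 4 * bx * E))
  Dx / d
}

# theta -> per-record predicted proton (alpha, beta). Predicted endpoints
# that are unusable (non-positive dose, SF outside (0,1)) are clamped and
# the clamp amount reported so the objective can penalise them smoothly.
flint_predict_ab <- function(theta, prep, intercept, force_branch = NULL) {
  fam <- intercept_families[[intercept]]
  m <- prep$m
  per <- 2L + fam$npar
  Dmat <- matrix(0, prep$n, m)
  Smat <- matrix(0, prep$n, m)
  penalty <- 0
  for (j in seq_len(m)) {
    th <- theta[((j - 1L) * per + 1L):(j * per)]
    pred <- th[1] * exp(-th[2] * prep$let) * prep$vx[, j] +
      fam$fn(prep$let, th[-(1:2)])
    if (identical(prep$sf_levels[[j]], "SF2Gy")) {
      bad <- pred < 1e-6 | pred > 1 - 1e-6
      penalty <- penalty + sum(pmax(pred - (1 - 1e-6), 0)^2 +
                                 pmax(1e-6 - pred, 0)^2)
      pred <- pmin(pmax(pred, 1e-6), 1 - 1e-6)
      Dmat[, j] <- 2
      Smat[, j] <- log(pred)
    } else {
      bad <- pred < 1e-6
      penalty <- penalty + sum(pmax(1e-6 - pred, 0)^2)
      pred <- pmax(pred, 1e-6)
      Dmat[, j] <- pred
      Smat[, j] <- log(prep$sf_levels[[j]])
    }
  }
  ab <- reconstruct_ab_matrix(Dmat, Smat, force_branch)
  alpha <- ab$alpha; beta <- ab$beta
  if (!is.null(force_branch)) {
    # frozen-branch evaluation at a perturbed theta can step just over a
    # feasibility boundary; clamp rather than error
    alpha <- pmax(alpha, 0); beta <- pmax(beta, 0)
  }
  # near-coincident predicted endpoint doses (possible when an SF2Gy
  # endpoint's fixed 2 Gy dose meets a predicted dose) make the normal
  # equations singular; replace the degenerate solution and penalise so the
  # optimizer backs away smoothly
  bad <- !is.finite(alpha) | !is.finite(beta) | alpha > 1e3 | beta > 1e3
  if (any(bad)) {
    alpha[bad] <- 1; beta[bad] <- 0.1
    penalty <- penalty + sum(bad)
  }
  list(alpha = alpha, beta = beta, branch = ab$branch, penalty = penalty)
}

# Residual vector under either objective. For "l2" the residuals are square
# roots of the per-experiment normalised curve distances, so that the summed
# squared residuals equal the summed distances (the dataset objective).
flint_residuals <- function(theta, prep, intercept, objective,
                            force_branch = NULL) {
  pr <- flint_predict_ab(theta, prep, intercept, force_branch)
  if (objective == "l2") {
    d <- curve_l2_distance_vec(pr$alpha, pr$beta, prep$alpha_p, prep$beta_p)
    r <- sqrt(d)
  } else {
    rbe_pred <- rbe_at_dose_vec(prep$alpha_x, prep$beta_x, pr$alpha, pr$beta, 2)
    rbe_meas <- rbe_at_dose_vec(prep$alpha_x, prep$beta_x,
                                prep$alpha_p, prep$beta_p, 2)
    r <- rbe_pred - rbe_meas
  }
  attr(r, "penalty") <- pr$penalty
  r
}

flint_objective <- function(theta, prep, intercept, objective) {
  r <- flint_residuals(theta, prep, intercept, objective)
  val <- sum(r^2) + 1e3 * attr(r, "penalty")
  if (!is.finite(val)) val <- 1e12
  val
}

flint_default_start <- function(sf_levels, intercept) {
  fam <- intercept_families[[intercept]]
  unlist(lapply(sf_levels, function(s) c(1, 0.02, fam$start)))
}

flint_par_names <- function(sf_levels, intercept) {
  fam <- intercept_families[[intercept]]
  unlist(lapply(seq_along(sf_levels), function(j)
    paste0(c("c", "f", fam$names), j)))
}

# Deterministic staged minimisation. The L2 objective (a sum of norms) is
# not differentiable where a curve is interpolated exactly, which stalls
# gradient methods arbitrarily far from a perfect fit; a smooth
# sum-of-squared-distances pre-stage lands in the right basin (and, on
# noiseless data, at the exact solution), after which Nelder-Mead plus a
# BFGS polish minimise the target objective itself.
flint_minimise <- function(theta0, prep, intercept, objective, settings,
                           prestage = TRUE) {
  obj <- function(th) flint_objective(th, prep, intercept, objective)
  start <- theta0
  if (prestage && objective == "l2") {
    obj_sq <- function(th) {
      r <- flint_residuals(th, prep, intercept, "l2")
      val <- sum(as.numeric(r)^4) + 1e3 * attr(r, "penalty")
      if (!is.finite(val)) 1e12 else val
    }
    s1 <- stats::optim(theta0, obj_sq, method = "Nelder-Mead",
                       control = list(maxit = 800,
                                      reltol = settings$optim_reltol))
    s2 <- tryCatch(
      stats::optim(s1$par, obj_sq, method = "BFGS",
                   control = list(maxit = 300,
                                  reltol = settings$optim_reltol)),
      error = function(e) s1)
    start <- if (s2$value <= s1$value) s2$par else s1$par
  }
  o1 <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 1000,
                                    reltol = settings$optim_reltol))
  o2 <- tryCatch(
    stats::optim(o1$par, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = settings$optim_reltol)),
    error = function(e) o1)
  if (o2$value > o1$value) o2 <- o1
  if (obj(start) < o2$value) {
    o2$par <- start
    o2$value <- obj(start)
  }
  o2$converged <- is.finite(o2$value)
  o2
}

# Sandwich (robust M-estimator) covariance: the dataset objective is a sum
# of per-record terms q_i(theta) (a curve distance, or a squared RBE
# residual) whose minimiser is an M-estimator, so
#   cov(theta_hat) = H^-1 B H^-1,
# with H the Hessian of the total objective and B the sum of per-record
# gradient outer products. Unlike the Gauss-Newton form, this remains valid
# when the per-record terms have non-zero mean at the optimum (the L2
# distance objective does).
fit_vcov_sandwich <- function(theta, prep, intercept, objective) {
  n <- prep$n; k <- length(theta)
  if (n <= k) return(NULL)
  per_record <- function(th) {
    r <- as.numeric(flint_residuals(th, prep, intercept, objective))
    r^2  # q_i: distance (l2) or squared RBE residual (rbe2gy)
  }
  # The constrained reconstruction makes the raw objective only piecewise
  # smooth (records switch branches as theta moves), so derivatives are
  # taken on the branch-frozen objective: each record's active branch at
  # the optimum is held fixed, which is the standard active-set treatment
  # and yields a smooth surface in a neighbourhood of theta-hat.
  branches <- flint_predict_ab(theta, prep, intercept)$branch
  per_record <- function(th) {
    r <- as.numeric(flint_residuals(th, prep, intercept, objective,
                                    force_branch = branches))
    r^2
  }
  f <- function(th) sum(per_record(th))
  # Per-record gradients (for B) are stable at small steps on the frozen
  # surface. The Hessian, however, must estimate the curvature of the
  # EXPECTED objective: a sum of curve-space norms has sample curvature
  # ~1/d_i at near-interpolated records, so small-step second differences
  # diverge. Differencing at sampling-scale steps acts as the numerical
  # smoothing (Powell-style) that recovers the population curvature; the
  # step is refined once from provisional standard errors.
  G <- matrix(0, n, k)
  hg <- pmax(abs(theta), 0.02) * 1e-4
  for (j in seq_len(k)) {
    up <- theta; up[j] <- up[j] + hg[j]
    dn <- theta; dn[j] <- dn[j] - hg[j]
    G[, j] <- (per_record(up) - per_record(dn)) / (2 * hg[j])
  }
  B <- crossprod(scale(G, center = TRUE, scale = FALSE))
  hessian_at <- function(h) {
    f0 <- f(theta)
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      up <- theta; up[j] <- up[j] + h[j]
      dn <- theta; dn[j] <- dn[j] - h[j]
      H[j, j] <- (f(up) - 2 * f0 + f(dn)) / h[j]^2
    }
    for (j in seq_len(k - 1)) for (l in (j + 1):k) {
      pp <- theta; pp[c(j, l)] <- pp[c(j, l)] + h[c(j, l)]
      pm <- theta; pm[j] <- pm[j] + h[j]; pm[l] <- pm[l] - h[l]
      mp <- theta; mp[j] <- mp[j] - h[j]; mp[l] <- mp[l] + h[l]
      mm <- theta; mm[c(j, l)] <- mm[c(j, l)] - h[c(j, l)]
      H[j, l] <- H[l, j] <- (f(pp) - f(pm) - f(mp) + f(mm)) /
        (4 * h[j] * h[l])
    }
    H
  }
  sandwich <- function(H) {
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Hi)) return(NULL)
    V <- Hi %*% B %*% Hi
    if (any(!is.finite(V)) || any(diag(V) <= 0)) return(NULL)
    (V + t(V)) / 2
  }
  V1 <- sandwich(hessian_at(pmax(abs(theta), 0.02) * 0.05))
  if (is.null(V1)) return(NULL)
  h2 <- pmin(pmax(sqrt(diag(V1)), 1e-3), pmax(abs(theta), 0.02) * 0.25)
  V2 <- sandwich(hessian_at(h2))
  if (is.null(V2)) V1 else V2
}

# Pairs (case-resampling) bootstrap covariance: resample experiments with
# replacement, refit warm-started from the full-data optimum with a reduced
# iteration budget, and take the empirical covariance of the refitted
# parameters. Deterministic under the settings seed.
fit_vcov_bootstrap <- function(theta, data, sf_levels, intercept, objective,
                               n_boot, settings) {
  n <- nrow(data)
  est <- with_preserved_seed(settings$multistart_seed + 1L, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      prep_b <- prepare_fit_data(data[idx, , drop = FALSE], sf_levels)
      obj <- function(th) flint_objective(th, prep_b, intercept, objective)
      o <- stats::optim(theta, obj, method = "Nelder-Mead",
                        control = list(maxit = 600,
                                       reltol = settings$optim_reltol))
      o$par
    }, theta))
  })
  V <- stats::cov(est)
  dimnames(V) <- NULL
  V
}

#' Bayesian information criterion for a least-squares fit
#'
#' Gaussian-residual convention: \eqn{BIC = n \ln(Q/n) + k \ln n} where `Q`
#' is the minimised objective, `n` the number of observations (here,
#' survival curves) and `k` the number of free parameters. Only differences
#' between BIC values of fits to the same data are meaningful. A
#' non-positive objective (attainable on noiseless data) is floored before
#' the logarithm.
#'
#' @param objective_value minimised objective.
#' @param n number of observations; must exceed `k`.
#' @param k number of free parameters.
#' @param settings an [rbe_settings] object (supplies the floor).
#' @return BIC value (smaller is better).
#' @export
#' @examples
#' bic(10, n = 10, k = 0) # 10*log(1) = 0
bic <- function(objective_value, n, k, settings = rbe_settings()) {
  if (n <= k) stop("BIC requires n > k")
  q <- max(objective_value, settings$objective_floor)
  n * log(q / n) + k * log(n)
}

#' Fit the six-parameter proton RBE model
#'
#' Fits LET-dependent slope and intercept laws for a set of survival
#' endpoints (by default the two the model is built on, \eqn{e^{-1}} and
#' \eqn{e^{-3}}, giving six free parameters) to a filtered paired survival
#' table. Each record's predicted endpoints are converted to a predicted
#' proton \eqn{(\alpha, \beta)} by the closed-form constrained
#' reconstruction, and the parameters minimise either
#' \itemize{
#'   \item `objective = "l2"`: the sum over experiments of the normalised L2
#'     distance between predicted and measured survival curves, or
#'   \item `objective = "rbe2gy"`: the residual sum of squares of predicted
#'     vs measured RBE at a 2 Gy proton dose.
#' }
#' Parameter covariance is estimated from the residual Jacobian at the
#' optimum. The fit is deterministic given `start`.
#'
#' @param data a survival table (see [read_survival_table()],
#'   [simulate_survival_data()]), already quality-filtered.
#' @param sf_levels list of survival levels in (0,1) and/or `"SF2Gy"`.
#' @param intercept intercept family: `"linear"` (default, \eqn{pL}),
#'   `"constant"`, `"linear_offset"`, or `"exponential"`.
#' @param objective `"l2"` or `"rbe2gy"`.
#' @param start optional numeric start vector (length `k`).
#' @param se how to estimate the parameter covariance: `"sandwich"`
#'   (default) uses the branch-frozen, numerically smoothed M-estimator
#'   sandwich — fast but approximate for the sum-of-norms L2 objective,
#'   whose sample curvature is dominated by near-interpolated records;
#'   `"bootstrap"` resamples experiments with replacement and refits
#'   (`n_boot` warm-started refits — slower, distribution-free);
#'   `"none"` skips covariance estimation (used inside cross-validation
#'   folds).
#' @param n_boot bootstrap resamples for `se = "bootstrap"`.
#' @param settings an [rbe_settings] object.
#' @return An object of class `"rbe_fit"` with components `coefficients`,
#'   `vcov`, `model` (a [flint_model] when the canonical two-endpoint linear
#'   parameterisation is used), `objective_value`, `n`, `k`, `bic`,
#'   `converged`, `data`, and the usual accessor methods.
#' @seealso [predict.rbe_fit()], [loocv()], [compare_models()]
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_survival_data(synth_config(n = 40, seed = 1))
#' f <- rbe_fit(d)
#' coef(f)
rbe_fit <- function(data, sf_levels = list(exp(-1), exp(-3)),
                    intercept = c("linear", "constant", "linear_offset",
                                  "exponential"),
                    objective = c("l2", "rbe2gy"),
                    start = NULL, se = c("sandwich", "bootstrap", "none"),
                    n_boot = 50, settings = rbe_settings()) {
  intercept <- match.arg(intercept)
  objective <- match.arg(objective)
  se <- match.arg(se)
  cl <- match.call()
  if (any(data$beta_p < 0) || any(data$beta_x < 0))
    stop("data contain beta < 0; apply_exclusion_filters() first")
  prep <- prepare_fit_data(data, sf_levels)
  prestage <- is.null(start)  # warm starts skip the smooth pre-stage
  if (is.null(start)) start <- flint_default_start(sf_levels, intercept)
  opt <- flint_minimise(start, prep, intercept, objective, settings,
                        prestage = prestage)
  theta <- opt$par
  names(theta) <- flint_par_names(sf_levels, intercept)
  V <- switch(se,
    sandwich = fit_vcov_sandwich(theta, prep, intercept, objective),
    bootstrap = fit_vcov_bootstrap(theta, data, sf_levels, intercept,
                                   objective, n_boot, settings),
    none = NULL)
  if (!is.null(V)) dimnames(V) <- list(names(theta), names(theta))
  k <- length(theta)
  canonical <- intercept == "linear" && length(sf_levels) == 2L &&
    !any(vapply(sf_levels, identical, TRUE, y = "SF2Gy")) &&
    isTRUE(all.equal(unlist(sf_levels), c(exp(-1), exp(-3))))
  model <- if (canonical)
    theta_model(unname(theta), cov = if (!is.null(V)) unname(V) else NULL)
  structure(list(coefficients = theta, vcov = V, model = model,
                 objective = objective, objective_value = opt$value,
                 n = prep$n, k = k,
                 bic = bic(opt$value, prep$n, k, settings),
                 converged = opt$converged, sf_levels = sf_levels,
                 intercept = intercept, data = data, settings = settings,
                 call = cl),
            class = "rbe_fit")
}

#' @export
print.rbe_fit <- function(x, ...) {
  cat("Proton RBE model fit (", length(x$sf_levels), " endpoints, ",
      x$intercept, " intercept, objective = ", x$objective, ")\n", sep = "")
  print(round(x$coefficients, 6))
  cat(sprintf("n = %d curves, k = %d parameters, objective = %.6g, BIC = %.2f\n",
              x$n, x$k, x$objective_value, x$bic))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.rbe_fit <- function(object, ...) object$coefficients

#' @export
vcov.rbe_fit <- function(object, ...) object$vcov

#' @export
summary.rbe_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0))
  else rep(NA_real_, object$k)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  structure(list(coefficients = tab, n = object$n, k = object$k,
                 objective = object$objective,
                 objective_value = object$objective_value, bic = object$bic,
                 converged = object$converged),
            class = "summary.rbe_fit")
}

#' @export
print.summary.rbe_fit <- function(x, ...) {
  cat("Six-parameter proton RBE model — summary\n")
  stats::printCoefmat(x$coefficients, digits = 5)
  cat(sprintf("\nObjective (%s): %.6g on n = %d curves; BIC = %.2f\n",
              x$objective, x$objective_value, x$n, x$bic))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Predict from a fitted proton RBE model
#'
#' @param object an [rbe_fit].
#' @param newdata data.frame with columns `alpha_x`, `beta_x`,
#'   `let_d_kev_um` (defaults to the training data).
#' @param type `"parameters"` (predicted proton alpha/beta), `"rbe"` (needs
#'   `dose` or `sf`), or `"endpoints"` (predicted proton iso-survival doses).
#' @param dose,sf evaluation point for `type = "rbe"`: physical proton dose
#'   (Gy) or survival level.
#' @param se.fit return delta-method standard errors (canonical two-endpoint
#'   fits only).
#' @param ... unused.
#' @return A data.frame (or vector for `type = "rbe"` without `se.fit`).
#' @export
predict.rbe_fit <- function(object, newdata = NULL,
                            type = c("parameters", "rbe", "endpoints"),
                            dose = NULL, sf = NULL, se.fit = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  prep <- prepare_fit_data(newdata, object$sf_levels)
  pr <- flint_predict_ab(object$coefficients, prep, object$intercept)
  if (type == "parameters" && !se.fit)
    return(data.frame(alpha_p = pr$alpha, beta_p = pr$beta))
  if (type == "endpoints") {
    fam <- intercept_families[[object$intercept]]
    per <- 2L + fam$npar
    out <- sapply(seq_len(prep$m), function(j) {
      th <- object$coefficients[((j - 1L) * per + 1L):(j * per)]
      th[1] * exp(-th[2] * prep$let) * prep$vx[, j] +
        fam$fn(prep$let, th[-(1:2)])
    })
    out <- matrix(out, nrow = prep$n)
    colnames(out) <- paste0("endpoint", seq_len(prep$m))
    return(as.data.frame(out))
  }
  if (type == "rbe" && !se.fit) {
    if (is.null(dose) == is.null(sf))
      stop("supply exactly one of `dose` or `sf`")
    if (!is.null(dose))
      return(rbe_at_dose_vec(prep$alpha_x, prep$beta_x, pr$alpha, pr$beta, dose))
    return(lq_dose_root(prep$alpha_x, prep$beta_x, sf) /
             lq_dose_root(pr$alpha, pr$beta, sf))
  }
  # se.fit path: per-record delta method through the full machinery
  if (is.null(object$model))
    stop("se.fit is available for canonical two-endpoint linear fits only")
  rows <- lapply(seq_len(nrow(newdata)), function(i) {
    ph <- record_lq(newdata[i, ], "x")
    u <- prediction_uncertainty(ph, newdata$let_d_kev_um[i], object$model,
                                dose = dose, sf = sf,
                                what = if (type == "rbe") "rbe" else "curve")
    if (type == "rbe") data.frame(rbe = u$value, stderr = u$stderr)
    else data.frame(alpha_p = u$curve$alpha, beta_p = u$curve$beta,
                    se_alpha = u$stderr[1], se_beta = u$stderr[2])
  })
  do.call(rbind, rows)
}

#' Residuals of a proton RBE model fit
#'
#' @param object an [rbe_fit].
#' @param type `"l2"` for per-experiment normalised curve distances (the
#'   components of the L2 objective) or `"rbe2gy"` for RBE-at-2-Gy
#'   differences (predicted minus measured).
#' @param ... unused.
#' @return Numeric vector, one element per training curve.
#' @export
residuals.rbe_fit <- function(object, type = c("l2", "rbe2gy"), ...) {
  type <- match.arg(type)
  prep <- prepare_fit_data(object$data, object$sf_levels)
  r <- flint_residuals(object$coefficients, prep, object$intercept, type)
  if (type == "l2") as.numeric(r)^2 else as.numeric(r)
}

#' Simulate paired survival datasets from a fitted model
#'
#' Draws new synthetic survival tables whose proton endpoints follow the
#' fitted slope/intercept laws (canonical two-endpoint fits only), using the
#' package's generator.
#'
#' @param object an [rbe_fit] with a canonical two-endpoint model.
#' @param nsim number of datasets.
#' @param seed integer seed (mandatory for reproducibility).
#' @param n records per dataset (defaults to the training size).
#' @param ... passed to [synth_config()].
#' @return A list of `nsim` survival tables.
#' @export
simulate.rbe_fit <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  if (is.null(object$model))
    stop("simulate() needs a canonical two-endpoint linear fit")
  if (is.null(seed)) stop("`seed` is required")
  lapply(seq_len(nsim), function(i) {
    cfg <- synth_config(n = n, true_params = object$model,
                        seed = seed + i - 1L, ...)
    simulate_survival_data(cfg)
  })
}

#' Diagnostic plot of a proton RBE model fit
#'
#' Scatter of measured vs predicted proton iso-survival dose at the model's
#' first endpoint, with the identity line; points coloured by LET tertile.
#'
#' @param x an [rbe_fit].
#' @param ... passed to [graphics::plot()].
#' @export
plot.rbe_fit <- function(x, ...) {
  prep <- prepare_fit_data(x$data, x$sf_levels)
  pr <- flint_predict_ab(x$coefficients, prep, x$intercept)
  lev <- x$sf_levels[[1]]
  if (identical(lev, "SF2Gy")) {
    meas <- exp(-prep$alpha_p * 2 - prep$beta_p * 4)
    pred <- exp(-pr$alpha * 2 - pr$beta * 4)
    lab <- "SF at 2 Gy"
  } else {
    meas <- lq_dose_root(prep$alpha_p, prep$beta_p, lev)
    pred <- lq_dose_root(pr$alpha, pr$beta, lev)
    lab <- sprintf("D at SF = %.3g (Gy)", lev)
  }
  tert <- cut(prep$let, stats::quantile(prep$let, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  graphics::plot(meas, pred, col = tert + 1, pch = 19,
                 xlab = paste("measured", lab), ylab = paste("predicted", lab),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
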