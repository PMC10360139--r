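#' Linear-quadratic survival-curve parameters
#'
#' Container for the parameters of one linear-quadratic (LQ) survival curve,
#' \eqn{SF(D) = \exp(-\alpha D - \beta D^2)}, optionally with the 2x2
#' covariance matrix of \eqn{(\alpha, \beta)} from the curve fit. Negative
#' \eqn{\alpha} or \eqn{\beta} are representable (unconstrained fits can
#' produce them) but most operations require a usable curve: \eqn{\beta \ge 0}
#' and \eqn{\alpha + \beta > 0}.
#'
#' @param alpha linear coefficient, 1/Gy.
#' @param beta quadratic coefficient, 1/Gy^2.
#' @param cov optional 2x2 symmetric covariance matrix of `(alpha, beta)`.
#' @return An object of class `"lq"`.
#' @export
#' @examples
#' lq(0.2, 0.05)
lq <- function(alpha, beta, cov = NULL) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(alpha) == 1L, length(beta) == 1L,
            is.finite(alpha), is.finite(beta))
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (!all(dim(cov) == c(2L, 2L)))
      stop("`cov` must be a 2x2 matrix")
    if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov))))
      stop("`cov` must be symmetric")
    if (any(diag(cov) < 0))
      stop("`cov` must have non-negative diagonal")
    dimnames(cov) <- list(c("alpha", "beta"), c("alpha", "beta"))
  }
  structure(list(alpha = alpha, beta = beta, cov = cov), class = "lq")
}

#' @export
print.lq <- function(x, ...) {
  cat(sprintf("LQ curve: alpha = %.6g /Gy, beta = %.6g /Gy^2%s\n",
              x$alpha, x$beta,
              if (is.null(x$cov)) "" else " (with covariance)"))
  invisible(x)
}

check_usable_lq <- function(params, require_beta_nonneg = TRUE) {
  if (!inherits(params, "lq")) params <- lq(params[[1]], params[[2]])
  if (require_beta_nonneg && params$beta < 0)
    stop("beta < 0: survival integrals diverge; curve not usable here")
  if (params$alpha + params$beta <= 0)
    stop("degenerate curve: alpha = beta = 0 (or negative) is rejected")
  params
}

#' Surviving fraction under the linear-quadratic model
#'
#' @param params an [lq] object (or 2-element list with `alpha`, `beta`).
#' @param dose absorbed dose in Gy; may be a vector. Must be non-negative.
#' @return Surviving fraction(s) \eqn{\exp(-\alpha D - \beta D^2)}.
#' @export
#' @examples
#' surviving_fraction(lq(0.2, 0.05), 2) # exp(-0.6)
surviving_fraction <- function(params, dose) {
  if (any(dose < 0)) stop("negative dose rejected")
  if (!inherits(params, "lq")) params <- lq(params[[1]], params[[2]])
  exp(-params$alpha * dose - params$beta * dose^2)
}

# Vectorised positive root of beta*D^2 + alpha*D + log(sf) = 0, written in
# the cancellation-free form 2L / (alpha + sqrt(alpha^2 + 4*beta*L)),
# L = -log(sf). Valid for beta = 0 (reduces to L/alpha) and alpha = 0
# (reduces to sqrt(L/beta)).
lq_dose_root <- function(alpha, beta, sf) {
  L <- -log(sf)
  2 * L / (alpha + sqrt(alpha^2 + 4 * beta * L))
}

#' Iso-survival dose of an LQ curve
#'
#' Returns the dose at which the survival curve crosses a given survival
#' fraction: the unique positive root of
#' \eqn{\beta D^2 + \alpha D + \ln(sf) = 0}. The negative root of the
#' quadratic is discarded.
#'
#' @inheritParams surviving_fraction
#' @param sf target survival fraction, strictly inside (0, 1); vectorised.
#' @return Dose(s) in Gy.
#' @export
#' @examples
#' dose_for_sf(lq(0.5, 0), 0.1) # -log(0.1)/0.5
dose_for_sf <- function(params, sf) {
  if (any(sf <= 0 | sf >= 1)) stop("`sf` must lie strictly in (0, 1)")
  params <- check_usable_lq(params, require_beta_nonneg = FALSE)
  if (params$beta < 0)
    warning("beta < 0: iso-survival dose of a non-monotone LQ curve; ",
            "returning the smaller positive root")
  lq_dose_root(params$alpha, params$beta, sf)
}

# Scaled complementary error function erfcx(x) = exp(x^2) erfc(x) for
# x >= 0, via the log of the normal tail: erfc(x) = 2 pnorm(-x sqrt(2)), so
# erfcx(x) = 2 exp(x^2 + log pnorm(-x sqrt(2))). pnorm's log tail stays
# accurate far beyond where the product exp(x^2) * erfc(x) overflows /
# underflows (pracma::erfcx returns NaN above x ~ 27).
erfcx_nonneg <- function(x) {
  out <- numeric(length(x))
  small <- x < 15
  # below x = 15 the exponent sum x^2 + log(tail) is O(225), so the double
  # rounding of the exponent costs < 1e-13 relative
  out[small] <- 2 * exp(x[small]^2 +
                          stats::pnorm(-x[small] * sqrt(2), log.p = TRUE))
  if (any(!small)) {
    # asymptotic series 1/(x sqrt(pi)) (1 - 1/(2x^2) + 3/(4x^4) - ...);
    # truncation error < 1e-12 relative for x >= 15
    z <- 1 / (2 * x[!small]^2)
    out[!small] <- (1 - z + 3 * z^2 - 15 * z^3 + 105 * z^4) /
      (x[!small] * sqrt(pi))
  }
  out
}

# integral_0^inf exp(-a*D - b*D^2) dD, closed form.
# b > 0: sqrt(pi/(4b)) * exp(a^2/(4b)) * erfc(a/(2 sqrt(b)))
#      = sqrt(pi/(4b)) * erfcx(a/(2 sqrt(b)))   (overflow-safe)
# b = 0: 1/a (requires a > 0).
exp_lq_integral <- function(a, b) {
  out <- numeric(length(a))
  b <- rep_len(b, length(a))
  pos <- b > 0
  if (any(pos))
    out[pos] <- sqrt(pi / (4 * b[pos])) * erfcx_nonneg(a[pos] / (2 * sqrt(b[pos])))
  if (any(!pos)) {
    if (any(b[!pos] < 0)) stop("divergent integral: beta < 0")
    if (any(a[!pos] <= 0)) stop("divergent integral: alpha = beta = 0")
    out[!pos] <- 1 / a[!pos]
  }
  out
}

#' Mean inactivation dose
#'
#' The area under the survival curve, \eqn{\bar D = \int_0^\infty SF(D)\,dD},
#' a dose-like summary of overall radiosensitivity used here to normalise
#' curve distances. Computed in closed form via the scaled complementary
#' error function for \eqn{\beta > 0} and as \eqn{1/\alpha} for
#' \eqn{\beta = 0}.
#'
#' @inheritParams surviving_fraction
#' @return Mean inactivation dose in Gy.
#' @export
#' @examples
#' mean_inactivation_dose(lq(1, 0))  # 1
#' mean_inactivation_dose(lq(0, 1))  # sqrt(pi)/2
mean_inactivation_dose <- function(params) {
  params <- check_usable_lq(params)
  exp_lq_integral(params$alpha, params$beta)
}

#' Normalised L2 distance between two survival curves
#'
#' Root-integrated squared difference between two LQ survival curves over
#' \eqn{D \in [0, \infty)}, normalised by the mean inactivation dose of the
#' *measured* curve:
#' \deqn{d = \sqrt{\int_0^\infty (SF_{pred} - SF_{meas})^2 dD} \; / \; \bar D_{meas}.}
#' The numerator is symmetric in its arguments; the normalisation is not
#' (swapping `pred` and `meas` changes the result). This convention is the
#' package's fixed choice and is isolated here so it can be swapped.
#' All three integrals have closed forms.
#'
#' @param pred,meas [lq] curves (both must have \eqn{\beta \ge 0}).
#' @return Dimensionless distance; zero iff the curves are identical.
#' @export
#' @examples
#' curve_l2_distance(lq(1, 0), lq(2, 0)) # sqrt(1/12)/0.5
curve_l2_distance <- function(pred, meas) {
  pred <- check_usable_lq(pred)
  meas <- check_usable_lq(meas)
  d2 <- exp_lq_integral(2 * pred$alpha, 2 * pred$beta) -
    2 * exp_lq_integral(pred$alpha + meas$alpha, pred$beta + meas$beta) +
    exp_lq_integral(2 * meas$alpha, 2 * meas$beta)
  sqrt(max(d2, 0)) / exp_lq_integral(meas$alpha, meas$beta)
}

# Vectorised version over parallel parameter vectors; used by the fitting
# engine. All inputs are equal-length vectors with beta >= 0.
curve_l2_distance_vec <- function(alpha_pred, beta_pred, alpha_meas, beta_meas) {
  d2 <- exp_lq_integral(2 * alpha_pred, 2 * beta_pred) -
    2 * exp_lq_integral(alpha_pred + alpha_meas, beta_pred + beta_meas) +
    exp_lq_integral(2 * alpha_meas, 2 * beta_meas)
  sqrt(pmax(d2, 0)) / exp_lq_integral(alpha_meas, beta_meas)
}

#' RBE at iso-survival
#'
#' Ratio of the photon dose to the proton dose producing the same survival
#' fraction: \eqn{RBE_{SF} = D_{SF,photon} / D_{SF,proton}}.
#'
#' @param photon,proton [lq] curves.
#' @param sf survival level in (0, 1); vectorised.
#' @return Dimensionless RBE.
#' @export
rbe_at_iso_survival <- function(photon, proton, sf) {
  dose_for_sf(photon, sf) / dose_for_sf(proton, sf)
}

#' RBE at a proton dose
#'
#' Iso-effect RBE at a given physical proton dose \eqn{d}: the photon dose
#' \eqn{D_x} with \eqn{SF_{photon}(D_x) = SF_{proton}(d)}, divided by
#' \eqn{d}.
#'
#' @param photon,proton [lq] curves.
#' @param proton_dose physical proton dose in Gy, > 0; vectorised.
#' @return Dimensionless RBE.
#' @export
rbe_at_dose <- function(photon, proton, proton_dose) {
  if (any(proton_dose <= 0)) stop("`proton_dose` must be positive")
  photon <- check_usable_lq(photon, require_beta_nonneg = FALSE)
  proton <- check_usable_lq(proton, require_beta_nonneg = FALSE)
  sfp <- surviving_fraction(proton, proton_dose)
  lq_dose_root(photon$alpha, photon$beta, sfp) / proton_dose
}

#' Delta-method standard error of an iso-survival dose
#'
#' First-order propagation of the \eqn{(\alpha,\beta)} covariance into
#' \eqn{D_{SF}}. With \eqn{L = -\ln sf} and \eqn{D} the iso-survival dose,
#' the gradient is \eqn{\partial D/\partial\alpha = -D/(\alpha + 2\beta D)}
#' and \eqn{\partial D/\partial\beta = -D^2/(\alpha + 2\beta D)}. Both
#' components share the same sign, so a negative \eqn{\alpha}-\eqn{\beta}
#' covariance reduces the propagated error relative to ignoring it — the
#' reason iso-survival doses are better determined than \eqn{\alpha} or
#' \eqn{\beta} individually.
#'
#' @param params an [lq] object carrying a covariance matrix.
#' @param sf survival level in (0, 1).
#' @return Standard error of \eqn{D_{SF}} in Gy.
#' @export
propagate_endpoint_error <- function(params, sf) {
  params <- check_usable_lq(params)
  if (is.null(params$cov)) stop("`params` must carry a covariance matrix")
  D <- dose_for_sf(params, sf)
  denom <- params$alpha + 2 * params$beta * D
  g <- c(-D / denom, -D^2 / denom)
  sqrt(max(drop(t(g) %*% params$cov %*% g), 0))
}

#' Fit the linear-quadratic model to log-survival data
#'
#' Least-squares fit of \eqn{\log SF = -\alpha D - \beta D^2} (regression
#' through the origin in the design \eqn{(D, D^2)}), optionally weighted and
#' optionally constrained to \eqn{\alpha \ge 0, \beta \ge 0}. With exactly
#' two distinct doses and a feasible unconstrained solution the fit
#' interpolates both points exactly. The covariance matrix comes from the fit
#' Jacobian and residual variance; it is `NULL` when there are no residual
#' degrees of freedom.
#'
#' @param doses dose vector in Gy (at least two distinct values).
#' @param log_sf natural-log survival fractions at `doses`.
#' @param weights optional non-negative weights.
#' @param constrain_nonneg clamp negative parameters to zero and re-solve the
#'   remaining parameter (the usual constrained LQ fit).
#' @return An [lq] object with a `cov` matrix when estimable.
#' @export
#' @examples
#' fit_lq(c(1, 3), c(-1, -3)) # alpha = 1, beta = 0
fit_lq <- function(doses, log_sf, weights = NULL, constrain_nonneg = TRUE) {
  stopifnot(length(doses) == length(log_sf), length(doses) >= 2)
  if (length(unique(doses)) < 2) stop("need at least two distinct doses")
  if (is.null(weights)) weights <- rep(1, length(doses))
  y <- -log_sf
  X <- cbind(D = doses, D2 = doses^2)
  fit <- stats::lm.wfit(X, y, w = weights)
  ab <- fit$coefficients
  covm <- lq_fit_cov(X, y, weights, ab)
  if (constrain_nonneg && (ab[1] < 0 || ab[2] < 0)) {
    cand <- list()
    # alpha-only (beta = 0) and beta-only (alpha = 0) boundary solutions
    a1 <- max(0, sum(weights * doses * y) / sum(weights * doses^2))
    b1 <- max(0, sum(weights * doses^2 * y) / sum(weights * doses^4))
    rss <- function(a, b) sum(weights * (y - a * doses - b * doses^2)^2)
    cand <- list(c(a1, 0), c(0, b1))
    pick <- cand[[which.min(vapply(cand, function(p) rss(p[1], p[2]), 0))]]
    ab <- pick
    covm <- NULL
    if (ab[1] == 0) {
      v <- boundary_var(doses^2, y, weights, ab[2])
      if (!is.null(v)) covm <- matrix(c(0, 0, 0, v), 2)
    } else if (ab[2] == 0) {
      v <- boundary_var(doses, y, weights, ab[1])
      if (!is.null(v)) covm <- matrix(c(v, 0, 0, 0), 2)
    }
  }
  lq(unname(ab[1]), unname(ab[2]), cov = covm)
}

lq_fit_cov <- function(X, y, w, ab) {
  df <- nrow(X) - ncol(X)
  if (df < 1) return(NULL)
  r <- y - X %*% ab
  s2 <- sum(w * r^2) / df
  XtX <- crossprod(X * sqrt(w))
  s2 * solve(XtX)
}

boundary_var <- function(x, y, w, coef) {
  df <- length(y) - 1L
  if (df < 1) return(NULL)
  s2 <- sum(w * (y - coef * x)^2) / df
  s2 / sum(w * x^2)
}
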