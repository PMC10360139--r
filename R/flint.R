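#' Endpoint-function parameters (c, f, p)
#'
#' One survival endpoint's LET laws: the correlation slope decays
#' exponentially with LET, \eqn{slope(L) = c\,e^{-fL}}, and the intercept
#' grows linearly, \eqn{intercept(L) = p\,L}. Fitted values are expected
#' positive but negatives are representable (optimizers may explore them).
#'
#' @param c dimensionless slope amplitude (slope at LET = 0).
#' @param f slope decay rate per (keV/um).
#' @param p intercept rate, Gy per (keV/um).
#' @return An object of class `"endpoint_params"`.
#' @export
endpoint_params <- function(c, f, p) {
  stopifnot(is.numeric(c), is.numeric(f), is.numeric(p))
  structure(list(c = c, f = f, p = p), class = "endpoint_params")
}

#' Correlation slope at a given LET
#'
#' \eqn{slope(L) = c\,e^{-fL}}: equals `c` at LET 0 and decreases strictly
#' with LET when `f > 0`.
#'
#' @param let dose-weighted LET, keV/um (vectorised, >= 0).
#' @param params an [endpoint_params] object.
#' @return Dimensionless slope.
#' @export
slope_at_let <- function(let, params) {
  if (any(let < 0)) stop("`let` must be non-negative")
  params$c * exp(-params$f * let)
}

#' Correlation intercept at a given LET
#'
#' \eqn{intercept(L) = p\,L} (Gy); zero at LET 0.
#'
#' @inheritParams slope_at_let
#' @return Intercept in Gy.
#' @export
intercept_at_let <- function(let, params) {
  if (any(let < 0)) stop("`let` must be non-negative")
  params$p * let
}

#' Predict a proton iso-survival dose from the photon one
#'
#' The defining linear correlation: at fixed LET the proton endpoint is an
#' affine function of the photon endpoint,
#' \eqn{D_{SF,proton} = slope(L)\,D_{SF,photon} + intercept(L)}.
#'
#' @param d_x photon iso-survival dose, Gy (> 0; vectorised).
#' @inheritParams slope_at_let
#' @return Predicted proton iso-survival dose, Gy.
#' @export
predict_endpoint <- function(d_x, let, params) {
  if (any(d_x <= 0)) stop("photon endpoint must be positive")
  slope_at_let(let, params) * d_x + intercept_at_let(let, params)
}

#' Six-parameter proton RBE model
#'
#' Bundles the endpoint-function parameters for the two survival levels the
#' model is built on, \eqn{SF_1 = e^{-1}} and \eqn{SF_2 = e^{-3}}, with an
#' optional 6x6 covariance ordered `(c1, f1, p1, c2, f2, p2)`.
#'
#' @param sf1_params,sf2_params [endpoint_params] for the \eqn{e^{-1}} and
#'   \eqn{e^{-3}} endpoints.
#' @param cov optional 6x6 symmetric covariance matrix.
#' @return An object of class `"flint_model"`.
#' @seealso [flint_default_model()] for the shipped fitted parameters.
#' @export
flint_model <- function(sf1_params, sf2_params, cov = NULL) {
  stopifnot(inherits(sf1_params, "endpoint_params"),
            inherits(sf2_params, "endpoint_params"))
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    if (!all(dim(cov) == c(6L, 6L))) stop("`cov` must be 6x6")
    if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov))))
      stop("`cov` must be symmetric")
    nm <- c("c1", "f1", "p1", "c2", "f2", "p2")
    dimnames(cov) <- list(nm, nm)
  }
  structure(list(sf1_params = sf1_params, sf2_params = sf2_params, cov = cov),
            class = "flint_model")
}

#' @export
print.flint_model <- function(x, ...) {
  cat("Six-parameter proton RBE model (endpoints SF = e^-1, e^-3)\n")
  cat(sprintf("  e^-1: c1 = %.6g, f1 = %.6g /(keV/um), p1 = %.6g Gy/(keV/um)\n",
              x$sf1_params$c, x$sf1_params$f, x$sf1_params$p))
  cat(sprintf("  e^-3: c2 = %.6g, f2 = %.6g /(keV/um), p2 = %.6g Gy/(keV/um)\n",
              x$sf2_params$c, x$sf2_params$f, x$sf2_params$p))
  if (!is.null(x$cov)) cat("  (6x6 parameter covariance attached)\n")
  invisible(x)
}

#' Shipped default model parameters
#'
#' The fitted six-parameter values and their full covariance obtained by
#' minimising the normalised survival-curve L2 distance over the 397
#' cell-line/LET training compilation, as published with the model.
#'
#' @return A [flint_model] with covariance.
#' @export
#' @examples
#' m <- flint_default_model()
#' slope_at_let(0, m$sf1_params) # 1.041543
flint_default_model <- function() {
  v <- c(c1 = 1.041543e+00, f1 = 4.708586e-02, p1 = 2.376115e-02,
         c2 = 1.045578e+00, f2 = 3.213278e-02, p2 = 6.550494e-02)
  se <- c(2.439889e-02, 7.931656e-03, 9.021992e-03,
          5.593340e-02, 1.341988e-02, 3.257196e-02)
  cv <- diag(se^2)
  off <- rbind(
    c(1, 2,  1.072615e-04), c(1, 3,  6.169650e-05), c(1, 4,  1.783393e-04),
    c(1, 5, -2.609667e-05), c(1, 6, -8.508367e-05), c(2, 3,  6.242400e-05),
    c(2, 4, -4.298168e-05), c(2, 5, -2.548386e-05), c(2, 6, -6.796549e-05),
    c(3, 4, -6.503621e-05), c(3, 5, -2.627735e-05), c(3, 6, -7.880709e-05),
    c(4, 5,  3.983314e-04), c(4, 6,  6.113882e-04), c(5, 6,  4.084385e-04))
  cv[off[, 1:2]] <- off[, 3]
  cv[off[, 2:1]] <- off[, 3]
  flint_model(endpoint_params(v[["c1"]], v[["f1"]], v[["p1"]]),
              endpoint_params(v[["c2"]], v[["f2"]], v[["p2"]]),
              cov = cv)
}

model_theta <- function(model) {
  c(c1 = model$sf1_params$c, f1 = model$sf1_params$f, p1 = model$sf1_params$p,
    c2 = model$sf2_params$c, f2 = model$sf2_params$f, p2 = model$sf2_params$p)
}

theta_model <- function(theta, cov = NULL) {
  flint_model(endpoint_params(theta[[1]], theta[[2]], theta[[3]]),
              endpoint_params(theta[[4]], theta[[5]], theta[[6]]), cov = cov)
}

# --- closed-form reconstruction of (alpha, beta) from iso-survival points ---

# Vectorised constrained zero-intercept LQ regression through endpoint sets.
# D, logSF: matrices (rows = cases, cols = endpoints). Returns data.frame
# with alpha, beta, branch. Solves
#   min_{alpha,beta >= 0} sum_j (alpha D_j + beta D_j^2 + logSF_j)^2
# via the unconstrained normal equations
#   alpha = (S4 T1 - S3 T2) / (S3^2 - S2 S4)
#   beta  = (S2 T2 - S3 T1) / (S3^2 - S2 S4)
# with Sk = sum D^k, Tk = sum D^k logSF, falling back to the boundary
# solutions alpha|beta=0 = -T1/S2, beta|alpha=0 = -T2/S4 and keeping the
# feasible candidate with the smaller residual (for a convex 2-parameter
# problem this candidate set is exhaustive).
reconstruct_ab_matrix <- function(D, logSF, force_branch = NULL) {
  S2 <- rowSums(D^2); S3 <- rowSums(D^3); S4 <- rowSums(D^4)
  T1 <- rowSums(D * logSF); T2 <- rowSums(D^2 * logSF)
  den <- S3^2 - S2 * S4
  a_u <- (S4 * T1 - S3 * T2) / den
  b_u <- (S2 * T2 - S3 * T1) / den
  a_b0 <- pmax(0, -T1 / S2)       # beta clamped to 0
  b_a0 <- pmax(0, -T2 / S4)       # alpha clamped to 0
  if (is.null(force_branch)) {
    rss <- function(a, b) rowSums((a * D + b * D^2 + logSF)^2)
    r_u <- rss(a_u, b_u)
    r_b0 <- rss(a_b0, 0)
    r_a0 <- rss(0, b_a0)
    feasible_u <- a_u >= 0 & b_u >= 0
    r_u[!feasible_u] <- Inf
    pick <- max.col(-cbind(r_u, r_b0, r_a0), ties.method = "first")
  } else {
    pick <- match(force_branch, c("unconstrained", "beta0", "alpha0"))
  }
  alpha <- ifelse(pick == 1, a_u, ifelse(pick == 2, a_b0, 0))
  beta <- ifelse(pick == 1, b_u, ifelse(pick == 2, 0, b_a0))
  data.frame(alpha = alpha, beta = beta,
             branch = c("unconstrained", "beta0", "alpha0")[pick])
}

#' Reconstruct an LQ curve from a set of iso-survival endpoints
#'
#' Given endpoint pairs \eqn{(SF_j, D_j)}, solves the zero-intercept
#' regression \eqn{\min \sum_j (\alpha D_j + \beta D_j^2 + \ln SF_j)^2}
#' by the closed-form normal equations, with constrained fallbacks
#' (\eqn{\alpha = -\sum D \ln SF / \sum D^2} when \eqn{\beta} clamps to zero,
#' and symmetrically) whenever a parameter comes out negative. With exactly
#' two endpoints the unconstrained solution interpolates both points.
#'
#' @param sf vector of survival fractions in (0, 1).
#' @param dose vector of matching doses in Gy (distinct, > 0).
#' @return An [lq] object; attribute `"branch"` records which solution
#'   (unconstrained, `beta0`, `alpha0`) was used.
#' @export
#' @examples
#' reconstruct_alpha_beta(c(exp(-1), exp(-3)), c(1, 3)) # alpha 1, beta 0
reconstruct_alpha_beta <- function(sf, dose) {
  stopifnot(length(sf) == length(dose), length(dose) >= 2)
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(sf <= 0 | sf >= 1)) stop("survival fractions must lie in (0, 1)")
  if (length(unique(dose)) < length(dose)) stop("coincident doses")
  res <- reconstruct_ab_matrix(matrix(dose, nrow = 1),
                               matrix(log(sf), nrow = 1))
  structure(lq(res$alpha, res$beta), branch = res$branch)
}

#' Two-point reconstruction at SF = e^-1 and e^-3
#'
#' Closed-form \eqn{(\alpha, \beta)} through the two iso-survival points
#' \eqn{(d_1, e^{-1})} and \eqn{(d_2, e^{-3})}:
#' \deqn{\alpha = \frac{(d_1^3+d_2^3)(d_1^2+3d_2^2)-(d_1^4+d_2^4)(d_1+3d_2)}
#'                     {(d_1^3+d_2^3)^2-(d_1^2+d_2^2)(d_1^4+d_2^4)}}
#' and the matching expression for \eqn{\beta}; if either comes out negative
#' it is clamped to zero and the other parameter re-solved
#' (\eqn{\alpha|_{\beta=0}=(d_1+3d_2)/(d_1^2+d_2^2)},
#' \eqn{\beta|_{\alpha=0}=(d_1^2+3d_2^2)/(d_1^4+d_2^4)}). When the
#' unconstrained solution is feasible the returned curve passes exactly
#' through both points.
#'
#' @param d1 dose at survival \eqn{e^{-1}}, Gy.
#' @param d2 dose at survival \eqn{e^{-3}}, Gy; must exceed `d1`.
#' @return An [lq] object.
#' @export
reconstruct_alpha_beta_two_point <- function(d1, d2) {
  if (any(d1 <= 0) || any(d2 <= 0)) stop("doses must be positive")
  if (any(d2 <= d1))
    stop("d2 <= d1: no LQ curve with non-negative parameters passes through ",
         "inverted iso-survival points")
  den <- (d1^3 + d2^3)^2 - (d1^2 + d2^2) * (d1^4 + d2^4)
  alpha <- ((d1^3 + d2^3) * (d1^2 + 3 * d2^2) -
              (d1^4 + d2^4) * (d1 + 3 * d2)) / den
  beta <- ((d1^3 + d2^3) * (d1 + 3 * d2) -
             (d1^2 + d2^2) * (d1^2 + 3 * d2^2)) / den
  if (length(d1) == 1L) {
    branch <- "unconstrained"
    if (beta < 0) {
      beta <- 0; alpha <- (d1 + 3 * d2) / (d1^2 + d2^2); branch <- "beta0"
    } else if (alpha < 0) {
      alpha <- 0; beta <- (d1^2 + 3 * d2^2) / (d1^4 + d2^4); branch <- "alpha0"
    }
    return(structure(lq(alpha, beta), branch = branch))
  }
  neg_b <- beta < 0
  alpha[neg_b] <- (d1[neg_b] + 3 * d2[neg_b]) / (d1[neg_b]^2 + d2[neg_b]^2)
  beta[neg_b] <- 0
  neg_a <- !neg_b & alpha < 0
  beta[neg_a] <- (d1[neg_a]^2 + 3 * d2[neg_a]^2) / (d1[neg_a]^4 + d2[neg_a]^4)
  alpha[neg_a] <- 0
  data.frame(alpha = alpha, beta = beta)
}

#' Predict a proton survival curve from a photon curve and LET
#'
#' Maps the photon curve's iso-survival doses at \eqn{e^{-1}} and
#' \eqn{e^{-3}} through the model's two endpoint laws and reconstructs the
#' proton \eqn{(\alpha, \beta)} from the predicted pair. With identity
#' parameters (`c = 1`, `f = 0`, `p = 0` at both endpoints) the photon curve
#' is returned unchanged.
#'
#' @param photon photon [lq] curve.
#' @param let dose-weighted LET, keV/um (scalar here; see
#'   [rbe_weighted_dose()] for the vectorised voxel path).
#' @param model a [flint_model]; defaults to the shipped parameters.
#' @return Predicted proton [lq] curve.
#' @export
#' @examples
#' predict_proton_curve(lq(0.3, 0.03), let = 9.9)
predict_proton_curve <- function(photon, let, model = flint_default_model()) {
  photon <- check_usable_lq(photon)
  d1x <- dose_for_sf(photon, exp(-1))
  d2x <- dose_for_sf(photon, exp(-3))
  d1p <- predict_endpoint(d1x, let, model$sf1_params)
  d2p <- predict_endpoint(d2x, let, model$sf2_params)
  if (d1p <= 0 || d2p <= 0)
    stop("model predicts a non-positive proton endpoint; parameters invalid here")
  reconstruct_alpha_beta_two_point(d1p, d2p)
}

#' Predicted proton RBE
#'
#' RBE of the model-predicted proton curve against the input photon curve,
#' either at iso-survival (`sf`) or at a physical proton dose per fraction
#' (`dose`). For a single endpoint the iso-survival form reduces
#' algebraically to
#' \eqn{RBE_{SF} = 1 / (c\,e^{-fL} + pL / D_{SF,photon})}.
#'
#' @inheritParams predict_proton_curve
#' @param dose physical proton dose in Gy (iso-effect RBE), or `NULL`.
#' @param sf survival level in (0, 1) (iso-survival RBE), or `NULL`.
#'   Exactly one of `dose` and `sf` must be given.
#' @return Dimensionless RBE.
#' @export
#' @examples
#' predict_rbe(lq(0.3, 0.03), let = 9.9, dose = 2)
predict_rbe <- function(photon, let, model = flint_default_model(),
                        dose = NULL, sf = NULL) {
  if (is.null(dose) == is.null(sf))
    stop("supply exactly one of `dose` or `sf`")
  proton <- predict_proton_curve(photon, let, model)
  if (!is.null(sf)) rbe_at_iso_survival(photon, proton, sf)
  else rbe_at_dose(photon, proton, dose)
}

#' Delta-method uncertainty of a model prediction
#'
#' Propagates the 6x6 model-parameter covariance and the photon
#' \eqn{(\alpha, \beta)} covariance through the prediction by a first-order
#' (delta-method) expansion with a central-difference Jacobian. The 95%
#' confidence band is \eqn{\pm 1.96} standard errors.
#'
#' @inheritParams predict_rbe
#' @param what `"rbe"` (needs `dose` or `sf`) or `"curve"` (standard errors
#'   of the predicted \eqn{\alpha_p} and \eqn{\beta_p}).
#' @return For `"rbe"`, a list with `value` and `stderr`; for `"curve"`, a
#'   list with the predicted [lq] and `stderr = c(alpha, beta)`.
#' @export
prediction_uncertainty <- function(photon, let, model = flint_default_model(),
                                   dose = NULL, sf = NULL,
                                   what = c("rbe", "curve")) {
  what <- match.arg(what)
  photon <- check_usable_lq(photon)
  if (is.null(model$cov)) stop("model covariance missing")
  pcov <- if (is.null(photon$cov)) matrix(0, 2, 2) else photon$cov
  Sigma <- rbind(cbind(model$cov, matrix(0, 6, 2)),
                 cbind(matrix(0, 2, 6), pcov))
  theta0 <- c(model_theta(model), alpha_x = photon$alpha, beta_x = photon$beta)
  fn <- function(th) {
    m <- theta_model(th[1:6])
    ph <- lq(th[[7]], th[[8]])
    pr <- predict_proton_curve(ph, let, m)
    if (what == "curve") c(pr$alpha, pr$beta)
    else if (!is.null(sf)) rbe_at_iso_survival(ph, pr, sf)
    else rbe_at_dose(ph, pr, dose)
  }
  f0 <- fn(theta0)
  J <- matrix(0, length(f0), length(theta0))
  h <- pmax(abs(theta0), 1e-3) * 1e-6
  for (j in seq_along(theta0)) {
    up <- theta0; up[j] <- up[j] + h[j]
    dn <- theta0; dn[j] <- dn[j] - h[j]
    J[, j] <- (fn(up) - fn(dn)) / (2 * h[j])
  }
  V <- J %*% Sigma %*% t(J)
  se <- sqrt(pmax(diag(V), 0))
  if (what == "curve")
    list(curve = lq(f0[1], f0[2]), stderr = c(alpha = se[1], beta = se[2]))
  else list(value = unname(f0), stderr = unname(se))
}
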