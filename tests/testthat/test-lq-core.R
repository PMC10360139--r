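test_that("surviving fraction evaluates the LQ law and rejects bad input", {
  expect_equal(surviving_fraction(lq(1, 0), 0), 1)
  expect_equal(surviving_fraction(lq(0.5, 0), log(10) / 0.5), 0.1)
  expect_equal(surviving_fraction(lq(0.2, 0.05), 2), exp(-0.6))
  expect_error(surviving_fraction(lq(0.2, 0.05), -1), "negative dose")
})

test_that("iso-survival dose inverts the survival curve", {
  expect_equal(dose_for_sf(lq(0.5, 0), 0.1), log(10) / 0.5)
  expect_equal(dose_for_sf(lq(0, 0.25), exp(-1)), 2)
  # quadratic-formula case, verified by re-substitution
  d <- dose_for_sf(lq(0.3, 0.03), 0.37)
  expect_equal(surviving_fraction(lq(0.3, 0.03), d), 0.37, tolerance = 1e-12)
  expect_error(dose_for_sf(lq(0.3, 0.03), 1.2), "strictly in")
  expect_error(dose_for_sf(lq(0.3, 0.03), 0), "strictly in")
  expect_error(dose_for_sf(lq(0, 0), 0.5), "degenerate")
})

test_that("dose/SF round-trip holds to 1e-10 over the parameter box", {
  set.seed(11)
  for (i in 1:200) {
    p <- random_lq()
    if (p$alpha + p$beta < 1e-3) next
    sf <- runif(1, 0.01, 0.99)
    d <- dose_for_sf(lq(p$alpha, p$beta), sf)
    expect_equal(surviving_fraction(lq(p$alpha, p$beta), d), sf,
                 tolerance = 1e-10)
  }
})

test_that("mean inactivation dose matches closed forms and quadrature", {
  expect_equal(mean_inactivation_dose(lq(1, 0)), 1)
  expect_equal(mean_inactivation_dose(lq(0, 1)), sqrt(pi) / 2,
               tolerance = 1e-12)
  # continuity of the beta -> 0 limit
  expect_equal(mean_inactivation_dose(lq(1, 1e-12)), 1, tolerance = 1e-5)
  set.seed(12)
  for (i in 1:50) {
    p <- random_lq(beta_range = c(1e-4, 0.2))
    mid <- mean_inactivation_dose(lq(p$alpha, p$beta))
    expect_equal(mid, mid_quadrature(p$alpha, p$beta), tolerance = 1e-8)
  }
  expect_error(mean_inactivation_dose(lq(1, -0.01)), "beta < 0")
})

test_that("curve L2 distance has the analytic value and its asymmetry", {
  expect_equal(curve_l2_distance(lq(0.7, 0.05), lq(0.7, 0.05)), 0)
  # int (e^-D - e^-2D)^2 dD = 1/2 - 2/3 + 1/4 = 1/12; MID(meas) = 1/2
  expect_equal(curve_l2_distance(lq(1, 0), lq(2, 0)), sqrt(1 / 12) / 0.5,
               tolerance = 1e-12)
  # numerator symmetric, normalisation not
  d_ab <- curve_l2_distance(lq(1, 0), lq(2, 0))
  d_ba <- curve_l2_distance(lq(2, 0), lq(1, 0))
  expect_equal(d_ab * 0.5, d_ba * 1.0, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(d_ab, d_ba)))
})

test_that("RBE definitions behave at iso-survival and iso-dose", {
  expect_equal(rbe_at_iso_survival(lq(0.3, 0.02), lq(0.3, 0.02), 0.1), 1)
  expect_equal(rbe_at_iso_survival(lq(0.5, 0), lq(1, 0), 0.1), 2)
  expect_equal(rbe_at_dose(lq(0.5, 0), lq(1, 0), 2), 2)
  # quadratic-inversion oracle: solve for the photon dose giving the same SF
  ph <- lq(0.3, 0.03); pr <- lq(0.45, 0.03)
  r <- rbe_at_dose(ph, pr, 2)
  sfp <- surviving_fraction(pr, 2)
  dx <- uniroot(function(D) surviving_fraction(ph, D) - sfp, c(0.1, 50),
                tol = 1e-12)$root
  expect_equal(r, dx / 2, tolerance = 1e-8)
})

test_that("endpoint error propagation uses the covariance correctly", {
  p0 <- lq(0.5, 0, cov = matrix(0, 2, 2))
  expect_equal(propagate_endpoint_error(p0, 0.1), 0)
  # single-variable delta method at beta = 0
  s <- 0.04
  p1 <- lq(0.5, 0, cov = diag(c(s^2, 0)))
  expect_equal(propagate_endpoint_error(p1, 0.1),
               abs(log(0.1)) * s / 0.5^2, tolerance = 1e-12)
  # negative alpha-beta covariance shrinks the error
  v <- diag(c(0.03^2, 0.004^2))
  vneg <- v; vneg[1, 2] <- vneg[2, 1] <- -0.9 * 0.03 * 0.004
  se0 <- propagate_endpoint_error(lq(0.4, 0.04, cov = v), 0.1)
  seneg <- propagate_endpoint_error(lq(0.4, 0.04, cov = vneg), 0.1)
  expect_lt(seneg, se0)
  expect_error(propagate_endpoint_error(lq(0.4, 0.04), 0.1), "covariance")
})

test_that("fit_lq recovers parameters and honours the constraint", {
  f <- fit_lq(c(1, 3), c(-1, -3))
  expect_equal(f$alpha, 1, tolerance = 1e-12)
  expect_equal(f$beta, 0, tolerance = 1e-12)
  # noiseless round trip at four doses
  D <- c(1, 2, 4, 6)
  f2 <- fit_lq(D, -(0.2 * D + 0.05 * D^2))
  expect_equal(f2$alpha, 0.2, tolerance = 1e-9)
  expect_equal(f2$beta, 0.05, tolerance = 1e-9)
  # data forcing unconstrained beta < 0: compare to the box oracle
  D3 <- c(1, 2, 3, 4)
  y3 <- -(1.0 * D3 - 0.05 * D3^2) + c(0.01, -0.02, 0.015, -0.01)
  fc <- fit_lq(D3, y3, constrain_nonneg = TRUE)
  or <- nnls_lq_oracle(D3, y3)
  expect_equal(fc$alpha, or[1], tolerance = 1e-5)
  expect_equal(fc$beta, or[2], tolerance = 1e-5)
  expect_error(fit_lq(c(2, 2), c(-1, -1)), "distinct")
  expect_error(fit_lq(2, -1), "length")
})
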