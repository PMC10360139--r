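test_that("slope and intercept laws evaluate the shipped parameters", {
  m <- flint_default_model()
  expect_equal(slope_at_let(0, m$sf1_params), 1.041543)
  expect_equal(slope_at_let(5, endpoint_params(1, 0, 0)), 1)
  expect_equal(slope_at_let(1, endpoint_params(2, log(2), 0)), 1)
  expect_equal(intercept_at_let(0, m$sf1_params), 0)
  expect_equal(intercept_at_let(10, m$sf1_params), 0.2376115)
  expect_equal(intercept_at_let(2, m$sf2_params), 2 * 6.550494e-02)
  expect_error(slope_at_let(-1, m$sf1_params), "non-negative")
})

test_that("endpoint prediction is the affine law in the photon dose", {
  m <- flint_default_model()
  expect_equal(predict_endpoint(5, 0, m$sf1_params), 5 * 1.041543)
  expect_equal(predict_endpoint(1, 3, endpoint_params(1, 0, 0)), 1)
  # affine in d_x at fixed LET (the defining linearity)
  d <- predict_endpoint(c(1, 2, 3), 7, m$sf1_params)
  expect_equal(diff(d, differences = 2), 0, tolerance = 1e-12)
  expect_error(predict_endpoint(0, 1, m$sf1_params), "positive")
})

test_that("two-point reconstruction matches hand-solved cases", {
  ab <- reconstruct_alpha_beta_two_point(1, 3)
  expect_equal(ab$alpha, 1, tolerance = 1e-12)
  expect_equal(ab$beta, 0, tolerance = 1e-12)
  ab2 <- reconstruct_alpha_beta_two_point(2, 2 * sqrt(3))
  expect_equal(ab2$alpha, 0, tolerance = 1e-10)
  expect_equal(ab2$beta, 0.25, tolerance = 1e-12)
  expect_error(reconstruct_alpha_beta_two_point(3, 2), "inverted")
})

test_that("two-point reconstruction interpolates any nonneg curve exactly", {
  set.seed(21)
  for (i in 1:100) {
    p <- random_lq(beta_range = c(0, 0.15))
    if (p$alpha + p$beta < 0.05) next
    d1 <- dose_for_sf(lq(p$alpha, p$beta), exp(-1))
    d2 <- dose_for_sf(lq(p$alpha, p$beta), exp(-3))
    ab <- reconstruct_alpha_beta_two_point(d1, d2)
    expect_equal(ab$alpha, p$alpha, tolerance = 1e-8)
    expect_equal(ab$beta, p$beta, tolerance = 1e-8)
  }
})

test_that("general reconstruction specialises to the two-point forms", {
  set.seed(22)
  for (i in 1:50) {
    d1 <- runif(1, 0.5, 4); d2 <- d1 * runif(1, 1.05, 4)
    gen <- reconstruct_alpha_beta(c(exp(-1), exp(-3)), c(d1, d2))
    two <- reconstruct_alpha_beta_two_point(d1, d2)
    expect_equal(gen$alpha, two$alpha, tolerance = 1e-10)
    expect_equal(gen$beta, two$beta, tolerance = 1e-10)
  }
  # noiseless multi-endpoint recovery
  sf <- exp(-(1:3))
  d <- vapply(sf, function(s) dose_for_sf(lq(0.2, 0.05), s), 0)
  ab <- reconstruct_alpha_beta(sf, d)
  expect_equal(ab$alpha, 0.2, tolerance = 1e-9)
  expect_equal(ab$beta, 0.05, tolerance = 1e-9)
  expect_error(reconstruct_alpha_beta(0.5, 2), "length|>= 2")
  expect_error(reconstruct_alpha_beta(c(0.5, 0.3), c(2, 2)), "coincident")
})

test_that("constrained reconstruction agrees with the NNLS oracle", {
  set.seed(23)
  n_checked <- 0
  worst <- 0
  for (i in 1:300) {
    m <- sample(2:4, 1)
    dose <- sort(runif(m, 0.3, 8))
    if (min(diff(dose)) < 1e-3) next
    logsf <- -(runif(1, 0.05, 1.2) * dose + runif(1, -0.05, 0.15) * dose^2)
    logsf <- pmin(logsf, -1e-3)
    ab <- reconstruct_alpha_beta(exp(logsf), dose)
    or <- nnls_lq_oracle(dose, logsf)
    worst <- max(worst, abs(ab$alpha - or[1]), abs(ab$beta - or[2]))
    n_checked <- n_checked + 1
  }
  expect_lt(worst, 1e-6)
  expect_gt(n_checked, 250)
})

test_that("identity parameters are a fixed point of the prediction", {
  ident <- flint_model(endpoint_params(1, 0, 0), endpoint_params(1, 0, 0))
  set.seed(24)
  for (i in 1:50) {
    p <- random_lq(beta_range = c(0.001, 0.15))
    pr <- predict_proton_curve(lq(p$alpha, p$beta), runif(1, 0, 30), ident)
    expect_equal(pr$alpha, p$alpha, tolerance = 1e-8)
    expect_equal(pr$beta, p$beta, tolerance = 1e-8)
    expect_equal(predict_rbe(lq(p$alpha, p$beta), 5, ident, dose = 2), 1,
                 tolerance = 1e-8)
  }
})

test_that("iso-survival RBE reduces to the closed-form endpoint law", {
  # RBE_{SF} = 1 / (c e^{-f LET} + p LET / D_{SF,x}) holds exactly at a
  # level the predicted curve interpolates: the model's own e^-1 endpoint
  m <- flint_default_model()
  cfp <- m$sf1_params
  ph <- lq(0.5, 0.1)
  for (L in c(0, 2, 9.9, 15)) {
    d1x <- dose_for_sf(ph, exp(-1))
    closed <- 1 / (slope_at_let(L, cfp) + intercept_at_let(L, cfp) / d1x)
    expect_equal(predict_rbe(ph, L, m, sf = exp(-1)), closed,
                 tolerance = 1e-9)
  }
  # limit: D_{SF,x} -> infinity gives RBE -> e^{f LET} / c (evaluated with
  # both endpoint laws equal so the reconstruction stays unconstrained)
  same <- flint_model(cfp, cfp)
  ph_rr <- lq(0.004, 1e-5)
  expect_equal(predict_rbe(ph_rr, 10, same, sf = exp(-1)),
               exp(cfp$f * 10) / cfp$c, tolerance = 5e-3)
})

test_that("sub-unity RBE occurs exactly below the radiosensitivity threshold", {
  m <- flint_default_model()
  cfp <- m$sf1_params
  same <- flint_model(cfp, cfp)
  for (L in c(5, 15, 30)) {
    thresh <- intercept_at_let(L, cfp) / (1 - slope_at_let(L, cfp))
    # slope < 1 at these LETs so the threshold is positive
    expect_gt(thresh, 0)
    for (frac in c(0.5, 0.9, 1.1, 2)) {
      d1x <- frac * thresh
      alpha <- 1 / d1x  # linear photon curve with that e^-1 dose
      # the closed-form law crosses unity exactly at the threshold
      r <- 1 / (slope_at_let(L, cfp) + intercept_at_let(L, cfp) / d1x)
      expect_equal(r < 1, frac < 1)
      # the full pipeline reproduces the sign wherever the reconstruction
      # interpolates the e^-1 endpoint (unconstrained branch)
      pr <- predict_proton_curve(lq(alpha, 0), L, same)
      if (identical(attr(pr, "branch"), "unconstrained"))
        expect_equal(predict_rbe(lq(alpha, 0), L, same, sf = exp(-1)) < 1,
                     frac < 1)
    }
  }
})

test_that("higher LET raises the predicted RBE for a radioresistant line", {
  ph <- lq(0.15, 0.03)
  r <- vapply(c(1, 5, 10, 20, 30), function(L)
    predict_rbe(ph, L, dose = 2), 0)
  expect_true(all(diff(r) > 0))
})

test_that("delta-method uncertainty matches a Monte Carlo oracle", {
  m <- flint_default_model()
  ph <- lq(0.35, 0.035)
  u <- prediction_uncertainty(ph, 9.9, m, dose = 2)
  # parametric MC over the model covariance
  set.seed(25)
  ch <- chol(m$cov)
  draws <- replicate(4000, {
    th <- c(1.041543e+00, 4.708586e-02, 2.376115e-02,
            1.045578e+00, 3.213278e-02, 6.550494e-02) +
      drop(t(ch) %*% rnorm(6))
    mm <- flint_model(endpoint_params(th[1], th[2], th[3]),
                      endpoint_params(th[4], th[5], th[6]))
    tryCatch(predict_rbe(ph, 9.9, mm, dose = 2), error = function(e) NA)
  })
  expect_equal(u$stderr, sd(draws, na.rm = TRUE), tolerance = 0.05)
  # zero covariance -> zero stderr
  m0 <- flint_model(m$sf1_params, m$sf2_params, cov = matrix(0, 6, 6))
  u0 <- prediction_uncertainty(ph, 9.9, m0, dose = 2)
  expect_equal(u0$stderr, 0, tolerance = 1e-9)
  # stderr grows with LET under the shipped covariance
  se <- vapply(c(1, 10, 25), function(L)
    prediction_uncertainty(ph, L, m, dose = 2)$stderr, 0)
  expect_true(all(diff(se) > 0))
})
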