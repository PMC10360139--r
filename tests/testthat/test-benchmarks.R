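test_that("benchmark models have the published zero-LET asymptotes", {
  ph <- lq(0.3, 0.03)  # alpha/beta = 10
  w <- benchmark_predict(benchmark_spec("wedenberg"), ph, 0, dose = 2)
  expect_equal(w$rbe, 1, tolerance = 1e-10)
  m <- benchmark_predict(benchmark_spec("mcnamara"), ph, 0, dose = 2)
  # at LET = 0: RBE_max = p0, RBE_min = p2
  expect_equal(m$proton$alpha, 0.3 * 0.99064, tolerance = 1e-10)
  expect_equal(m$proton$beta, 0.03 * 1.1012^2, tolerance = 1e-10)
  mr <- benchmark_predict(benchmark_spec("mairani"), ph, 0, dose = 2)
  expect_equal(mr$rbe, 1, tolerance = 1e-10)
})

test_that("the three models give distinct finite RBE >= ~1 at 2 keV/um", {
  ph <- lq(0.3, 0.03)
  r <- vapply(c("wedenberg", "mcnamara", "mairani"), function(id)
    benchmark_predict(benchmark_spec(id), ph, 2, dose = 2)$rbe, 0)
  expect_true(all(is.finite(r)))
  expect_true(all(r > 0.95))
  expect_equal(anyDuplicated(round(r, 6)), 0)
})

test_that("degenerate coefficients collapse Wedenberg to RBE = 1", {
  sp <- benchmark_spec("wedenberg", params = c(q = 0))
  ph <- lq(0.3, 0.03)
  for (L in c(1, 5, 20))
    expect_equal(benchmark_predict(sp, ph, L, dose = 2)$rbe, 1,
                 tolerance = 1e-10)
})

test_that("beta_x = 0 is rejected (alpha/beta diverges)", {
  expect_error(benchmark_predict(benchmark_spec("wedenberg"), lq(0.5, 0), 2),
               "beta_x")
})

test_that("RBE is continuous in LET and dose on the model domains", {
  ph <- lq(0.35, 0.035)
  for (id in c("wedenberg", "mcnamara", "mairani")) {
    sp <- benchmark_spec(id)
    L <- seq(0, 30, length.out = 100)
    r <- vapply(L, function(l) benchmark_predict(sp, ph, l, dose = 2)$rbe, 0)
    expect_true(all(is.finite(r)))
    expect_lt(max(abs(diff(r))), 0.05)
    dd <- seq(0.5, 8, length.out = 50)
    rd <- vapply(dd, function(d) benchmark_predict(sp, ph, 5, dose = d)$rbe, 0)
    expect_lt(max(abs(diff(rd))), 0.05)
  }
})

test_that("retraining never worsens the objective and reports chi2/BIC", {
  d <- small_synth(n = 80, seed = 51)
  for (id in c("wedenberg", "mcnamara")) {
    sp <- benchmark_spec(id)
    r <- retrain_benchmark(sp, d, objective = "rbe2gy")
    expect_lte(r$objective_value,
               rbekit:::benchmark_objective(unname(sp$params), sp, d,
                                            "rbe2gy") + 1e-9)
    expect_true(is.finite(r$chi2_nu))
    expect_true(is.finite(r$bic))
  }
})

test_that("chi-squared and BIC match hand computation on a 5-record fixture", {
  d <- small_synth(n = 5, seed = 52)
  sp <- benchmark_spec("wedenberg")
  r <- retrain_benchmark(sp, d, objective = "rbe2gy")
  sp2 <- sp; sp2$params[] <- r$params
  pred <- vapply(1:5, function(i)
    benchmark_predict(sp2, lq(d$alpha_x[i], d$beta_x[i]),
                      d$let_d_kev_um[i], dose = 2)$rbe, 0)
  meas <- vapply(1:5, function(i)
    rbe_at_dose(lq(d$alpha_x[i], d$beta_x[i]),
                lq(d$alpha_p[i], d$beta_p[i]), 2), 0)
  rss <- sum((pred - meas)^2)
  expect_equal(r$objective_value, rss, tolerance = 1e-8)
  expect_equal(r$bic, 5 * log(rss / 5) + 1 * log(5), tolerance = 1e-8)
  chi2_hand <- sum(((pred - meas) / (0.10 * meas))^2) / (5 - 1)
  expect_equal(r$chi2_nu, chi2_hand, tolerance = 1e-8)
})

test_that("data generated by a Wedenberg truth prefer retrained Wedenberg", {
  # build a dataset whose proton curves follow the Wedenberg form exactly,
  # plus small noise; the retrained Wedenberg should beat the
  # six-parameter model on BIC (fewer parameters, right family)
  set.seed(53)
  n <- 120
  ab <- photon_ab_from <- data.frame(alpha = runif(n, 0.2, 0.5),
                                     beta = runif(n, 0.02, 0.06))
  L <- exp(runif(n, log(0.5), log(20)))
  sp <- benchmark_spec("wedenberg")
  d <- data.frame(cell_line = sprintf("w%d", 1:n),
                  alpha_x = ab$alpha, beta_x = ab$beta,
                  alpha_p = NA_real_, beta_p = NA_real_,
                  let_d_kev_um = L, photon_source = "6 MV",
                  assay = "clonogenic", oxygenation = "normoxic",
                  source_tag = "wedenberg-truth")
  for (i in 1:n) {
    pr <- benchmark_predict(sp, lq(d$alpha_x[i], d$beta_x[i]), L[i])$proton
    d$alpha_p[i] <- pr$alpha * exp(rnorm(1, 0, 0.03))
    d$beta_p[i] <- pr$beta * exp(rnorm(1, 0, 0.03))
  }
  cmp <- compare_models(d, models = c("flint", "wedenberg"))
  expect_lt(cmp$bic_rbe2gy[cmp$model == "wedenberg"],
            cmp$bic_rbe2gy[cmp$model == "flint"])
})

test_that("comparison table covers requested models and LET restriction", {
  d <- small_synth(n = 60, seed = 54)
  cmp <- compare_models(d, models = c("flint", "wedenberg"), max_let = 20)
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$n == sum(d$let_d_kev_um < 20)))
  expect_true(all(is.finite(cmp$bic_l2)))
  one <- compare_models(d, models = "mcnamara")
  expect_equal(nrow(one), 1)
})
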