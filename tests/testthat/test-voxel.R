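test_that("scalar grids validate shape, spacing and values", {
  g <- scalar_grid(matrix(1:6 / 2, 2, 3), spacing = c(2, 2))
  expect_s3_class(g, "scalar_grid")
  expect_error(scalar_grid(matrix(-1, 2, 2)), "non-negative")
  expect_error(scalar_grid(array(1, dim = c(2, 2, 2, 2))), "2-D or 3-D")
  expect_error(scalar_grid(matrix(1, 2, 2), spacing = 1), "one spacing")
})

test_that("2-D grids round-trip through delimited text", {
  g <- scalar_grid(matrix(runif(12), 3, 4), spacing = c(1.5, 2.5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_scalar_grid(g, path)
  back <- read_scalar_grid(path)
  expect_equal(back$values, g$values, tolerance = 1e-12)
  expect_equal(back$spacing, g$spacing)
})

test_that("identity model returns the dose grid unchanged", {
  ident <- flint_model(endpoint_params(1, 0, 0), endpoint_params(1, 0, 0))
  dose <- scalar_grid(matrix(c(0, 1, 2, 3), 2, 2))
  let <- scalar_grid(matrix(c(1, 5, 10, 20), 2, 2))
  out <- rbe_weighted_dose(dose, let, lq(0.3, 0.03), ident)
  expect_equal(out$values, dose$values, tolerance = 1e-9)
})

test_that("uniform grids reduce to the scalar prediction path", {
  m <- flint_default_model()
  dose <- scalar_grid(matrix(2, 4, 4))
  let <- scalar_grid(matrix(9.9, 4, 4))
  ph <- lq(0.3, 0.03)
  out <- rbe_weighted_dose(dose, let, ph, m)
  expect_equal(unique(as.numeric(out$values)),
               2 * predict_rbe(ph, 9.9, m, dose = 2), tolerance = 1e-9)
  # fractions scale linearly; zero-dose voxels stay zero
  dose0 <- scalar_grid(matrix(c(0, 2, 2, 2), 2, 2))
  let0 <- scalar_grid(matrix(9.9, 2, 2))
  o27 <- rbe_weighted_dose(dose0, let0, ph, m, fractions = 27)
  expect_equal(o27$values[1, 1], 0)
  expect_equal(o27$values[2, 1],
               27 * 2 * predict_rbe(ph, 9.9, m, dose = 2), tolerance = 1e-9)
})

test_that("higher-LET voxels receive higher RBE-weighted dose", {
  m <- flint_default_model()
  dose <- scalar_grid(matrix(2, 1, 2))
  let <- scalar_grid(matrix(c(1, 10), 1, 2))
  out <- rbe_weighted_dose(dose, let, lq(0.15, 0.03), m)  # radioresistant
  expect_gt(out$values[1, 2], out$values[1, 1])
})

test_that("benchmark models run on grids and mismatches are rejected", {
  dose <- scalar_grid(matrix(2, 2, 2))
  let <- scalar_grid(matrix(5, 2, 2))
  out <- rbe_weighted_dose(dose, let, lq(0.3, 0.03),
                           benchmark_spec("mcnamara"))
  expect_true(all(out$values > 2))  # RBE > 1 for this tissue at 5 keV/um
  bad <- scalar_grid(matrix(5, 2, 3))
  expect_error(rbe_weighted_dose(dose, bad, lq(0.3, 0.03)), "mismatch")
})

test_that("difference maps are antisymmetric and zero for identical input", {
  a <- scalar_grid(matrix(runif(9, 1, 3), 3, 3))
  b <- scalar_grid(matrix(runif(9, 1, 3), 3, 3))
  expect_equal(model_difference_map(a, a)$values, matrix(0, 3, 3))
  ab <- model_difference_map(a, b)
  ba <- model_difference_map(b, a)
  expect_equal(ab$values, -ba$values)
  # reference comparison against a flat RBE = 1.1 map
  m <- flint_default_model()
  dose <- scalar_grid(matrix(2, 2, 2)); let <- scalar_grid(matrix(15, 2, 2))
  rwd <- rbe_weighted_dose(dose, let, lq(0.2, 0.02), m)
  flat <- scalar_grid(1.1 * dose$values)
  diffm <- model_difference_map(rwd, flat)
  expect_equal(diffm$values, rwd$values - 1.1 * dose$values)
})

test_that("3-D arrays follow the identical voxel-wise path", {
  m <- flint_default_model()
  dose <- scalar_grid(array(2, dim = c(2, 2, 2)), spacing = c(1, 1, 2))
  let <- scalar_grid(array(5, dim = c(2, 2, 2)), spacing = c(1, 1, 2))
  out <- rbe_weighted_dose(dose, let, lq(0.3, 0.03), m)
  expect_equal(dim(out$values), c(2, 2, 2))
  expect_equal(unique(as.numeric(out$values)),
               2 * predict_rbe(lq(0.3, 0.03), 5, m, dose = 2),
               tolerance = 1e-9)
})
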