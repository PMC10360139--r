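test_that("survival tables round-trip through CSV and malformed input is named", {
  tab <- filter_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_table(tab, path)
  back <- read_survival_table(path)
  expect_s3_class(back, "survival_table")
  expect_equal(nrow(back), 10)
  expect_equal(back$alpha_x, tab$alpha_x)

  bad <- tab; bad$beta_p[3] <- "NA"
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_survival_table(path), "beta_p.*row.*3")

  greek <- tab; names(greek)[2] <- "α"
  write.csv(greek, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  expect_error(read_survival_table(path), "dialect")

  dropped <- tab[, setdiff(names(tab), "let_d_kev_um")]
  write.csv(dropped, path, row.names = FALSE, quote = FALSE)
  expect_error(read_survival_table(path), "let_d_kev_um")
})

test_that("exclusion filters drop each rule once and reconcile", {
  res <- apply_exclusion_filters(filter_fixture())
  expect_equal(res$report$total_in, 10)
  expect_equal(res$report$total_out, 4)
  expect_equal(nrow(res$kept), 4)
  # per-rule counts: the double violator is counted under both its rules
  counts <- res$report$excluded_by_rule
  expect_equal(unname(counts[c("beta_nonpositive", "radioresistant",
                               "viability_assay", "high_let")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(unname(counts["hypoxic"]), 2L)
  expect_equal(unname(counts["low_energy_photon"]), 1L)
  # reconciliation: unique exclusions + kept = total
  expect_equal(res$report$n_excluded + res$report$total_out,
               res$report$total_in)
})

test_that("the LET cut is a strict inequality and filters are idempotent", {
  tab <- filter_fixture()[1:4, ]
  tab$let_d_kev_um <- 37.8
  res <- apply_exclusion_filters(tab)
  expect_equal(res$report$total_out, 4)  # 37.8 exactly is kept
  tab$let_d_kev_um[1] <- 37.81
  res2 <- apply_exclusion_filters(tab)
  expect_equal(unname(res2$report$excluded_by_rule["high_let"]), 1L)
  # idempotence
  res3 <- apply_exclusion_filters(res2$kept)
  expect_equal(res3$report$n_excluded, 0L)
  expect_equal(res3$kept, res2$kept, ignore_attr = TRUE)
})

test_that("photon source parsing targets low-energy x-rays only", {
  tab <- filter_fixture()[1:5, ]
  tab$beta_p <- 0.03
  tab$photon_source <- c("6 MV", "Co-60", "Cs-137", "250 kVp", "160kVp")
  res <- apply_exclusion_filters(tab)
  expect_equal(unname(res$report$excluded_by_rule["low_energy_photon"]), 1L)
  expect_false("CL05" %in% res$kept$cell_line)
  # unparseable descriptor is kept (with a message)
  tab$photon_source[1] <- "unknown source"
  expect_message(res2 <- apply_exclusion_filters(tab), "unparseable")
  expect_true("CL01" %in% res2$kept$cell_line)
})

test_that("radiosensitivity metrics are ordered and match closed forms", {
  rec <- filter_fixture()[1, ]
  rec$alpha_x <- 0.5; rec$beta_x <- 0
  m <- radiosensitivity_metrics(rec)
  d10 <- m$value[m$quality == "photon" & m$metric == "D10"]
  expect_equal(d10, log(10) / 0.5, tolerance = 1e-12)
  sf2 <- m$value[m$quality == "photon" & m$metric == "SF2Gy"]
  expect_equal(sf2, exp(-1), tolerance = 1e-12)
  # monotone ordering D5 > D10 > D20 > D37 > D50 for any usable curve
  pr <- m[m$quality == "proton" & m$metric != "SF2Gy", ]
  expect_true(all(diff(pr$value[match(c("D5", "D10", "D20", "D37", "D50"),
                                      pr$metric)]) < 0))
})

test_that("correlation by LET reproduces exact and noisy linear laws", {
  set.seed(3)
  n <- 12
  tab <- data.frame(
    cell_line = sprintf("c%d", 1:n),
    alpha_x = runif(n, 0.2, 0.6), beta_x = runif(n, 0.02, 0.06),
    alpha_p = NA_real_, beta_p = NA_real_,
    let_d_kev_um = 2.6, photon_source = "6 MV", assay = "clonogenic",
    oxygenation = "normoxic", source_tag = "t")
  # construct proton curves whose D10 is exactly 0.9 * photon D10 (pure
  # proportional law => slope 0.9, intercept 0, r = 1)
  for (i in 1:n) {
    d10x <- dose_for_sf(lq(tab$alpha_x[i], tab$beta_x[i]), 0.1)
    a <- -log(0.1) / (0.9 * d10x)  # linear proton curve through the point
    tab$alpha_p[i] <- a; tab$beta_p[i] <- 0
  }
  cc <- correlation_by_let(tab, metric = "D10")
  expect_equal(cc$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cc$slope, 0.9, tolerance = 1e-12)
  expect_equal(cc$intercept, 0, tolerance = 1e-10)

  # noisy law recovered within sampling error
  d <- simulate_survival_data(synth_config(n = 120, let_values = 2.6,
                                           seed = 9))
  cc2 <- correlation_by_let(d, metric = "D37")
  m <- flint_default_model()
  expect_equal(cc2$slope, slope_at_let(2.6, m$sf1_params), tolerance = 0.1)

  # degenerate cases error
  tab3 <- tab[1:2, ]
  expect_error(correlation_by_let(tab3), "records")
  tab$alpha_p <- 0.5; tab$beta_p <- 0
  expect_error(correlation_by_let(tab, metric = "D10"), "constant")
})
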