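# Shared fixtures, all generated in code.

# random usable LQ parameters
random_lq <- function(n = 1, alpha_range = c(0.05, 2), beta_range = c(0, 0.2)) {
  data.frame(alpha = runif(n, alpha_range[1], alpha_range[2]),
             beta = runif(n, beta_range[1], beta_range[2]))
}

# quadrature cross-check for the mean inactivation dose
mid_quadrature <- function(alpha, beta) {
  stats::integrate(function(D) exp(-alpha * D - beta * D^2), 0, Inf,
                   rel.tol = 1e-12)$value
}

# brute-force non-negative least squares for the zero-intercept LQ
# regression (the independent oracle for the constrained reconstruction):
# convex objective, box-constrained L-BFGS-B from several starts
nnls_lq_oracle <- function(dose, logsf) {
  obj <- function(p) sum((p[1] * dose + p[2] * dose^2 + logsf)^2)
  gr <- function(p) {
    r <- p[1] * dose + p[2] * dose^2 + logsf
    2 * c(sum(r * dose), sum(r * dose^2))
  }
  best <- NULL
  for (s in list(c(0.5, 0.05), c(0.01, 0.2), c(1.5, 0.001), c(0, 0))) {
    o <- stats::optim(s, obj, gr, method = "L-BFGS-B", lower = c(0, 0),
                      control = list(factr = 1, pgtol = 1e-14,
                                     maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par
}

# the ten-record table exercising every exclusion rule: records 1-4 clean,
# 5-9 violate one rule each, 10 violates two rules at once
filter_fixture <- function() {
  base <- data.frame(
    cell_line = sprintf("CL%02d", 1:10),
    alpha_x = 0.3, beta_x = 0.03, alpha_p = 0.35, beta_p = 0.035,
    let_d_kev_um = 2.6, photon_source = "6 MV", assay = "clonogenic",
    oxygenation = "normoxic", source_tag = "fixture",
    stringsAsFactors = FALSE)
  base$beta_p[5] <- -0.01                       # beta_nonpositive
  base$oxygenation[6] <- "hypoxic"              # hypoxic
  base$alpha_x[7] <- 0.02; base$beta_x[7] <- 5e-4   # photon D10 > 40 Gy
  base$assay[8] <- "viability"                  # viability_assay
  base$let_d_kev_um[9] <- 40                    # high_let (> 37.8)
  base$photon_source[10] <- "180 kVp"           # low_energy_photon ...
  base$oxygenation[10] <- "hypoxic"             # ... and hypoxic
  base
}

# small clean synthetic table for fitting tests
small_synth <- function(n = 60, seed = 1, noise = 0.10, ...) {
  simulate_survival_data(synth_config(n = n, let_range = c(0.5, 37.8),
                                      endpoint_noise_cv = noise,
                                      seed = seed, ...))
}

table5_truth <- function() {
  c(c1 = 1.041543, f1 = 0.04708586, p1 = 0.02376115,
    c2 = 1.045578, f2 = 0.03213278, p2 = 0.06550494)
}
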