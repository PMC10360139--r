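#' Configuration for the synthetic paired-survival generator
#'
#' Defines the statistical structure of a generated training set: per cell
#' line a photon LQ curve drawn from log-normal radiosensitivity
#' distributions, and proton endpoints generated by the linear
#' slope/intercept law in LET with multiplicative log-normal noise.
#' Defaults emulate the regime of the published training compilation:
#' in-house LET values \{1.2, 2.6, 9.9\} keV/um (set `let_range` for a
#' continuum up to the 37.8 keV/um inclusion limit), a photon
#' \eqn{D_{37\%}} median of 2.5 Gy, and a 10% endpoint noise CV.
#'
#' @param n number of paired records (before contamination).
#' @param let_values discrete LET grid (keV/um) sampled uniformly.
#' @param let_range optional length-2 range; when given, LET is drawn
#'   uniformly from it instead of `let_values`.
#' @param true_params a [flint_model] used as ground truth (default: the
#'   shipped fitted parameters).
#' @param photon_d37_median,photon_d37_sdlog log-normal distribution of the
#'   photon dose at survival \eqn{e^{-1}} (Gy; log-scale SD).
#' @param alpha_beta_median,alpha_beta_sdlog log-normal distribution of the
#'   photon \eqn{\alpha/\beta} ratio (Gy).
#' @param endpoint_noise_cv relative SD of the multiplicative log-normal
#'   noise applied to each generated proton endpoint.
#' @param contamination named integer vector of records to append that
#'   violate specific exclusion rules; names drawn from
#'   `beta_nonpositive`, `hypoxic`, `radioresistant`, `viability_assay`,
#'   `high_let`, `low_energy_photon`.
#' @param seed integer seed; mandatory (generation is deterministic per
#'   seed).
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n = 397, let_values = c(1.2, 2.6, 9.9),
                         let_range = NULL,
                         true_params = flint_default_model(),
                         photon_d37_median = 2.5, photon_d37_sdlog = 0.35,
                         alpha_beta_median = 8, alpha_beta_sdlog = 0.6,
                         endpoint_noise_cv = 0.10,
                         contamination = integer(), seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n >= 1, photon_d37_median > 0, alpha_beta_median > 0,
            endpoint_noise_cv >= 0)
  if (!is.null(let_range)) stopifnot(length(let_range) == 2, let_range[1] > 0)
  structure(list(n = as.integer(n), let_values = let_values,
                 let_range = let_range, true_params = true_params,
                 photon_d37_median = photon_d37_median,
                 photon_d37_sdlog = photon_d37_sdlog,
                 alpha_beta_median = alpha_beta_median,
                 alpha_beta_sdlog = alpha_beta_sdlog,
                 endpoint_noise_cv = endpoint_noise_cv,
                 contamination = contamination, seed = as.integer(seed)),
            class = "synth_config")
}

# Photon (alpha, beta) from D37 (dose at SF e^-1) and the alpha/beta ratio:
# alpha*D + (alpha/r)*D^2 = 1  =>  alpha = 1 / (D + D^2/r).
photon_ab_from_d37 <- function(d37, ab_ratio) {
  alpha <- 1 / (d37 + d37^2 / ab_ratio)
  beta <- alpha / ab_ratio
  cbind(alpha = alpha, beta = beta)
}

#' Generate a synthetic paired photon/proton survival table
#'
#' Photon curves are drawn from the configured radiosensitivity
#' distributions; proton iso-survival doses at \eqn{e^{-1}} and \eqn{e^{-3}}
#' follow the ground-truth slope/intercept laws with multiplicative
#' log-normal noise, and the proton \eqn{(\alpha, \beta)} is recovered by
#' the two-point reconstruction. Draws whose noisy endpoints invert
#' (\eqn{D_{e^{-3}} \le D_{e^{-1}}}) are resampled and counted. Requested
#' contamination records (violating specific quality filters) are appended
#' with rule tags in `source_tag`. Output is deterministic per seed.
#'
#' @param config a [synth_config].
#' @return A survival table (`data.frame`, class `"survival_table"`) with a
#'   `"truth"` attribute carrying the generating [flint_model], the true
#'   per-record endpoints, and the resample count.
#' @export
#' @examples
#' d <- simulate_survival_data(synth_config(n = 20, seed = 42))
#' nrow(d)
simulate_survival_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_preserved_seed(config$seed, {
    n <- config$n
    m <- config$true_params
    sdlog <- sqrt(log(1 + config$endpoint_noise_cv^2))
    let <- numeric(n); d1x <- d2x <- numeric(n)
    alpha_x <- beta_x <- numeric(n)
    mu1 <- mu2 <- d1p <- d2p <- numeric(n)
    n_resampled <- 0L
    todo <- seq_len(n)
    # Draws are accepted only if the resulting record satisfies every
    # quality filter a clean training record must satisfy: endpoints not
    # inverted, implied proton beta strictly positive (endpoint ratio
    # inside (1, 3)), and no iso-survival dose in the radioresistant
    # regime. Rejected draws are redrawn wholesale and counted.
    while (length(todo)) {
      k <- length(todo)
      # continuum LET values are drawn log-uniformly: compiled proton
      # survival data are dominated by low LET_d (clinical beams), with
      # high-LET end-of-range measurements rare
      L <- if (!is.null(config$let_range))
        exp(stats::runif(k, log(config$let_range[1]),
                         log(config$let_range[2])))
      else config$let_values[sample.int(length(config$let_values), k,
                                        replace = TRUE)]
      d37 <- stats::rlnorm(k, log(config$photon_d37_median),
                           config$photon_d37_sdlog)
      abr <- stats::rlnorm(k, log(config$alpha_beta_median),
                           config$alpha_beta_sdlog)
      ab <- photon_ab_from_d37(d37, abr)
      e1 <- lq_dose_root(ab[, 1], ab[, 2], exp(-1))
      e2 <- lq_dose_root(ab[, 1], ab[, 2], exp(-3))
      m1 <- predict_endpoint(e1, L, m$sf1_params)
      m2 <- predict_endpoint(e2, L, m$sf2_params)
      p1 <- m1 * stats::rlnorm(k, -sdlog^2 / 2, sdlog)
      p2 <- m2 * stats::rlnorm(k, -sdlog^2 / 2, sdlog)
      ratio <- p2 / p1
      d10x <- lq_dose_root(ab[, 1], ab[, 2], 0.1)
      # proton D10 lies below the e^-3 endpoint dose, so p2 <= 40 bounds it
      ok <- ratio > 1 & ratio < 3 & d10x <= 40 & p2 <= 40
      acc <- todo[ok]
      let[acc] <- L[ok]; alpha_x[acc] <- ab[ok, 1]; beta_x[acc] <- ab[ok, 2]
      d1x[acc] <- e1[ok]; d2x[acc] <- e2[ok]
      mu1[acc] <- m1[ok]; mu2[acc] <- m2[ok]
      d1p[acc] <- p1[ok]; d2p[acc] <- p2[ok]
      n_resampled <- n_resampled + sum(!ok)
      todo <- todo[!ok]
    }
    abp <- reconstruct_ab_matrix(cbind(d1p, d2p),
                                 matrix(c(-1, -3), n, 2, byrow = TRUE))
    ab <- cbind(alpha = alpha_x, beta = beta_x)
    out <- data.frame(
      cell_line = sprintf("SYN%03d", seq_len(n)),
      alpha_x = ab[, 1], beta_x = ab[, 2],
      alpha_p = abp$alpha, beta_p = abp$beta,
      let_d_kev_um = let,
      photon_source = "6 MV", assay = "clonogenic",
      oxygenation = "normoxic", source_tag = "synthetic",
      stringsAsFactors = FALSE)
    out <- append_contamination(out, config)
    class(out) <- c("survival_table", "data.frame")
    attr(out, "truth") <- list(true_params = m,
                               endpoints = cbind(d1 = mu1, d2 = mu2),
                               n_resampled = n_resampled)
    out
  })
}

# Contamination rows reuse a clean template row and break exactly one rule
# each (tagged in source_tag), so filter reports can be checked by
# construction.
append_contamination <- function(out, config) {
  cont <- config$contamination
  if (!length(cont)) return(out)
  template <- out[rep(1L, 1), , drop = FALSE]
  rows <- list()
  idx <- nrow(out)
  for (rule in names(cont)) {
    for (i in seq_len(cont[[rule]])) {
      r <- template
      idx <- idx + 1L
      r$cell_line <- sprintf("SYN%03d", idx)
      r$source_tag <- paste0("contaminated:", rule)
      switch(rule,
        beta_nonpositive = {r$beta_p <- -0.01},
        hypoxic = {r$oxygenation <- "hypoxic"},
        radioresistant = {r$alpha_x <- 0.02; r$beta_x <- 0.0005
                          r$alpha_p <- 0.025; r$beta_p <- 0.0006},
        viability_assay = {r$assay <- "viability"},
        high_let = {r$let_d_kev_um <- 60},
        low_energy_photon = {r$photon_source <- "180 kVp"},
        stop("unknown contamination rule: ", rule))
      rows[[length(rows) + 1L]] <- r
    }
  }
  rbind(out, do.call(rbind, rows))
}
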