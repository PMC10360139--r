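#' @section Survival-table CSV dialect:
#' UTF-8, comma-separated, one header row. Mandatory columns:
#' `cell_line, alpha_x, beta_x, alpha_p, beta_p, let_d_kev_um, photon_source,
#' assay, oxygenation, source_tag`. Optional covariance columns
#' `cov_x_aa, cov_x_ab, cov_x_bb, cov_p_aa, cov_p_ab, cov_p_bb` carry the
#' photon/proton (alpha, beta) fit covariances. One row per cell-line/LET
#' combination.
#' @name survival-table
#' @keywords internal
NULL

mandatory_cols <- c("cell_line", "alpha_x", "beta_x", "alpha_p", "beta_p",
                    "let_d_kev_um", "photon_source", "assay", "oxygenation",
                    "source_tag")
numeric_cols <- c("alpha_x", "beta_x", "alpha_p", "beta_p", "let_d_kev_um")
cov_cols <- c("cov_x_aa", "cov_x_ab", "cov_x_bb",
              "cov_p_aa", "cov_p_ab", "cov_p_bb")

#' Read a paired photon/proton survival table
#'
#' Reads a CSV of paired clonogenic-survival LQ parameters (one row per
#' cell-line/LET combination) in the dialect described under
#' \link{survival-table}. Rows with non-numeric entries in numeric columns
#' are reported by row number.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` of class `"survival_table"`.
#' @export
read_survival_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  nm <- names(raw)
  if (any(grepl("[^\x01-\x7F]", nm)))
    stop("unsupported header dialect: non-ASCII column names (",
         paste(nm[grepl("[^\x01-\x7F]", nm)], collapse = ", "),
         "); expected e.g. `alpha_x`")
  if (anyDuplicated(nm)) stop("duplicated column names in header")
  missing <- setdiff(mandatory_cols, nm)
  if (length(missing))
    stop("missing mandatory columns: ", paste(missing, collapse = ", "))
  for (col in intersect(c(numeric_cols, cov_cols), nm)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    bad <- union(bad, which(is.na(v)))
    if (length(bad))
      stop(sprintf("non-numeric value in column `%s` at data row(s) %s",
                   col, paste(bad, collapse = ", ")))
    raw[[col]] <- v
  }
  if (any(raw$let_d_kev_um <= 0)) stop("let_d_kev_um must be positive")
  class(raw) <- c("survival_table", "data.frame")
  raw
}

#' Write a survival table
#'
#' @param x a survival table `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Parse a photon source descriptor; returns TRUE if the record must be
# excluded as a low-energy (< 200 kVp) x-ray reference, FALSE if it passes,
# NA if unparseable (kept, by design: the rule targets known low-energy
# sources).
low_energy_photon_source <- function(desc) {
  desc <- trimws(desc)
  kvp <- regmatches(desc, regexec("([0-9]+\\.?[0-9]*)\\s*kVp?", desc,
                                  ignore.case = TRUE))
  out <- rep(NA, length(desc))
  kv <- vapply(kvp, function(m) if (length(m)) as.numeric(m[2]) else NA_real_, 0)
  out[!is.na(kv)] <- kv[!is.na(kv)] < 200
  mv <- grepl("MV|MeV|Co[- ]?60|Cs[- ]?137", desc, ignore.case = TRUE)
  out[is.na(out) & mv] <- FALSE
  out
}

#' Quality filters for the paired survival dataset
#'
#' Applies the training-data exclusion rules and returns the retained rows
#' together with a per-rule report. The rules, each counted independently
#' (a record can fail several but is excluded once):
#' \describe{
#'   \item{beta_nonpositive}{\eqn{\beta \le 0} for either radiation quality —
#'     non-physical fits whose survival integrals (and \eqn{\alpha/\beta})
#'     diverge.}
#'   \item{hypoxic}{hypoxic oxygenation (oxygen enhancement inflates RBE).}
#'   \item{radioresistant}{photon or proton \eqn{D_{10\%} > 40} Gy, where LQ
#'     extrapolation is untrustworthy; a name-based exclusion list can be
#'     supplied in addition.}
#'   \item{viability_assay}{survival measured by viability rather than
#'     clonogenic assay.}
#'   \item{high_let}{proton LET_d strictly above 37.8 keV/um (beyond clinical
#'     relevance).}
#'   \item{low_energy_photon}{photon reference below 200 kVp; megavoltage,
#'     Co-60 and Cs-137 sources pass; unparseable descriptors are kept and
#'     reported via a message.}
#' }
#'
#' @param records a survival table (see [read_survival_table()]).
#' @param d10_limit_gy radioresistance cut on \eqn{D_{10\%}} (Gy).
#' @param let_limit_kev_um LET cut (strict inequality), keV/um.
#' @param exclude_cell_lines optional character vector of cell-line names to
#'   exclude under the `radioresistant` rule regardless of their parameters.
#' @return A list with `kept` (filtered table) and `report` (a
#'   `"filter_report"`: `total_in`, `excluded_by_rule`, `total_out`).
#' @export
apply_exclusion_filters <- function(records, d10_limit_gy = 40,
                                    let_limit_kev_um = 37.8,
                                    exclude_cell_lines = character()) {
  n <- nrow(records)
  # D10 is left NA (rule not triggered) for curves the beta rule already
  # rejects, so one defect is not double-counted across unrelated rules.
  d10 <- function(a, b) {
    ok <- b >= 0 & (a + b) > 0
    out <- rep(NA_real_, length(a))
    out[ok] <- lq_dose_root(a[ok], b[ok], 0.1)
    out
  }
  src <- low_energy_photon_source(records$photon_source)
  if (any(is.na(src)))
    message(sum(is.na(src)), " record(s) with unparseable photon source kept")
  fails <- list(
    beta_nonpositive = records$beta_x <= 0 | records$beta_p <= 0,
    hypoxic = tolower(records$oxygenation) == "hypoxic",
    radioresistant = d10(records$alpha_x, records$beta_x) > d10_limit_gy |
      d10(records$alpha_p, records$beta_p) > d10_limit_gy |
      records$cell_line %in% exclude_cell_lines,
    viability_assay = tolower(records$assay) == "viability",
    high_let = records$let_d_kev_um > let_limit_kev_um,
    low_energy_photon = !is.na(src) & src
  )
  fails <- lapply(fails, function(f) {f[is.na(f)] <- FALSE; f})
  any_fail <- Reduce(`|`, fails)
  kept <- records[!any_fail, , drop = FALSE]
  report <- structure(list(
    total_in = n,
    excluded_by_rule = vapply(fails, sum, 0L),
    total_out = nrow(kept),
    n_excluded = sum(any_fail)), class = "filter_report")
  list(kept = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d in, %d excluded, %d kept\n",
              x$total_in, x$n_excluded, x$total_out))
  for (r in names(x$excluded_by_rule))
    cat(sprintf("  %-20s %d\n", r, x$excluded_by_rule[[r]]))
  invisible(x)
}

record_lq <- function(rec, quality = c("x", "p")) {
  quality <- match.arg(quality)
  a <- rec[[paste0("alpha_", quality)]]
  b <- rec[[paste0("beta_", quality)]]
  cc <- paste0("cov_", quality, c("_aa", "_ab", "_bb"))
  covm <- NULL
  if (all(cc %in% names(rec)) && all(!is.na(unlist(rec[cc]))))
    covm <- matrix(c(rec[[cc[1]]], rec[[cc[2]]], rec[[cc[2]]], rec[[cc[3]]]), 2)
  lq(a, b, cov = covm)
}

#' Radiosensitivity metrics of one paired experiment
#'
#' The six iso-survival summaries per radiation quality: \eqn{D_{5\%}},
#' \eqn{D_{10\%}}, \eqn{D_{20\%}}, \eqn{D_{37\%}}, \eqn{D_{50\%}} (Gy) and
#' \eqn{SF_{2Gy}} (dimensionless), with delta-method standard errors when
#' the record carries covariance columns.
#'
#' @param record one row of a survival table (data.frame or list).
#' @return A `data.frame` with columns `quality`, `metric`, `value`,
#'   `stderr`.
#' @export
radiosensitivity_metrics <- function(record) {
  levels <- c(D5 = 0.05, D10 = 0.10, D20 = 0.20, D37 = 0.37, D50 = 0.50)
  out <- list()
  for (q in c("x", "p")) {
    par <- record_lq(record, q)
    check_usable_lq(par)
    vals <- dose_for_sf(par, levels)
    ses <- if (!is.null(par$cov))
      vapply(levels, function(s) propagate_endpoint_error(par, s), 0)
    else rep(NA_real_, length(levels))
    sf2 <- surviving_fraction(par, 2)
    sf2_se <- NA_real_
    if (!is.null(par$cov)) {
      g <- c(-2, -4) * sf2  # d/dalpha, d/dbeta of exp(-2a-4b)
      sf2_se <- sqrt(max(drop(t(g) %*% par$cov %*% g), 0))
    }
    out[[q]] <- data.frame(
      quality = if (q == "x") "photon" else "proton",
      metric = c(names(levels), "SF2Gy"),
      value = c(vals, sf2),
      stderr = c(ses, sf2_se), row.names = NULL)
  }
  rbind(out$x, out$p)
}

#' Photon-proton endpoint correlation within LET groups
#'
#' For each distinct LET value with at least `min_n` records, computes the
#' Pearson correlation and the ordinary least-squares slope and intercept of
#' the proton endpoint against the photon endpoint — the linear correlation
#' on which the model is built. Fits are unweighted by default; inverse
#' variance weighting by propagated endpoint errors is available.
#'
#' @param records a survival table.
#' @param metric endpoint name: one of `"D5"`, `"D10"`, `"D20"`, `"D37"`,
#'   `"D50"`, `"SF2Gy"`.
#' @param min_n minimum records per LET group (default 3).
#' @param weighted use inverse-variance weights from propagated standard
#'   errors (requires covariance columns).
#' @return A `data.frame` with one row per LET group: `let_d`, `n`,
#'   `pearson_r`, `slope`, `intercept`.
#' @export
correlation_by_let <- function(records, metric = "D10", min_n = 3,
                               weighted = FALSE) {
  lv <- c(D5 = 0.05, D10 = 0.10, D20 = 0.20, D37 = 0.37, D50 = 0.50)
  endpoint <- function(q, i) {
    par <- record_lq(records[i, ], q)
    if (metric == "SF2Gy") surviving_fraction(par, 2)
    else dose_for_sf(par, lv[[metric]])
  }
  groups <- split(seq_len(nrow(records)), records$let_d_kev_um)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < min_n)
      stop(sprintf("LET group %s has %d < %d records", g, length(idx), min_n))
    x <- vapply(idx, function(i) endpoint(q = "x", i = i), 0)
    y <- vapply(idx, function(i) endpoint(q = "p", i = i), 0)
    if (stats::sd(x) == 0) stop("zero variance in photon endpoint")
    if (stats::sd(y) == 0) stop("undefined correlation: proton endpoint constant")
    w <- NULL
    if (weighted) {
      se <- vapply(idx, function(i) {
        par <- record_lq(records[i, ], "p")
        if (is.null(par$cov)) stop("weighted fit needs covariance columns")
        propagate_endpoint_error(par, lv[[metric]])
      }, 0)
      w <- 1 / se^2
    }
    fit <- stats::lm(y ~ x, weights = w)
    data.frame(let_d = as.numeric(g), n = length(idx),
               pearson_r = stats::cor(x, y),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]))
  })
  do.call(rbind, rows)
}
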