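#' Scalar grid (dose or LET map)
#'
#' A 2-D or 3-D array of non-negative finite voxel values (physical dose
#' per fraction in Gy, or LET_d in keV/um) with per-axis spacing in mm.
#'
#' @param values numeric matrix or 3-D array.
#' @param spacing numeric vector of voxel spacings (mm), one per axis.
#' @return An object of class `"scalar_grid"`.
#' @export
scalar_grid <- function(values, spacing = rep(1, length(dim(values)))) {
  values <- as.array(values)
  nd <- length(dim(values))
  if (!nd %in% 2:3) stop("grid must be 2-D or 3-D")
  if (length(spacing) != nd) stop("one spacing per axis required")
  if (any(!is.finite(values)) || any(values < 0))
    stop("grid values must be finite and non-negative")
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("scalar grid %s, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grid shape mismatch")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("grid spacing mismatch")
}

#' Read / write a 2-D scalar grid as delimited text
#'
#' Plain whitespace-delimited text, one matrix row per line; the spacing is
#' stored in a `# spacing: dx dy` comment on the first line.
#'
#' @param path file path.
#' @return [scalar_grid] (for the reader); `path` invisibly (writer).
#' @export
read_scalar_grid <- function(path) {
  first <- readLines(path, n = 1)
  spacing <- c(1, 1)
  skip <- 0
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("spacing:\\s*([0-9.eE+-]+)\\s+([0-9.eE+-]+)",
                                   first))[[1]]
    if (length(m)) spacing <- as.numeric(m[2:3])
    skip <- 1
  }
  vals <- as.matrix(utils::read.table(path, skip = skip))
  dimnames(vals) <- NULL
  scalar_grid(vals, spacing)
}

#' @rdname read_scalar_grid
#' @param grid a 2-D [scalar_grid].
#' @export
write_scalar_grid <- function(grid, path) {
  if (length(dim(grid$values)) != 2L)
    stop("text format supports 2-D grids")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spacing: %g %g", grid$spacing[1], grid$spacing[2]),
             con)
  utils::write.table(grid$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' RBE-weighted dose map
#'
#' Applies an RBE model voxel by voxel to co-registered per-fraction dose
#' and LET_d grids: each voxel's RBE is evaluated at that voxel's
#' per-fraction dose and the output is dose x RBE (times the fraction
#' count, for total RBE-weighted dose). Exactly the scalar model mapped over
#' the grid — no smoothing or interpolation. Zero-dose voxels short-circuit
#' to 0 (RBE is undefined at zero dose).
#'
#' @param dose per-fraction physical dose grid (Gy), a [scalar_grid].
#' @param let LET_d grid (keV/um), aligned with `dose`.
#' @param photon photon tissue [lq] parameters (single tissue; no default —
#'   a tissue choice is required).
#' @param model a [flint_model], an [rbe_fit] with a canonical model, or a
#'   [benchmark_spec].
#' @param fractions fraction count multiplying the per-fraction result.
#' @return A [scalar_grid] of RBE-weighted dose (Gy RBE).
#' @export
rbe_weighted_dose <- function(dose, let, photon, model = flint_default_model(),
                              fractions = 1) {
  stopifnot(inherits(dose, "scalar_grid"), inherits(let, "scalar_grid"))
  check_aligned(dose, let)
  photon <- check_usable_lq(photon)
  if (inherits(model, "rbe_fit")) {
    if (is.null(model$model))
      stop("rbe_fit without a canonical two-endpoint model")
    model <- model$model
  }
  d <- as.numeric(dose$values)
  L <- as.numeric(let$values)
  rbe <- numeric(length(d))
  nz <- d > 0
  if (any(nz)) {
    if (inherits(model, "benchmark_spec")) {
      if (photon$beta <= 0) stop("benchmark models require beta_x > 0")
      abr <- photon$alpha / photon$beta
      rm <- model$rbe_max_min(L[nz], abr, model$params)
      ap <- photon$alpha * rm$rbe_max
      bp <- photon$beta * rm$rbe_min^2
    } else if (inherits(model, "flint_model")) {
      d1x <- lq_dose_root(photon$alpha, photon$beta, exp(-1))
      d2x <- lq_dose_root(photon$alpha, photon$beta, exp(-3))
      d1p <- predict_endpoint(d1x, L[nz], model$sf1_params)
      d2p <- predict_endpoint(d2x, L[nz], model$sf2_params)
      ab <- reconstruct_alpha_beta_two_point(pmin(d1p, d2p * (1 - 1e-9)), d2p)
      ap <- ab$alpha; bp <- ab$beta
    } else stop("unsupported model object")
    rbe[nz] <- rbe_at_dose_vec(photon$alpha, photon$beta, ap, bp, d[nz])
  }
  scalar_grid(array(fractions * d * rbe, dim = dim(dose$values)),
              dose$spacing)
}

#' Voxel-wise difference of two maps
#'
#' Arithmetic difference A - B of aligned grids (e.g., two models'
#' RBE-weighted dose maps). Antisymmetric: `model_difference_map(a, b)`
#' equals the negation of `model_difference_map(b, a)`.
#'
#' @param grid_a,grid_b aligned [scalar_grid]s.
#' @return A grid-shaped array difference wrapped in a list of class
#'   `"scalar_grid"` (values may be negative, so invariants on sign are not
#'   enforced).
#' @export
model_difference_map <- function(grid_a, grid_b) {
  stopifnot(inherits(grid_a, "scalar_grid"), inherits(grid_b, "scalar_grid"))
  check_aligned(grid_a, grid_b)
  structure(list(values = grid_a$values - grid_b$values,
                 spacing = grid_a$spacing),
            class = "scalar_grid")
}
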