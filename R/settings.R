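#' Numerical settings for rbekit computations
#'
#' A single settings object collects every numerical tolerance used by the
#' package so that they can be adjusted in one place. All functions that need
#' a tolerance accept a `settings` argument defaulting to `rbe_settings()`.
#'
#' @param sf_truncation survival fraction below which the survival integral
#'   tail is truncated in quadrature cross-checks (the closed forms are exact
#'   and do not truncate).
#' @param quad_rel_tol relative tolerance for adaptive quadrature.
#' @param root_tol relative tolerance for iso-survival dose round-trips.
#' @param objective_floor floor applied to a non-positive least-squares
#'   objective before taking its logarithm in the BIC (a noiseless fit can
#'   reach an objective of exactly zero).
#' @param optim_reltol relative convergence tolerance passed to the optimizer.
#' @param multistart_n number of random restarts for multi-modal candidate
#'   LET-function families.
#' @param multistart_seed integer seed from which the fixed restart list is
#'   derived, so grid searches are reproducible bit for bit.
#'
#' @return A list of class `"rbe_settings"`.
#' @export
#' @examples
#' s <- rbe_settings(multistart_n = 6)
#' s$multistart_n
rbe_settings <- function(sf_truncation = 1e-12,
                         quad_rel_tol = 1e-10,
                         root_tol = 1e-12,
                         objective_floor = 1e-12,
                         optim_reltol = 1e-12,
                         multistart_n = 6,
                         multistart_seed = 20220728L) {
  stopifnot(sf_truncation > 0, quad_rel_tol > 0, objective_floor > 0,
            multistart_n >= 1)
  structure(list(sf_truncation = sf_truncation,
                 quad_rel_tol = quad_rel_tol,
                 root_tol = root_tol,
                 objective_floor = objective_floor,
                 optim_reltol = optim_reltol,
                 multistart_n = as.integer(multistart_n),
                 multistart_seed = as.integer(multistart_seed)),
            class = "rbe_settings")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps library fits deterministic without
# clobbering the user's random stream.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
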