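#' Spearman correlation with a spatial-autocorrelation-corrected p-value
#'
#' Null correlations come from variogram-matched surrogates of `map_a` (the
#' slope map); the p-value is the two-sided add-one permutation p. The rho is
#' symmetric in the arguments but the p is not: surrogates are generated for
#' the first argument.
#'
#' @param map_a length-R numeric map (surrogates are of this map).
#' @param map_b length-R numeric map.
#' @param distmat R x R distance matrix (ignored when `surrogates` given).
#' @param n_surr number of surrogates.
#' @param seed integer seed.
#' @param surrogates optional precomputed `surrogate_ensemble` of `map_a`.
#' @return list with `rho`, `p_sac`, `null_rho`.
#' @export
spearman_sac <- function(map_a, map_b, distmat = NULL, n_surr = 1000,
                         seed = 1L, surrogates = NULL) {
  rho <- stats::cor(map_a, map_b, method = "spearman")
  if (is.null(surrogates)) {
    surrogates <- make_surrogates(map_a, distmat, n = n_surr, seed = seed)
  }
  S <- if (inherits(surrogates, "surrogate_ensemble")) surrogates$maps else surrogates
  rb <- rank(map_b)
  null_rho <- apply(S, 1, function(s) stats::cor(rank(s), rb))
  list(rho = rho, p_sac = sac_pvalue(rho, null_rho), null_rho = null_rho)
}

#' Rank-based partial correlation with SAC-corrected p-value
#'
#' All maps are rank-transformed; the slope map and the target map are
#' residualised on the control maps by least squares and their residuals
#' correlated (partial Spearman). The null pushes each surrogate of the
#' slope map through the identical rank + residualisation pipeline.
#'
#' @param slope length-R slope map (surrogates are of this map).
#' @param target length-R target map.
#' @param controls R x k matrix of control maps (or `NULL` for none, in
#'   which case the statistic reduces to the simple Spearman rho).
#' @param distmat distance matrix (ignored when `surrogates` given).
#' @param n_surr number of surrogates.
#' @param seed integer seed.
#' @param surrogates optional precomputed `surrogate_ensemble` of `slope`.
#' @return list with `rho`, `p_sac`, `null_rho`.
#' @export
partial_spearman_sac <- function(slope, target, controls = NULL, distmat = NULL,
                                 n_surr = 1000, seed = 1L, surrogates = NULL) {
  R <- length(slope)
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    C <- cbind(1, apply(controls, 2, rank))
    if (kappa(C, exact = TRUE) > 1e8) stop("collinear control maps")
  } else {
    C <- matrix(1, R, 1)
  }
  # residual-maker for the rank-transformed control design
  Mres <- diag(R) - C %*% solve(crossprod(C), t(C))
  res_t <- drop(Mres %*% rank(target))
  res_s <- drop(Mres %*% rank(slope))
  rho <- stats::cor(res_s, res_t)
  if (is.null(surrogates)) {
    surrogates <- make_surrogates(slope, distmat, n = n_surr, seed = seed)
  }
  S <- if (inherits(surrogates, "surrogate_ensemble")) surrogates$maps else surrogates
  null_rho <- apply(S, 1, function(s) stats::cor(drop(Mres %*% rank(s)), res_t))
  list(rho = rho, p_sac = sac_pvalue(rho, null_rho), null_rho = null_rho)
}

#' Laminar-specific partial correlation of a slope map
#'
#' Partial correlation of the slope map with one cortical lamina thickness,
#' controlling the remaining five laminas, with SAC-corrected p.
#'
#' @param slope length-R slope map over cortical regions.
#' @param laminas R x 6 matrix of laminar thickness maps, columns `L1`..`L6`.
#' @param target lamina name (e.g. `"L5"`).
#' @param distmat distance matrix over the same regions.
#' @param n_surr number of surrogates.
#' @param seed integer seed.
#' @param surrogates optional precomputed ensemble of `slope`.
#' @return list with `rho`, `p_sac`, `null_rho`, `target`.
#' @export
partial_laminar <- function(slope, laminas, target, distmat = NULL,
                            n_surr = 1000, seed = 1L, surrogates = NULL) {
  laminas <- as.matrix(laminas)
  if (!target %in% colnames(laminas)) stop("unknown target lamina: ", target)
  out <- partial_spearman_sac(slope, laminas[, target],
                              laminas[, setdiff(colnames(laminas), target), drop = FALSE],
                              distmat, n_surr, seed, surrogates)
  out$target <- target
  out
}

#' Correlate a slope map with a set of cortical maps
#'
#' Simple Spearman SAC tests for each map, reusing one surrogate ensemble of
#' the slope map.
#'
#' @param slope length-R slope map over cortical regions.
#' @param maps R x m matrix of cortical maps (named columns).
#' @param distmat distance matrix.
#' @param n_surr number of surrogates.
#' @param seed integer seed.
#' @return data.frame: `map`, `rho`, `p_sac`.
#' @export
cortical_map_correlations <- function(slope, maps, distmat, n_surr = 1000,
                                      seed = 1L) {
  ens <- make_surrogates(slope, distmat, n = n_surr, seed = seed)
  res <- lapply(colnames(maps), function(nm) {
    r <- spearman_sac(slope, maps[, nm], surrogates = ens)
    data.frame(map = nm, rho = r$rho, p_sac = r$p_sac, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
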