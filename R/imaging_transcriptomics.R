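#' Read a region-by-gene expression matrix
#'
#' TSV with a `region_id` first column and one column per gene.
#'
#' @param path path to the TSV file.
#' @return an `expression_matrix`: list with `values` (regions x genes),
#'   `gene_ids`, `region_ids`.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (names(tab)[1] != "region_id") stop("expression table must start with a region_id column")
  structure(list(values = as.matrix(tab[, -1, drop = FALSE]),
                 gene_ids = names(tab)[-1],
                 region_ids = tab$region_id),
            class = "expression_matrix")
}

#' Write an expression matrix
#' @param expr an `expression_matrix`.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(region_id = expr$region_ids, expr$values, check.names = FALSE)
  names(df) <- c("region_id", expr$gene_ids)
  write_tsv_full(df, path)
}

#' Align a slope map with an expression matrix over cortical regions
#'
#' Restricts to cortical regions present in both, co-orders rows, z-scores
#' the response and each gene column (constant columns dropped with a
#' warning).
#'
#' @param slope_map a `slope_map` (or numeric vector aligned with `regions`).
#' @param expression an `expression_matrix`.
#' @param regions region table.
#' @return list with `y` (standardised slopes), `X` (standardised
#'   regions x genes), `region_ids`, `gene_ids`.
#' @export
align_expression <- function(slope_map, expression, regions) {
  beta <- if (is.data.frame(slope_map)) slope_map$beta_age else as.numeric(slope_map)
  stopifnot(length(beta) == nrow(regions))
  cort_ids <- regions$id[regions$cortical]
  common <- intersect(cort_ids, expression$region_ids)
  if (length(common) < 10) stop("fewer than 10 cortical regions shared with expression data")
  y <- beta[match(common, regions$id)]
  X <- expression$values[match(common, expression$region_ids), , drop = FALSE]
  colnames(X) <- expression$gene_ids
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d constant gene column(s)", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  list(y = as.numeric(scale(y)), X = scale(X),
       region_ids = common, gene_ids = colnames(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Univariate-response partial least squares
#'
#' PLS1 by successive cross-covariance directions with deflation: component
#' weights `w_k` are proportional to `X_k' y_k`, scores `t_k = X_k w_k`, and
#' both `X` and `y` are deflated on `t_k`. Component signs are flipped so
#' every score correlates nonnegatively with `y`. Explained fractions are the
#' per-component shares of the response sum of squares (scores are mutually
#' orthogonal, so shares are additive).
#'
#' @param X regions x genes matrix (standardised).
#' @param y length-R response (standardised).
#' @param n_components number of components (at most `min(nrow(X) - 1, ncol(X))`).
#' @return object of class `pls_result`: `weights` (genes x K), `scores`
#'   (regions x K), `explained` (length K), `r` (per-component correlation
#'   with `y`), `r1`, `gene_ids`.
#' @export
pls_fit <- function(X, y, n_components = 15) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (n_components > min(nrow(X) - 1, ncol(X))) {
    stop("n_components exceeds min(n_regions - 1, n_genes)")
  }
  y0 <- y
  ss_y0 <- sum(y0^2)
  Xk <- X; yk <- y
  K <- n_components
  W <- matrix(0, ncol(X), K)
  Tm <- matrix(0, nrow(X), K)
  explained <- r <- numeric(K)
  for (k in seq_len(K)) {
    w <- drop(crossprod(Xk, yk))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { K <- k - 1; break }
    w <- w / nw
    t <- drop(Xk %*% w)
    tt <- sum(t^2)
    if (stats::cor(t, y0) < 0) { w <- -w; t <- -t }
    b <- sum(t * yk) / tt
    explained[k] <- (b^2 * tt) / ss_y0
    r[k] <- stats::cor(t, y0)
    W[, k] <- w
    Tm[, k] <- t
    Xk <- Xk - t %*% crossprod(t, Xk) / tt
    yk <- yk - b * t
  }
  structure(list(weights = W[, seq_len(K), drop = FALSE],
                 scores = Tm[, seq_len(K), drop = FALSE],
                 explained = explained[seq_len(K)],
                 r = r[seq_len(K)], r1 = r[1],
                 gene_ids = colnames(X)),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d components; component 1: r = %.3f, explained = %.1f%%\n",
              ncol(x$weights), x$r1, 100 * x$explained[1]))
  invisible(x)
}

#' Variogram-matched spatially autocorrelated surrogate maps
#'
#' Null maps preserving the spatial autocorrelation of `map`: each surrogate
#' is a random permutation of the map smoothed with exponential distance
#' kernels over a grid of bandwidths; the bandwidth and an affine rescaling
#' (plus white noise for the nugget) are chosen to minimise squared error to
#' the empirical binned variogram; finally each surrogate is affinely
#' standardised to the source mean and sd. A constant map yields constant
#' surrogates.
#'
#' @param map length-R numeric map.
#' @param distmat R x R Euclidean centroid distance matrix (mm).
#' @param n number of surrogates.
#' @param seed integer seed.
#' @param n_bins number of variogram bins.
#' @param n_bandwidths number of log-spaced kernel bandwidths.
#' @param dmax_q distance quantile bounding the variogram fit.
#' @return object of class `surrogate_ensemble`: `maps` (n x R matrix) and
#'   `params`.
#' @export
make_surrogates <- function(map, distmat, n = 10000, seed = 1L, n_bins = 25,
                            n_bandwidths = 20, dmax_q = 0.7) {
  if (!all(is.finite(map))) stop("map contains non-finite values")
  R <- length(map)
  stopifnot(nrow(distmat) == R, ncol(distmat) == R)
  set.seed(seed)
  params <- list(n_bins = n_bins, n_bandwidths = n_bandwidths,
                 dmax_q = dmax_q, seed = seed)
  if (stats::sd(map) == 0) {
    return(structure(list(maps = matrix(map[1], n, R), params = params),
                     class = "surrogate_ensemble"))
  }
  ut <- which(upper.tri(distmat))
  pr <- arrayInd(ut, dim(distmat))
  d_ut <- distmat[ut]
  dmax <- stats::quantile(d_ut, dmax_q)
  keep <- d_ut <= dmax & d_ut > 0
  pi_ <- pr[keep, 1]; pj <- pr[keep, 2]
  bin <- pmin(n_bins, ceiling(d_ut[keep] / dmax * n_bins))
  bin_n <- tabulate(bin, n_bins)
  occ <- which(bin_n > 0)  # occupied bins only; empty bins carry no constraint
  variogram <- function(M) {
    # M: R x m candidate maps -> |occ| x m binned semivariances
    D2 <- (M[pi_, , drop = FALSE] - M[pj, , drop = FALSE])^2
    0.5 * rowsum(D2, bin) / bin_n[occ]
  }
  v_emp <- drop(variogram(matrix(map, ncol = 1)))
  n_occ <- length(occ)
  # relative weighting: small short-range semivariances (smooth maps) must be
  # matched as carefully as the sill
  wts <- 1 / pmax(v_emp, 0.05 * mean(v_emp))
  wts <- wts / sum(wts)
  d_pos <- d_ut[d_ut > 0]
  bw <- exp(seq(log(min(d_pos) / 2), log(2 * dmax), length.out = n_bandwidths))
  # exponential and Gaussian smoothing kernels over the bandwidth grid
  kernels <- c(
    lapply(bw, function(h) { K <- exp(-distmat / h); K / rowSums(K) }),
    lapply(bw, function(h) { K <- exp(-(distmat / h)^2); K / rowSums(K) })
  )
  # parsimony reference: a distance-free (flat) variogram fit. A smoothed,
  # affinely rescaled candidate replaces the raw permutation only when it
  # explains most of the variogram's deviation from flatness; maps without
  # spatial structure therefore keep the exchangeable permutation null.
  sse_flat <- sum(wts * (v_emp - sum(wts * v_emp))^2)
  sse_margin <- 0.25

  out <- matrix(0, n, R)
  chunk <- 500L
  done <- 0L
  while (done < n) {
    m <- min(chunk, n - done)
    P <- vapply(seq_len(m), function(i) map[sample.int(R)], numeric(R))
    best_sse <- rep(sse_margin * sse_flat, m)
    best <- P
    for (K in kernels) {
      S <- K %*% P
      vc <- variogram(S)
      # weighted affine fit v_emp ~ alpha + beta * v_cand per candidate
      vbar <- drop(wts %*% vc)
      ve_bar <- sum(wts * v_emp)
      vcc <- vc - rep(vbar, each = n_occ)
      cv <- drop(wts %*% (vcc * (v_emp - ve_bar)))
      vv <- drop(wts %*% vcc^2)
      beta <- pmax(0, cv / pmax(vv, 1e-300))
      alpha <- pmax(0, ve_bar - beta * vbar)
      pred <- rep(alpha, each = n_occ) + vc * rep(beta, each = n_occ)
      sse <- drop(wts %*% (pred - v_emp)^2)
      upd <- sse < best_sse
      if (any(upd)) {
        noise <- matrix(stats::rnorm(R * sum(upd)), R)
        best[, upd] <- S[, upd, drop = FALSE] *
          rep(sqrt(beta[upd]), each = R) + noise * rep(sqrt(alpha[upd]), each = R)
        best_sse[upd] <- sse[upd]
      }
    }
    # affine standardisation to the source moments
    mu <- colMeans(best); sdev <- apply(best, 2, stats::sd)
    best <- (best - rep(mu, each = R)) / rep(sdev, each = R) *
      stats::sd(map) + mean(map)
    out[done + seq_len(m), ] <- t(best)
    done <- done + m
  }
  structure(list(maps = out, params = params), class = "surrogate_ensemble")
}

#' Empirical binned variogram of a map
#' @param map length-R numeric map.
#' @param distmat R x R distance matrix.
#' @param n_bins number of bins.
#' @param dmax_q distance quantile cap.
#' @return data.frame with bin midpoints `distance` and semivariance `gamma`.
#' @export
map_variogram <- function(map, distmat, n_bins = 25, dmax_q = 0.7) {
  ut <- which(upper.tri(distmat))
  pr <- arrayInd(ut, dim(distmat))
  d_ut <- distmat[ut]
  dmax <- stats::quantile(d_ut, dmax_q)
  keep <- d_ut <= dmax & d_ut > 0
  bin <- pmin(n_bins, ceiling(d_ut[keep] / dmax * n_bins))
  diffs <- (map[pr[keep, 1]] - map[pr[keep, 2]])^2
  out <- data.frame(distance = (seq_len(n_bins) - 0.5) / n_bins * dmax,
                    gamma = 0.5 * as.numeric(tapply(diffs, factor(bin, seq_len(n_bins)), mean)))
  out[!is.na(out$gamma), ]
}

#' Add-one permutation p-value against surrogate correlations
#'
#' Two-sided: `p = (1 + #{|r_null| >= |r_obs|}) / (n + 1)`; depends only on
#' the rank of `|r_obs|` among the null values.
#'
#' @param observed_r observed correlation.
#' @param surrogate_rs null correlations.
#' @return scalar p-value in (0, 1].
#' @export
sac_pvalue <- function(observed_r, surrogate_rs) {
  (1 + sum(abs(surrogate_rs) >= abs(observed_r))) / (length(surrogate_rs) + 1)
}

#' Spatial-autocorrelation-corrected test of the PLS component-1 association
#'
#' Refits the first PLS component against every surrogate map and compares
#' the observed score-map correlation with the null correlations.
#'
#' @param X standardised regions x genes matrix.
#' @param y standardised response map.
#' @param surrogates a `surrogate_ensemble` of `y` (or n x R matrix).
#' @return list with `r1`, `p_sac`, `null_r`.
#' @export
pls_sac_test <- function(X, y, surrogates) {
  S <- if (inherits(surrogates, "surrogate_ensemble")) surrogates$maps else surrogates
  r_obs <- pls_fit(X, y, n_components = 1)$r1
  null_r <- apply(S, 1, function(ys) {
    ys <- as.numeric(scale(ys))
    w <- drop(crossprod(X, ys))
    t <- drop(X %*% w)
    stats::cor(t, ys)
  })
  list(r1 = r_obs, p_sac = sac_pvalue(r_obs, null_r), null_r = null_r)
}

#' Bootstrap z-scores for PLS component-1 gene weights
#'
#' Resamples regions with replacement, refits component 1, aligns each
#' replicate's sign to the full-data component (sign of the weight-vector
#' correlation), and returns `z = weight / bootstrap SD` with two-sided
#' normal p-values and Bonferroni selection.
#'
#' @param X standardised regions x genes matrix.
#' @param y standardised response map.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param alpha Bonferroni selection level (family-wise, across genes).
#' @return data.frame of class `gene_weight_table`: `gene`, `weight`, `z`,
#'   `p`, `selected` in {"positive","negative","none"}.
#' @export
bootstrap_gene_weights <- function(X, y, n_boot = 1000, seed = 1L, alpha = 0.01) {
  set.seed(seed)
  X <- as.matrix(X); y <- as.numeric(y)
  Rc <- nrow(X)
  w_full <- drop(crossprod(X, y))
  w_full <- w_full / sqrt(sum(w_full^2))
  if (stats::cor(drop(X %*% w_full), y) < 0) w_full <- -w_full
  draws <- matrix(0, ncol(X), n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(Rc, replace = TRUE)
    yb <- y[idx]
    if (stats::sd(yb) == 0) stop("bootstrap sample has zero variance in y")
    # the refit reapplies the full estimator, including standardisation of
    # the resampled response and gene columns
    yb <- (yb - mean(yb)) / stats::sd(yb)
    Xb <- X[idx, , drop = FALSE]
    mu <- colMeans(Xb)
    sds <- sqrt(colMeans(Xb^2) - mu^2) * sqrt(Rc / (Rc - 1))
    sds[sds == 0] <- 1
    Xb <- (Xb - rep(mu, each = Rc)) / rep(sds, each = Rc)
    wb <- drop(crossprod(Xb, yb))
    nb <- sqrt(sum(wb^2))
    if (nb > 0) wb <- wb / nb
    if (sum(wb * w_full) < 0) wb <- -wb
    draws[, b] <- wb
  }
  sd_boot <- apply(draws, 1, stats::sd)
  z <- ifelse(sd_boot > 0, w_full / sd_boot, sign(w_full) * Inf)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(gene = colnames(X) %||% sprintf("g%d", seq_len(ncol(X))),
                    weight = w_full, z = z, p = p,
                    stringsAsFactors = FALSE)
  out$selected <- select_genes(out, alpha = alpha, label_only = TRUE)
  class(out) <- c("gene_weight_table", "data.frame")
  out
}

#' Bonferroni gene selection
#'
#' A gene is selected iff `p * G < alpha` (strict), with direction given by
#' the sign of its weight.
#'
#' @param table a `gene_weight_table` (columns `gene`, `weight`, `p`).
#' @param alpha family-wise selection level (default 1%).
#' @param label_only return the per-gene label vector instead of lists.
#' @return list with `positive` and `negative` gene id vectors (or a label
#'   vector when `label_only`).
#' @export
select_genes <- function(table, alpha = 0.01, label_only = FALSE) {
  G <- nrow(table)
  sel <- table$p * G < alpha
  lab <- ifelse(sel & table$weight > 0, "positive",
                ifelse(sel & table$weight < 0, "negative", "none"))
  if (label_only) return(lab)
  list(positive = table$gene[lab == "positive"],
       negative = table$gene[lab == "negative"])
}
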