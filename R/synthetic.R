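#' Sample a smooth spatial field over region centroids
#'
#' Gaussian-process draw with squared-exponential covariance
#' `exp(-d^2 / (2 * length_scale^2))` over Euclidean centroid distances, used
#' for planted slope fields, expression components and cortical maps.
#'
#' @param centroids R x 3 matrix of centroid coordinates (mm).
#' @param length_scale spatial correlation length (mm).
#' @param n number of independent fields.
#' @return R x n matrix of standard-normal-marginal spatially smooth fields.
#' @export
gp_field <- function(centroids, length_scale = 20, n = 1) {
  d <- as.matrix(stats::dist(centroids))
  K <- exp(-d^2 / (2 * length_scale^2))
  diag(K) <- diag(K) + 1e-8
  L <- chol(K)
  z <- matrix(stats::rnorm(nrow(d) * n), nrow(d), n)
  crossprod(L, z)
}

#' Generate a synthetic region table
#'
#' Centroids are sampled in one hemisphere of a 140 x 170 x 120 mm bounding
#' box and mirrored across x = 0, so `R/2` regions per hemisphere. Module
#' labels come from spatial k-means (8 modules, fewer with a warning when R
#' is small); a fraction of regions nearest the midline centre are flagged
#' subcortical.
#'
#' @param R number of regions (even).
#' @param seed integer seed.
#' @param n_modules target number of functional modules.
#' @param subcortical_frac fraction of regions flagged non-cortical.
#' @return a region table (see [read_region_table()]).
#' @export
make_regions <- function(R = 90, seed = 1L, n_modules = 8, subcortical_frac = 0.1) {
  if (R %% 2 != 0) stop("R must be even (hemisphere mirroring)")
  set.seed(seed)
  half <- R / 2
  right <- cbind(x = stats::runif(half, 4, 70),
                 y = stats::runif(half, -85, 85),
                 z = stats::runif(half, -60, 60))
  left <- right
  left[, "x"] <- -left[, "x"]
  xyz <- rbind(right, left)
  k <- if (R >= 2 * n_modules) n_modules else max(1, floor(R / 2))
  if (k < n_modules) warning(sprintf("only %d regions: using %d modules", R, k))
  km <- stats::kmeans(xyz, centers = k, nstart = 5)
  dist0 <- sqrt(rowSums(xyz^2))
  n_sub <- floor(subcortical_frac * R)
  subcortical <- rank(dist0, ties.method = "first") <= n_sub
  data.frame(
    id = seq_len(R),
    name = sprintf("region_%03d_%s", seq_len(R), rep(c("R", "L"), each = half)),
    hemisphere = rep(c("R", "L"), each = half),
    x = xyz[, "x"], y = xyz[, "y"], z = xyz[, "z"],
    module = paste0("module", km$cluster),
    cortical = !subcortical,
    stringsAsFactors = FALSE
  )
}

#' Default cohort-generator parameters
#'
#' Baseline edge weights decay exponentially with centroid distance and are
#' thresholded to a target density; the planted nodal slope field is a smooth
#' spatial process; subject heterogeneity enters as random intercepts and
#' random age slopes; ages are centred at 9.5 years so the planted slope is
#' the original-scale age coefficient.
#'
#' @return named list of generator parameters.
#' @export
cohort_params <- function() {
  list(
    weight_scale = 15,      # baseline edge weight at zero distance
    dist_decay = 70,        # mm, exponential decay of baseline weight
    density = 0.15,         # group edge density after thresholding
    slope_mean = 0.35,      # mean of the planted nodal slope field
    slope_sd = 0.15,        # spatial sd of the planted nodal slope field
    slope_scale = 20,       # mm, spatial length-scale of the slope field
    sigma_u = 0.5,          # subject random intercept sd (edge units)
    sigma_b = 0.05,         # subject random age-slope sd
    sigma_eps = 0.3,        # per-edge per-scan residual sd
    age_center = 9.5,       # years
    age_range_w1 = c(6, 11),# uniform wave-1 age
    wave_gap = 1,           # years between waves
    dropout = 0.3,          # per-wave dropout probability
    length_noise = 5        # mm sd of streamline-length noise
  )
}

#' Simulate a longitudinal scan design (no connectomes)
#'
#' Subjects enter at a uniform wave-1 age, return in yearly waves with
#' per-wave dropout, and carry sex, total brain volume and centre covariates.
#'
#' @param n_subjects number of subjects.
#' @param waves maximum number of waves (1-3).
#' @param seed integer seed.
#' @param params generator parameters ([cohort_params()]).
#' @return data.frame with columns `subject`, `wave`, `age`, `sex`, `tbv`,
#'   `centre`.
#' @export
simulate_design <- function(n_subjects = 200, waves = 3, seed = 1L,
                            params = cohort_params()) {
  set.seed(seed)
  age1 <- stats::runif(n_subjects, params$age_range_w1[1], params$age_range_w1[2])
  sex <- sample(c("F", "M"), n_subjects, replace = TRUE)
  centre <- sample(c("centre1", "centre2"), n_subjects, replace = TRUE)
  tbv0 <- stats::rnorm(n_subjects, 1.45e6, 8e4)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    for (w in seq_len(waves)) {
      if (w > 1 && stats::runif(1) < params$dropout) break
      age <- age1[i] + (w - 1) * params$wave_gap + stats::rnorm(1, 0, 0.05)
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("sub%04d", i), wave = w, age = age,
        sex = sex[i], tbv = tbv0[i] + 5e3 * (age - params$age_center),
        centre = centre[i], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate a scalar longitudinal response with known fixed and random effects
#'
#' Generates `y = b0 + (beta_age + b_i) * (age - center) + beta_quad *
#' (age - center)^2 + beta_sex * 1(male) + u_i + eps`, the structure the
#' trajectory models assume, for parameter-recovery and calibration studies.
#'
#' @param design data.frame from [simulate_design()] (or `cohort$scans`).
#' @param beta_age planted age slope (per year).
#' @param beta_quad planted quadratic age coefficient (0 = linear truth).
#' @param beta_sex planted sex effect.
#' @param sigma_u subject random intercept sd.
#' @param sigma_b subject random age-slope sd.
#' @param sigma_eps residual sd.
#' @param age_center centring constant (years).
#' @param seed integer seed.
#' @return numeric vector of responses aligned with `design` rows.
#' @export
simulate_trajectory_response <- function(design, beta_age = 0.35, beta_quad = 0,
                                         beta_sex = 0.1, sigma_u = 0.5,
                                         sigma_b = 0.05, sigma_eps = 0.3,
                                         age_center = 9.5, seed = 1L) {
  set.seed(seed)
  subs <- unique(design$subject)
  u <- stats::setNames(stats::rnorm(length(subs), 0, sigma_u), subs)
  b <- stats::setNames(stats::rnorm(length(subs), 0, sigma_b), subs)
  ac <- design$age - age_center
  2 + u[design$subject] + (beta_age + b[design$subject]) * ac +
    beta_quad * ac^2 + beta_sex * (design$sex == "M") +
    stats::rnorm(nrow(design), 0, sigma_eps)
}

#' Simulate a longitudinal connectome cohort with a planted slope field
#'
#' Baseline edge weights `mu_e = c * exp(-d_e / lambda)` are thresholded to
#' the target density; a smooth nodal slope field `f` gives each kept edge a
#' developmental slope `s_e = (f_a + f_b) / 2`; scan weights add subject
#' random intercepts/slopes and residual noise and are truncated at zero.
#' Lengths are centroid distances plus noise.
#'
#' @param regions region table ([make_regions()]).
#' @param n_subjects number of subjects.
#' @param waves maximum waves.
#' @param seed integer seed.
#' @param params generator parameters ([cohort_params()]).
#' @param null_slopes set `TRUE` to zero the slope field (no-age-effect null).
#' @return list with `cohort` and `truth` (latent field, edge slopes, planted
#'   per-node strength slopes, subject effects, truncation rate).
#' @export
simulate_cohort <- function(regions, n_subjects = 200, waves = 3, seed = 1L,
                            params = cohort_params(), null_slopes = FALSE) {
  design <- simulate_design(n_subjects, waves, seed = seed, params = params)
  set.seed(seed + 1L)
  xyz <- as.matrix(regions[c("x", "y", "z")])
  R <- nrow(regions)
  d <- as.matrix(stats::dist(xyz))
  mu <- params$weight_scale * exp(-d / params$dist_decay)
  ut <- upper.tri(mu)
  thr <- stats::quantile(mu[ut], 1 - params$density)
  support <- mu > thr & ut
  support <- support | t(support)
  mu[!support] <- 0

  f <- params$slope_mean + params$slope_sd *
    as.numeric(gp_field(xyz, params$slope_scale, 1))
  if (null_slopes) f <- rep(0, R)
  s <- (outer(f, rep(1, R)) + outer(rep(1, R), f)) / 2
  s[!support] <- 0

  lengths <- d + abs(stats::rnorm(R * R, 0, params$length_noise))
  lengths <- (lengths + t(lengths)) / 2
  lengths[!support] <- 0
  diag(lengths) <- 0

  subs <- unique(design$subject)
  u <- stats::setNames(stats::rnorm(length(subs), 0, params$sigma_u), subs)
  b <- stats::setNames(stats::rnorm(length(subs), 0, params$sigma_b), subs)

  sup_idx <- which(support & upper.tri(support))
  n_trunc <- 0; n_vals <- 0
  conns <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    ac <- design$age[k] - params$age_center
    si <- design$subject[k]
    w_ut <- mu[sup_idx] + s[sup_idx] * ac + u[si] + b[si] * ac +
      stats::rnorm(length(sup_idx), 0, params$sigma_eps)
    n_trunc <- n_trunc + sum(w_ut < 0)
    n_vals <- n_vals + length(w_ut)
    w_ut[w_ut < 0] <- 0
    W <- matrix(0, R, R)
    W[sup_idx] <- w_ut
    W <- W + t(W)
    conns[[k]] <- connectome(W, lengths)
  }
  cohort <- as_cohort(design, conns, regions)
  truth <- list(
    latent_field = f,
    edge_slopes = s,
    strength_slope = rowSums(s),
    subject_intercepts = u,
    subject_slopes = b,
    support = support,
    truncation_rate = n_trunc / n_vals,
    params = params
  )
  list(cohort = cohort, truth = truth)
}

#' Simulate a region-by-gene expression matrix with one planted component
#'
#' A latent spatial component is built to have exact Pearson correlation
#' `coupling_r` with the (standardised, cortical-subset) slope field; each
#' gene loads on it with weight +1/-1 (true-support genes) or 0 (decoys).
#' The remaining expression variance is shared co-expression structure — a
#' small number of spatially autocorrelated factors with random gene
#' loadings — plus a little independent noise, mirroring the low effective
#' dimensionality of regional transcriptomes.
#'
#' @param regions region table.
#' @param slope_field length-R nodal slope field to couple to (e.g. the
#'   planted `latent_field`); defaults to a fresh smooth field.
#' @param G number of genes.
#' @param n_true number of true-support genes (half positive, half negative).
#' @param coupling_r target correlation between latent component and slope
#'   field over cortical regions.
#' @param sa_scale spatial length-scale (mm) of expression factors.
#' @param n_factors number of shared co-expression factors.
#' @param noise_sd total non-component noise sd relative to unit component
#'   loading (split between shared factors and a white residual).
#' @param seed integer seed.
#' @return list with `expression` (class `expression_matrix`: `values`,
#'   `gene_ids`, `region_ids`) and `truth` (`true_weights` signed length-G,
#'   `support` gene ids, `latent`).
#' @export
simulate_expression <- function(regions, slope_field = NULL, G = 500,
                                n_true = 50, coupling_r = 0.5, sa_scale = 20,
                                n_factors = 10, noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  cort <- which(regions$cortical)
  xyz <- as.matrix(regions[cort, c("x", "y", "z")])
  Rc <- length(cort)
  if (is.null(slope_field)) {
    slope_field <- rep(NA_real_, nrow(regions))
    slope_field[cort] <- as.numeric(gp_field(xyz, sa_scale, 1))
  }
  f <- as.numeric(scale(slope_field[cort]))
  g0 <- as.numeric(gp_field(xyz, sa_scale, 1))
  g0 <- as.numeric(scale(stats::resid(stats::lm(g0 ~ f))))
  latent <- coupling_r * f + sqrt(1 - coupling_r^2) * g0

  w_true <- numeric(G)
  support <- sample.int(G, n_true)
  w_true[support[seq_len(floor(n_true / 2))]] <- 1
  w_true[support[(floor(n_true / 2) + 1):n_true]] <- -1

  # shared spatially autocorrelated co-expression factors + white residual
  Fac <- gp_field(xyz, sa_scale, n_factors)
  L <- matrix(stats::rnorm(n_factors * G, 0, 1 / sqrt(n_factors)), n_factors, G)
  X <- outer(latent, w_true) +
    noise_sd * (sqrt(0.9) * Fac %*% L + sqrt(0.1) * matrix(stats::rnorm(Rc * G), Rc, G))
  gene_ids <- sprintf("gene%04d", seq_len(G))
  colnames(X) <- gene_ids
  expr <- structure(list(values = X, gene_ids = gene_ids,
                         region_ids = regions$id[cort]),
                    class = "expression_matrix")
  list(expression = expr,
       truth = list(true_weights = w_true, support = gene_ids[sort(support)],
                    latent = latent, coupling_r = coupling_r))
}

#' Simulate gene annotations: cell classes and categories
#'
#' Every gene is assigned to exactly one of the seven canonical cell classes;
#' 80% of the positive true-support genes are concentrated in one designated
#' class. Categories comprise the positive and negative halves of the true
#' support (sign-coherent, as in separate positive/negative gene-list
#' enrichment) plus random decoys.
#'
#' @param gene_ids character vector of gene ids (the universe).
#' @param expr_truth `truth` element from [simulate_expression()].
#' @param n_decoys number of decoy categories.
#' @param seed integer seed.
#' @return list with `cell_annotation` (data.frame gene, class),
#'   `categories` (named list of gene vectors; `true_support` plus decoys)
#'   and `enriched_class`.
#' @export
simulate_annotations <- function(gene_ids, expr_truth, n_decoys = 15, seed = 1L) {
  set.seed(seed)
  classes <- c("astrocytes", "endothelial", "excitatory", "inhibitory",
               "microglia", "oligodendrocytes", "OPC")
  enriched <- "excitatory"
  cls <- sample(classes, length(gene_ids), replace = TRUE)
  names(cls) <- gene_ids
  pos <- gene_ids[expr_truth$true_weights > 0]
  relocate <- pos[stats::runif(length(pos)) < 0.8]
  cls[relocate] <- enriched
  categories <- list(
    true_support_pos = gene_ids[expr_truth$true_weights > 0],
    true_support_neg = gene_ids[expr_truth$true_weights < 0]
  )
  size <- length(categories$true_support_pos)
  for (k in seq_len(n_decoys)) {
    categories[[sprintf("decoy%02d", k)]] <- sample(gene_ids, size)
  }
  list(cell_annotation = data.frame(gene = gene_ids, class = unname(cls),
                                    stringsAsFactors = FALSE),
       categories = categories, enriched_class = enriched)
}

#' Simulate cytoarchitectural cortical maps with planted correlations
#'
#' Each map is `rho * z(slope) + sqrt(1 - rho^2) * z(noise)` with the noise a
#' smooth spatial field residualised on the slope, so the planted Pearson
#' correlation is exact (Spearman approximately so). When `partial_target`
#' names one of six laminar maps, that lamina is built from the slope field
#' and the remaining five from independent fields, planting a single
#' conditionally dependent lamina.
#'
#' @param regions region table.
#' @param slope_field length-R field (cortical entries used).
#' @param target_rhos named vector of planted correlations; defaults mirror
#'   plausible myelin/laminar/thickness couplings.
#' @param sa_scale spatial length-scale (mm) of map noise.
#' @param partial_target optional lamina name (`"L1"`..`"L6"`) to make the
#'   single conditionally dependent lamina (its rho applies; other laminas'
#'   rhos are set to 0).
#' @param seed integer seed.
#' @return list with `maps` (Rc x n matrix, columns named), `region_ids`,
#'   `target_rhos`.
#' @export
simulate_cortical_maps <- function(regions, slope_field,
                                   target_rhos = c(myelin = 0.4, L1 = -0.37,
                                                   L2 = 0, L3 = 0, L4 = 0.4,
                                                   L5 = -0.38, L6 = -0.43,
                                                   thickness = -0.39),
                                   sa_scale = 20, partial_target = NULL,
                                   seed = 1L) {
  set.seed(seed)
  cort <- which(regions$cortical)
  xyz <- as.matrix(regions[cort, c("x", "y", "z")])
  f <- as.numeric(scale(slope_field[cort]))
  if (!is.null(partial_target)) {
    laminas <- paste0("L", 1:6)
    if (!partial_target %in% laminas) stop("partial_target must be one of L1..L6")
    target_rhos[setdiff(laminas, partial_target)] <- 0
  }
  maps <- sapply(names(target_rhos), function(nm) {
    rho <- target_rhos[[nm]]
    g <- as.numeric(gp_field(xyz, sa_scale, 1))
    g <- as.numeric(scale(stats::resid(stats::lm(g ~ f))))
    rho * f + sqrt(1 - rho^2) * g
  })
  colnames(maps) <- names(target_rhos)
  list(maps = maps, region_ids = regions$id[cort], target_rhos = target_rhos)
}
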