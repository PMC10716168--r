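make_aligned <- function(coupling_r = 1, seed = 5) {
  regions <- test_regions()
  cortix <- which(regions$cortical)
  xyzc <- as.matrix(regions[cortix, c("x", "y", "z")])
  key <- sprintf("aligned_%g_%d", coupling_r, seed)
  cached(key, {
    set.seed(1000 + seed)
    f <- rep(NA_real_, nrow(regions))
    f[cortix] <- 0.35 + 0.15 * as.numeric(gp_field(xyzc, 20, 1))
    ex <- simulate_expression(regions, f, coupling_r = coupling_r, seed = seed)
    al <- align_expression(f, ex$expression, regions)
    list(al = al, truth = ex$truth, f = f, dist = as.matrix(stats::dist(xyzc)))
  })
}

test_that("alignment restricts to shared cortical regions and standardises", {
  regions <- test_regions()
  obj <- make_aligned()
  al <- obj$al
  expect_equal(length(al$y), sum(regions$cortical))
  expect_equal(mean(al$y), 0, tolerance = 1e-12)
  expect_equal(unname(apply(al$X[, 1:5], 2, stats::sd)), rep(1, 5))
  # constant gene column is dropped with a warning
  ex2 <- list(values = cbind(al$X, const = 1), gene_ids = c(al$gene_ids, "const"),
              region_ids = al$region_ids)
  class(ex2) <- "expression_matrix"
  expect_warning(al2 <- align_expression(obj$f, ex2, regions), "constant")
  expect_false("const" %in% al2$gene_ids)
  # disjoint regions error
  ex3 <- ex2; ex3$region_ids <- ex2$region_ids + 10000
  expect_error(suppressWarnings(align_expression(obj$f, ex3, regions)), "fewer than 10")
})

test_that("PLS explains a noiseless rank-one response completely", {
  set.seed(21)
  y <- stats::rnorm(40)
  w <- stats::rnorm(30)
  X <- outer(y, w)  # every gene proportional to y
  X <- X + 1e-12 * matrix(stats::rnorm(1200), 40)
  pls <- pls_fit(scale(X), as.numeric(scale(y)), n_components = 3)
  expect_equal(pls$explained[1], 1, tolerance = 1e-6)
  expect_equal(pls$r1, 1, tolerance = 1e-6)
  expect_error(pls_fit(X, y, n_components = 45), "n_components")
})

test_that("response negation flips weights but not explained variance; r1 >= 0", {
  obj <- make_aligned()
  p1 <- pls_fit(obj$al$X, obj$al$y, 5)
  p2 <- pls_fit(obj$al$X, -obj$al$y, 5)
  expect_equal(p1$explained, p2$explained, tolerance = 1e-9)
  expect_equal(p1$weights, -p2$weights, tolerance = 1e-9)
  expect_gte(p1$r1, 0)
  expect_gte(p2$r1, 0)
})

test_that("planted component weights are recovered at default generator settings", {
  obj <- make_aligned(coupling_r = 1)
  pls <- pls_fit(obj$al$X, obj$al$y, 10)
  wt <- obj$truth$true_weights[match(obj$al$gene_ids,
                                     sprintf("gene%04d", seq_along(obj$truth$true_weights)))]
  expect_gt(stats::cor(abs(pls$weights[, 1]), abs(wt)), 0.9)
  expect_gt(pls$explained[1], 0.5)
})

test_that("surrogates match the source variogram and moments", {
  obj <- make_aligned()
  y <- obj$al$y
  ens <- make_surrogates(y, obj$dist, n = 100, seed = 31)
  v0 <- map_variogram(y, obj$dist)
  vs <- rowMeans(sapply(1:100, function(i) map_variogram(ens$maps[i, ], obj$dist)$gamma))
  expect_lt(sum(abs(vs - v0$gamma)) / sum(v0$gamma), 0.2)
  expect_equal(rowMeans(ens$maps), rep(mean(y), 100), tolerance = 1e-8)
  expect_equal(apply(ens$maps, 1, stats::sd), rep(stats::sd(y), 100), tolerance = 1e-8)
  # determinism and degenerate input
  ens2 <- make_surrogates(y, obj$dist, n = 100, seed = 31)
  expect_identical(ens$maps, ens2$maps)
  cns <- make_surrogates(rep(2, length(y)), obj$dist, n = 5, seed = 1)
  expect_true(all(cns$maps == 2))
  expect_error(make_surrogates(c(y[-1], NA), obj$dist), "non-finite")
})

test_that("surrogates of a spatially unstructured map look like plain permutations", {
  obj <- make_aligned()
  set.seed(41)
  y <- stats::rnorm(nrow(obj$dist))
  ens <- make_surrogates(y, obj$dist, n = 60, seed = 42)
  v_sur <- as.numeric(sapply(1:60, function(i) map_variogram(ens$maps[i, ], obj$dist)$gamma))
  v_perm <- as.numeric(sapply(1:60, function(i) map_variogram(sample(y), obj$dist)$gamma))
  expect_gt(suppressWarnings(stats::ks.test(v_sur, v_perm)$p.value), 0.01)
})

test_that("add-one permutation p is rank-based with the documented extremes", {
  expect_equal(sac_pvalue(0.9, stats::runif(999, -0.5, 0.5)), 1 / 1000)
  nulls <- c(-0.8, -0.2, 0.1, 0.5, 0.9)
  expect_equal(sac_pvalue(0.5, nulls), (1 + 3) / 6)  # |r| at the null median
  expect_equal(sac_pvalue(0.1, nulls), 1)
  # depends only on the rank of |r_obs|
  expect_equal(sac_pvalue(0.3, nulls), sac_pvalue(-0.35, nulls))
})

test_that("SAC-corrected PLS test rejects a planted coupling, not a decoupled null", {
  obj <- make_aligned(coupling_r = 0.5, seed = 6)
  ens <- make_surrogates(obj$al$y, obj$dist, n = 300, seed = 51)
  tst <- pls_sac_test(obj$al$X, obj$al$y, ens)
  expect_lt(tst$p_sac, 0.05)
  obj0 <- make_aligned(coupling_r = 0, seed = 7)
  ens0 <- make_surrogates(obj0$al$y, obj0$dist, n = 300, seed = 52)
  tst0 <- pls_sac_test(obj0$al$X, obj0$al$y, ens0)
  expect_gt(tst0$p_sac, 0.05)
})

test_that("bootstrap z ranks true-support genes at the top, reproducibly", {
  obj <- make_aligned(coupling_r = 1)
  gw <- bootstrap_gene_weights(obj$al$X, obj$al$y, n_boot = 200, seed = 61)
  is_true <- gw$gene %in% obj$truth$support
  rank_ratio <- rank(-abs(gw$z)) / nrow(gw)
  expect_lt(stats::median(rank_ratio[is_true]), 0.1)
  gw2 <- bootstrap_gene_weights(obj$al$X, obj$al$y, n_boot = 200, seed = 61)
  expect_identical(gw, gw2)
})

test_that("Bonferroni selection is strict and sign-labelled", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    weight = c(2, -1, 0.5),
                    p = c(1e-9, 1, 0.01 / 3))  # c sits exactly at the boundary
  sel <- select_genes(tab, alpha = 0.01)
  expect_equal(sel$positive, "a")
  expect_equal(sel$negative, character(0))
  tab2 <- data.frame(gene = "x", weight = 1, p = 1)
  expect_equal(select_genes(tab2)$positive, character(0))
})
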