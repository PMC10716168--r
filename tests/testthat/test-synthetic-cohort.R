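test_that("generated regions mirror hemispheres and degrade module count gracefully", {
  regions <- test_regions()
  expect_equal(sum(regions$hemisphere == "L"), 45)
  expect_equal(sort(regions$x[regions$hemisphere == "L"]),
               sort(-regions$x[regions$hemisphere == "R"]))
  expect_equal(length(unique(regions$module)), 8)
  expect_true(all(table(regions$cortical)["FALSE"] == 9))
  expect_identical(make_regions(90, seed = 42), regions)
  expect_warning(small <- make_regions(4, seed = 1), "modules")
  expect_lte(length(unique(small$module)), 4)
  expect_error(make_regions(5), "even")
})

test_that("simulated cohorts satisfy connectome invariants and dropout structure", {
  regions <- test_regions()
  sim <- cached("sim_small", simulate_cohort(regions, n_subjects = 30, seed = 3))
  coh <- sim$cohort
  expect_s3_class(coh, "cohort")
  for (cn in coh$connectomes[1:3]) {
    expect_equal(cn$weights, t(cn$weights))
    expect_true(all(diag(cn$weights) == 0))
    expect_true(all(cn$weights >= 0))
    # lengths share the support of weights
    expect_equal(cn$lengths > 0, cn$weights > 0)
  }
  expect_true(all(coh$scans$age >= 6 & coh$scans$age <= 13.5))
  expect_true(all(table(coh$scans$subject) <= 3))
  expect_lt(sim$truth$truncation_rate, 0.01)
})

test_that("a noise-free cohort reproduces the planted edge slopes exactly", {
  regions <- make_regions(20, seed = 4)
  p <- cohort_params()
  p$sigma_u <- p$sigma_b <- p$sigma_eps <- 0
  p$dropout <- 0
  sim <- simulate_cohort(regions, n_subjects = 8, seed = 5, params = p)
  coh <- sim$cohort
  ij <- which(sim$truth$support & upper.tri(sim$truth$support), arr.ind = TRUE)[1:5, ]
  ages <- coh$scans$age - p$age_center
  for (r in seq_len(nrow(ij))) {
    w <- vapply(coh$connectomes, function(cn) cn$weights[ij[r, 1], ij[r, 2]], 0)
    slope <- stats::coef(stats::lm(w ~ ages))[2]
    expect_equal(unname(slope), sim$truth$edge_slopes[ij[r, 1], ij[r, 2]],
                 tolerance = 1e-8)
  }
})

test_that("full dropout after wave 1 leaves single-scan subjects", {
  regions <- make_regions(20, seed = 4)
  p <- cohort_params(); p$dropout <- 1
  sim <- simulate_cohort(regions, n_subjects = 10, seed = 6, params = p)
  expect_true(all(table(sim$cohort$scans$subject) == 1))
})

test_that("expression generator hits the target slope-field coupling exactly", {
  regions <- test_regions()
  cortix <- which(regions$cortical)
  set.seed(7)
  f <- rep(NA_real_, nrow(regions))
  f[cortix] <- stats::rnorm(length(cortix))
  for (r in c(0, 0.5, 1)) {
    ex <- simulate_expression(regions, f, G = 60, n_true = 10, coupling_r = r, seed = 8)
    expect_equal(stats::cor(ex$truth$latent, f[cortix]), r, tolerance = 1e-10)
  }
  ex <- simulate_expression(regions, f, seed = 9)
  expect_equal(sum(ex$truth$true_weights > 0), 25)
  expect_equal(sum(ex$truth$true_weights < 0), 25)
  expect_identical(simulate_expression(regions, f, seed = 9)$expression$values,
                   ex$expression$values)
})

test_that("annotations cover every gene once and concentrate the planted class", {
  regions <- test_regions()
  cortix <- which(regions$cortical)
  set.seed(10)
  f <- rep(NA_real_, nrow(regions)); f[cortix] <- stats::rnorm(length(cortix))
  ex <- simulate_expression(regions, f, seed = 11)
  ann <- simulate_annotations(ex$expression$gene_ids, ex$truth, seed = 12)
  expect_equal(sort(ann$cell_annotation$gene), sort(ex$expression$gene_ids))
  expect_false(any(duplicated(ann$cell_annotation$gene)))
  pos <- ex$expression$gene_ids[ex$truth$true_weights > 0]
  cls <- ann$cell_annotation$class[match(pos, ann$cell_annotation$gene)]
  expect_gt(mean(cls == ann$enriched_class), 0.6)
  expect_equal(ann$categories$true_support_pos, pos)
})

test_that("cortical map generator plants exact Pearson correlations", {
  regions <- test_regions()
  cortix <- which(regions$cortical)
  set.seed(13)
  f <- rep(NA_real_, nrow(regions)); f[cortix] <- stats::rnorm(length(cortix))
  cm <- simulate_cortical_maps(regions, f, seed = 14)
  for (nm in colnames(cm$maps)) {
    expect_equal(stats::cor(cm$maps[, nm], f[cortix]), cm$target_rhos[[nm]],
                 tolerance = 1e-10)
  }
  cm_rho1 <- simulate_cortical_maps(regions, f, target_rhos = c(myelin = 1), seed = 15)
  expect_equal(stats::cor(cm_rho1$maps[, 1], f[cortix], method = "spearman"), 1)
})
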