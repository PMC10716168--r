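test_that("a noise-free linear response is interpolated exactly", {
  des <- simulate_design(30, seed = 1)
  y <- 2 + 0.5 * des$age
  fit <- suppressWarnings(fit_lmm(y, des, "linear"))
  expect_equal(fit$beta_age, 0.5, tolerance = 1e-6)
  expect_lt(fit$residual_variance, 1e-10)
})

test_that("planted fixed effects are recovered from a noisy longitudinal design", {
  des <- simulate_design(150, seed = 2)
  y <- simulate_trajectory_response(des, beta_age = 0.35, beta_sex = 0.1, seed = 3)
  fit <- fit_lmm(y, des, "linear")
  expect_lt(abs(fit$beta_age - 0.35), 3 * fit$se_age)
  expect_true(fit$ci_age[1] < fit$beta_age && fit$beta_age < fit$ci_age[2])
  expect_lt(abs(fit$betas[["sexM"]] - 0.1), 0.1)
  # ML mixed fit is at least as good as the fixed-effects-only OLS fit
  ols <- stats::lm(y ~ I(des$age - mean(des$age)) + des$sex + scale(des$tbv) + des$centre)
  expect_gte(fit$loglik, as.numeric(stats::logLik(ols)) - 1e-6)
})

test_that("beta_age is invariant to shifting total brain volume", {
  des <- simulate_design(60, seed = 4)
  y <- simulate_trajectory_response(des, seed = 5)
  f1 <- fit_lmm(y, des, "linear")
  des2 <- des; des2$tbv <- des2$tbv + 1e5
  f2 <- fit_lmm(y, des2, "linear")
  expect_equal(f1$beta_age, f2$beta_age, tolerance = 1e-6)
})

test_that("AIC selection prefers the generating model and breaks ties to simpler", {
  des <- simulate_design(120, seed = 6)
  y_lin <- simulate_trajectory_response(des, beta_age = 0.35, seed = 7)
  fits <- list(linear = fit_lmm(y_lin, des, "linear"),
               quadratic = suppressWarnings(fit_lmm(y_lin, des, "quadratic")))
  expect_equal(aic_select(fits), "linear")
  y_quad <- simulate_trajectory_response(des, beta_age = 0.1, beta_quad = 0.08, seed = 8)
  fits_q <- list(linear = fit_lmm(y_quad, des, "linear"),
                 quadratic = suppressWarnings(fit_lmm(y_quad, des, "quadratic")))
  expect_equal(aic_select(fits_q), "quadratic")
  # exact tie goes to the model with fewer parameters
  tie <- list(quadratic = list(aic = 10, n_params = 9),
              linear = list(aic = 10, n_params = 7))
  expect_equal(aic_select(tie), "linear")
})

test_that("interaction model carries an age-by-sex term", {
  des <- simulate_design(80, seed = 9)
  y <- simulate_trajectory_response(des, seed = 10)
  fit <- fit_lmm(y, des, "interaction")
  expect_true(any(grepl("age_c:sex", names(fit$betas))))
})

test_that("single-scan subjects drop the random age slope with a warning", {
  des <- simulate_design(40, seed = 11)
  des <- des[!duplicated(des$subject), ]
  y <- simulate_trajectory_response(des, seed = 12)
  w <- capture_warnings(fit <- fit_lmm(y, des, "linear"))
  expect_match(w, "random age slope", all = FALSE)
  expect_true(fit$re_structure %in% c("intercept", "ols"))
  expect_true(is.finite(fit$beta_age) && is.finite(fit$p_age))
})

test_that("bootstrap interval is seed-reproducible and degenerate without noise", {
  des <- simulate_design(40, seed = 13)
  y <- 2 + 0.5 * des$age
  fit <- suppressWarnings(fit_lmm(y, des, "linear"))
  ci <- suppressWarnings(ci_age(fit, n_boot = 30, seed = 14))
  expect_lt(diff(ci), 1e-5)
  expect_lt(abs(mean(ci) - 0.5), 1e-5)
  y2 <- simulate_trajectory_response(des, seed = 15)
  fit2 <- fit_lmm(y2, des, "linear")
  ci_a <- ci_age(fit2, n_boot = 25, seed = 16)
  ci_b <- ci_age(fit2, n_boot = 25, seed = 16)
  expect_identical(ci_a, ci_b)
  expect_gt(diff(ci_a), 0)
})

test_that("slope maps give identical estimates for identical regions and exact Bonferroni", {
  des <- simulate_design(50, seed = 17)
  y <- simulate_trajectory_response(des, seed = 18)
  Y <- cbind(y, y, y)
  coh <- as_cohort(des)
  sm <- fit_slope_map(coh, Y, standardize = FALSE)
  expect_equal(sm$beta_age, rep(sm$beta_age[1], 3), tolerance = 1e-5)
  expect_equal(sm$p_bonf, pmin(1, sm$p * 3))
})

test_that("gradient contrasts detect a planted posterior-anterior slope difference", {
  regions <- test_regions()
  sm <- data.frame(beta_age = -regions$y / 100 + stats::rnorm(nrow(regions), 0, 0.01))
  gc <- gradient_contrast(sm, regions, "PA")
  expect_lt(gc$p, 0.05)
  expect_gt(gc$mean_low, gc$mean_high)  # posterior (low y) develops faster here
  flat <- data.frame(beta_age = rep(0.3, nrow(regions)) + stats::rnorm(nrow(regions), 0, 1e-6))
  expect_gt(gradient_contrast(flat, regions, "IS")$p, 0.05)
  expect_error(gradient_contrast(sm, regions, "XY"))
  expect_no_error(gradient_contrast(sm, regions, "ML"))
})
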