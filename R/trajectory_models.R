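#' Fit a developmental mixed-effect trajectory model
#'
#' Fits `y ~ age + sex + tbv + centre + (1 + age | subject)` by maximum
#' likelihood (ML, so AIC is comparable across fixed-effect structures), with
#' optional quadratic age term (plus its random slope) or age-by-sex
#' interaction. Age is mean-centred internally for conditioning and total
#' brain volume standardised; the age slope is reported on the original
#' scale. Random-effect structure falls back from correlated (intercept +
#' slope) to uncorrelated to intercept-only on singular/non-converged fits,
#' and drops the random age slope with a warning when fewer than two subjects
#' have repeated scans.
#'
#' @param y numeric response, one value per scan.
#' @param cohort a `cohort` or a scan data.frame with columns `subject`,
#'   `age`, `sex`, `tbv`, `centre`.
#' @param model_kind `"linear"`, `"quadratic"` or `"interaction"`.
#' @param extra_covariates optional data.frame of additional per-scan fixed
#'   covariates (e.g. global network strength for edge-level models).
#' @return object of class `trajectory_fit`: list with `betas`, `beta_age`,
#'   `se_age`, `t_age`, `p_age`, `ci_age` (Wald 95%), `aic`, `loglik`,
#'   `model_kind`, `random_variances`, `residual_variance`, `re_structure`,
#'   and the underlying `fit`.
#' @export
fit_lmm <- function(y, cohort, model_kind = c("linear", "quadratic", "interaction"),
                    extra_covariates = NULL) {
  model_kind <- match.arg(model_kind)
  df <- if (inherits(cohort, "cohort")) cohort$scans else as.data.frame(cohort)
  stopifnot(length(y) == nrow(df))
  dat <- data.frame(y = y,
                    subject = factor(df$subject),
                    age_c = df$age - mean(df$age),
                    sex = factor(df$sex),
                    tbv_z = as.numeric(scale(df$tbv)),
                    centre = factor(df$centre))
  age_mean <- mean(df$age)
  fixed <- "y ~ age_c + tbv_z"
  if (nlevels(dat$sex) > 1) fixed <- paste(fixed, "+ sex")
  if (nlevels(dat$centre) > 1) fixed <- paste(fixed, "+ centre")
  if (model_kind == "quadratic") fixed <- paste(fixed, "+ I(age_c^2)")
  if (model_kind == "interaction" && nlevels(dat$sex) > 1) {
    fixed <- paste(fixed, "+ age_c:sex")
  }
  if (!is.null(extra_covariates)) {
    extra_covariates <- as.data.frame(extra_covariates)
    dat <- cbind(dat, extra_covariates)
    fixed <- paste(fixed, "+", paste(names(extra_covariates), collapse = " + "))
  }

  n_repeat <- sum(table(dat$subject) >= 2)
  slope_terms <- if (model_kind == "quadratic") "age_c + I(age_c^2)" else "age_c"
  re_options <- c(
    full = sprintf("(1 + %s | subject)", slope_terms),
    diagonal = sprintf("(1 + %s || subject)", slope_terms),
    intercept = "(1 | subject)"
  )
  if (n_repeat < 2) {
    warning("fewer than 2 subjects with repeated scans: dropping random age slope")
    re_options <- re_options["intercept"]
  }

  fit <- NULL; used <- NA_character_
  for (re in names(re_options)) {
    form <- stats::as.formula(paste(fixed, "+", re_options[[re]]))
    cand <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(form, data = dat, REML = FALSE,
                       control = lme4::lmerControl(
                         optimizer = "bobyqa",
                         optCtrl = list(maxfun = 2e5),
                         check.conv.singular = "ignore",
                         # only the variance parameters are free, so many
                         # shrunken effects with few scans per subject are fine
                         check.nobs.vs.nRE = "ignore"))
      )),
      error = function(e) NULL)
    if (is.null(cand)) next
    # boundary (singular) fits are valid ML optima and keep AIC comparisons on
    # a common random-effect structure; only true non-convergence degrades
    conv_ok <- length(cand@optinfo$conv$lme4$messages) == 0
    if (conv_ok) { fit <- cand; used <- re; break }
    if (is.null(fit)) { fit <- cand; used <- re }  # best-effort fallback
  }
  if (is.null(fit)) {
    # degenerate designs (e.g. one scan per subject) fall back to fixed effects
    warning("random effects unidentifiable: falling back to a fixed-effects fit")
    lmfit <- stats::lm(stats::as.formula(fixed), data = dat)
    co <- summary(lmfit)$coefficients
    co <- cbind(co[, 1:3], df = lmfit$df.residual, co[, 4, drop = FALSE])
    colnames(co) <- c("Estimate", "Std. Error", "t value", "df", "Pr(>|t|)")
    fe <- stats::coef(lmfit)
    V <- as.matrix(stats::vcov(lmfit))
    fit <- lmfit
    used <- "ols"
  } else {
    sm <- summary(fit)
    co <- sm$coefficients
    fe <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
  }

  if (model_kind == "quadratic") {
    # back-transform: beta_age(original) = beta_age_c - 2 * mean(age) * beta_age2
    b1 <- fe[["age_c"]]; b2 <- fe[["I(age_c^2)"]]
    i1 <- which(names(fe) == "age_c"); i2 <- which(names(fe) == "I(age_c^2)")
    beta_age <- b1 - 2 * age_mean * b2
    se_age <- sqrt(V[i1, i1] + 4 * age_mean^2 * V[i2, i2] - 4 * age_mean * V[i1, i2])
    t_age <- beta_age / se_age
    df_age <- co["age_c", "df"]
    p_age <- 2 * stats::pt(-abs(t_age), df_age)
  } else {
    beta_age <- fe[["age_c"]]
    se_age <- co["age_c", "Std. Error"]
    t_age <- co["age_c", "t value"]
    df_age <- co["age_c", "df"]
    p_age <- co["age_c", "Pr(>|t|)"]
  }
  tcrit <- stats::qt(0.975, df_age)
  if (used == "ols") {
    vc <- data.frame(grp = "Residual", var2 = NA,
                     vcov = summary(fit)$sigma^2)
  } else {
    vc <- as.data.frame(lme4::VarCorr(fit))
  }

  structure(list(
    betas = fe,
    beta_age = unname(beta_age),
    se_age = unname(se_age),
    t_age = unname(t_age),
    p_age = unname(p_age),
    df_age = unname(df_age),
    ci_age = unname(c(beta_age - tcrit * se_age, beta_age + tcrit * se_age)),
    aic = stats::AIC(fit),
    loglik = as.numeric(stats::logLik(fit)),
    model_kind = model_kind,
    random_variances = vc[vc$grp != "Residual" & is.na(vc$var2), "vcov"],
    residual_variance = vc[vc$grp == "Residual", "vcov"],
    re_structure = used,
    age_mean = age_mean,
    n_params = attr(stats::logLik(fit), "df"),
    fit = fit
  ), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit %s> beta_age = %.4g (t = %.2f, p = %.3g), AIC = %.2f\n",
              x$model_kind, x$beta_age, x$t_age, x$p_age, x$aic))
  invisible(x)
}

#' Select a trajectory model by AIC
#'
#' @param fits named list of `trajectory_fit` objects (e.g. linear and
#'   quadratic fits of the same response).
#' @return the name of the model with minimal AIC; exact ties go to the model
#'   with fewer parameters (the simpler model).
#' @export
aic_select <- function(fits) {
  aics <- vapply(fits, function(f) f$aic, 0)
  np <- vapply(fits, function(f) f$n_params, 0)
  best <- which(aics <= min(aics) + 1e-8)
  names(fits)[best[order(np[best])][1]]
}

#' Parametric-bootstrap confidence interval for the age slope
#'
#' Simulates responses from the fitted model, refits, and takes percentile
#' bounds of the age slope (original scale). Reproducible from `seed`.
#'
#' @param fit a `trajectory_fit`.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param level confidence level.
#' @return length-2 numeric interval, with attribute `draws`.
#' @export
ci_age <- function(fit, n_boot = 1000, seed = 1L, level = 0.95) {
  set.seed(seed)
  mer <- fit$fit
  sims <- stats::simulate(mer, nsim = n_boot)
  draws <- vapply(seq_len(n_boot), function(b) {
    rf <- tryCatch(suppressWarnings(suppressMessages(lme4::refit(mer, sims[[b]]))),
                   error = function(e) NULL)
    if (is.null(rf)) return(NA_real_)
    fe <- lme4::fixef(rf)
    if (fit$model_kind == "quadratic") {
      fe[["age_c"]] - 2 * fit$age_mean * fe[["I(age_c^2)"]]
    } else fe[["age_c"]]
  }, 0)
  a <- (1 - level) / 2
  out <- unname(stats::quantile(draws, c(a, 1 - a), na.rm = TRUE))
  attr(out, "draws") <- draws
  out
}

#' Per-region standardised developmental slope map
#'
#' Each region's metric is z-scored across all scans (so slopes are
#' standardised effect sizes), fitted with the linear trajectory model, and
#' p-values are Bonferroni-corrected across regions. After one full fit, the
#' remaining regions reuse the model structure via `lme4::refit` with a
#' normal approximation for the t statistic; with cohorts of hundreds of
#' scans this is indistinguishable from the Satterthwaite p of the full fit.
#'
#' @param cohort a `cohort`.
#' @param metric nodal metric name (`"n_eglob"`, `"n_eloc"`,
#'   `"degree_strength"`, `"betweenness"`) computed per scan, or a
#'   scans x regions numeric matrix of precomputed responses.
#' @param standardize z-score each region's response across scans.
#' @param alpha family-wise significance level after Bonferroni.
#' @return data.frame of class `slope_map`: `region`, `beta_age`, `se`, `t`,
#'   `p`, `p_bonf`, `significant`.
#' @export
fit_slope_map <- function(cohort, metric = "n_eglob", standardize = TRUE,
                          alpha = 0.05) {
  Y <- if (is.matrix(metric)) metric else nodal_metric_matrix(cohort, metric)
  R <- ncol(Y)
  if (standardize) Y <- scale(Y)
  Y[is.nan(Y)] <- 0  # constant-across-scans region: zero signal

  base_fit <- fit_lmm(Y[, 1], cohort, "linear")
  mer <- base_fit$fit
  est <- se <- numeric(R)
  est[1] <- base_fit$beta_age
  se[1] <- base_fit$se_age
  for (r in seq_len(R)[-1]) {
    rf <- tryCatch(suppressWarnings(suppressMessages(lme4::refit(mer, Y[, r]))),
                   error = function(e) NULL)
    if (is.null(rf)) {
      f <- fit_lmm(Y[, r], cohort, "linear")
      est[r] <- f$beta_age; se[r] <- f$se_age
      next
    }
    fe <- lme4::fixef(rf)
    V <- as.matrix(stats::vcov(rf))
    i <- which(names(fe) == "age_c")
    est[r] <- fe[[i]]
    se[r] <- sqrt(V[i, i])
  }
  t <- est / se
  p <- 2 * stats::pnorm(-abs(t))
  p_bonf <- pmin(1, p * R)
  out <- data.frame(region = seq_len(R), beta_age = est, se = se, t = t,
                    p = p, p_bonf = p_bonf, significant = p_bonf < alpha)
  class(out) <- c("slope_map", "data.frame")
  out
}

#' Per-scan nodal metric matrix
#' @param cohort a `cohort` with connectomes.
#' @param metric one of `"n_eglob"`, `"n_eloc"`, `"degree_strength"`,
#'   `"betweenness"`.
#' @return scans x regions numeric matrix.
#' @export
nodal_metric_matrix <- function(cohort, metric = "n_eglob") {
  metric <- match.arg(metric, c("n_eglob", "n_eloc", "degree_strength", "betweenness"))
  fun <- switch(metric,
                n_eglob = nodal_efficiency,
                n_eloc = nodal_local_efficiency,
                degree_strength = degree_strength,
                betweenness = betweenness_centrality)
  t(vapply(cohort$connectomes, function(cn) fun(cn),
           numeric(n_regions(cohort$connectomes[[1]]))))
}

#' Spatial-gradient contrast of a slope map
#'
#' Splits regions into two groups at the median centroid coordinate along the
#' posterior-anterior (y), inferior-superior (z) or medial-lateral axis
#' (absolute x, split within each hemisphere) and compares standardised
#' slopes with a two-sample t-test.
#'
#' @param slope_map a `slope_map`.
#' @param regions region table aligned with the slope map.
#' @param axis `"PA"`, `"IS"` or `"ML"`.
#' @return list with `t`, `p`, `df`, group means `mean_low`/`mean_high`
#'   (posterior/anterior, inferior/superior, or medial/lateral).
#' @export
gradient_contrast <- function(slope_map, regions, axis = c("PA", "IS", "ML")) {
  axis <- match.arg(axis)
  beta <- slope_map$beta_age
  if (axis == "ML") {
    lat <- abs(regions$x)
    high <- unlist(lapply(split(seq_len(nrow(regions)), regions$hemisphere),
                          function(ix) ix[lat[ix] > stats::median(lat[ix])]))
    grp <- seq_len(nrow(regions)) %in% high
  } else {
    coord <- if (axis == "PA") regions$y else regions$z
    grp <- coord > stats::median(coord)
  }
  if (min(table(grp)) < 3) stop("fewer than 3 regions per gradient group")
  tt <- stats::t.test(beta[grp], beta[!grp])
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_low = mean(beta[!grp]), mean_high = mean(beta[grp]), axis = axis)
}
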