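# Developmental trajectories: linear-vs-quadratic mixed models of the global
# metrics, Bonferroni-corrected standardised nodal slope maps, recovery of
# the planted slope field, spatial gradients, and edge-type trajectories with
# network strength as a covariate.

source("analysis/00_config.R")

inp <- study_inputs()
cohort <- inp$sim$cohort

# global metric trajectories (z-scored responses -> standardised slopes)
e_glob <- vapply(cohort$connectomes, global_efficiency, 0)
s_p <- vapply(cohort$connectomes, network_strength, 0)
glob <- list()
for (m in c("global_efficiency", "network_strength")) {
  y <- as.numeric(scale(if (m == "global_efficiency") e_glob else s_p))
  fl <- fit_lmm(y, cohort, "linear")
  fq <- suppressWarnings(fit_lmm(y, cohort, "quadratic"))
  pick <- aic_select(list(linear = fl, quadratic = fq))
  cat(sprintf("%s: beta_age %.3f (t %.1f, p %.2e), AIC picks %s\n",
              m, fl$beta_age, fl$t_age, fl$p_age, pick))
  glob[[m]] <- list(beta_age = fl$beta_age, t = fl$t_age, p = fl$p_age,
                    ci = fl$ci_age, aic_linear = fl$aic, aic_quadratic = fq$aic,
                    selected = pick)
}
jsonlite::write_json(glob, results_path("global_trajectories.json"),
                     auto_unbox = TRUE, digits = NA)

# nodal slope maps
sm_std <- fit_slope_map(cohort, "n_eglob")
utils::write.table(sm_std, results_path("slope_map_nodal_efficiency.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("nodal efficiency: %d/%d regions significant after Bonferroni\n",
            sum(sm_std$significant), nrow(sm_std)))

Y <- nodal_metric_matrix(cohort, "degree_strength")
sm_raw <- fit_slope_map(cohort, Y, standardize = FALSE)
cat(sprintf("planted-slope recovery (degree strength, raw scale): r = %.3f\n",
            cor(sm_raw$beta_age, inp$sim$truth$strength_slope)))

for (ax in c("PA", "IS", "ML")) {
  g <- gradient_contrast(sm_std, inp$regions, ax)
  cat(sprintf("gradient %s: t = %.2f, p = %.3g\n", ax, g$t, g$p))
}

# edge-type trajectories, controlling global network strength
cls <- classify_edges(group_average_network(cohort), inp$regions)
ets <- cohort_edge_type_strength(cohort, cls)
types <- grep("\\.", names(ets), value = TRUE)
rows <- lapply(types, function(tp) {
  y <- ets[[tp]]
  if (anyNA(y)) return(NULL)
  f <- fit_lmm(as.numeric(scale(y)), cohort,
               extra_covariates = data.frame(s_p = as.numeric(scale(s_p))))
  data.frame(type = tp, beta_age = f$beta_age, t = f$t_age, p = f$p_age)
})
edge_traj <- do.call(rbind, rows)
edge_traj$p_bonf <- pmin(1, edge_traj$p * nrow(edge_traj))
utils::write.table(edge_traj, results_path("edge_type_trajectories.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(edge_traj, digits = 3)
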