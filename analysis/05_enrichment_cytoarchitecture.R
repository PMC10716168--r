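# Cell-type enrichment of the selected genes (10,000 gene resamples),
# surrogate-aware category enrichment, and Spearman / partial-laminar
# correlations of the slope map with cortical maps.

source("analysis/00_config.R")

inp <- study_inputs()
cohort <- inp$sim$cohort
regions <- inp$regions
cortix <- which(regions$cortical)
distc <- as.matrix(stats::dist(as.matrix(regions[cortix, c("x", "y", "z")])))

sm <- fit_slope_map(cohort, "n_eglob")
al <- align_expression(sm, inp$expr$expression, regions)
gw <- bootstrap_gene_weights(al$X, al$y, n_boot = 500, seed = inp$seeds[8])
sel <- select_genes(gw)

ct <- cell_type_test(sel$positive, inp$ann$cell_annotation, al$gene_ids,
                     n_perm = 10000, seed = inp$seeds[6])
utils::write.table(ct, results_path("cell_type_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("planted class '%s': overlap %d, p = %.4g (smallest class p: %s)\n",
            inp$ann$enriched_class,
            ct$observed[ct$class == inp$ann$enriched_class],
            ct$p[ct$class == inp$ann$enriched_class],
            ct$class[which.min(ct$p)]))

ens <- make_surrogates(al$y, distc, n = 500, seed = inp$seeds[7])
w <- stats::setNames(gw$weight, gw$gene)
cat_res <- category_enrichment_sa(w, inp$ann$categories, al$X, al$y, ens)
utils::write.table(cat_res, results_path("category_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("categories with q < 0.05:",
    paste(cat_res$category[!is.na(cat_res$q) & cat_res$q < 0.05], collapse = ", "), "\n")

slope_c <- as.numeric(scale(sm$beta_age[cortix]))
ens_slope <- make_surrogates(slope_c, distc, n = 500, seed = inp$seeds[5])
tab <- do.call(rbind, lapply(colnames(inp$cmaps$maps), function(nm) {
  r <- spearman_sac(slope_c, inp$cmaps$maps[, nm], surrogates = ens_slope)
  data.frame(map = nm, rho = r$rho, p_sac = r$p_sac,
             planted = inp$cmaps$target_rhos[[nm]])
}))
utils::write.table(tab, results_path("cortical_map_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, digits = 3)

lam <- inp$cmaps$maps[, paste0("L", 1:6)]
part <- do.call(rbind, lapply(paste0("L", 1:6), function(tg) {
  p <- partial_laminar(slope_c, lam, tg, surrogates = ens_slope)
  data.frame(lamina = tg, partial_rho = p$rho, p_sac = p$p_sac)
}))
utils::write.table(part, results_path("laminar_partial_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(part, digits = 3)
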