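# Weighted graph metrics of the group-average network (75% prevalence
# threshold) and of every scan, plus small-world normalisation against 100
# degree-preserving matched random networks.

source("analysis/00_config.R")

inp <- study_inputs()
cohort <- inp$sim$cohort

group <- group_average_network(cohort, prevalence = 0.75)
print(group)

ens <- random_ensemble(group, n = 100, seed = inp$seeds[6])
gm <- global_metrics(group, ens)
cat(sprintf("group network: E_glob %.3f, E_loc %.3f, L_p %.4f, C_p %.3f\n",
            gm$e_glob, gm$e_loc, gm$l_p, gm$c_p))
cat(sprintf("small-world: gamma %.2f, lambda %.2f, sigma %.2f (sigma > 1)\n",
            gm$gamma, gm$lambda, gm$sigma))
jsonlite::write_json(gm, results_path("group_global_metrics.json"),
                     auto_unbox = TRUE, digits = NA)

utils::write.table(nodal_metrics(group), results_path("group_nodal_metrics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

per_scan <- do.call(rbind, lapply(seq_along(cohort$connectomes), function(k) {
  data.frame(cohort$scans[k, c("subject", "wave", "age")],
             global_metrics(cohort$connectomes[[k]]))
}))
utils::write.table(per_scan, results_path("scan_global_metrics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("wrote per-scan global metrics for %d scans\n", nrow(per_scan)))

cls <- classify_edges(group, inp$regions)
utils::write.table(cls, results_path("edge_classification.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("edge taxonomy:", sum(cls$hub_class == "rich-club"), "rich-club /",
    sum(cls$hub_class == "feeder"), "feeder /",
    sum(cls$hub_class == "local"), "local edges;",
    sum(attr(cls, "hubs")), "hub regions\n")
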