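# Generate the synthetic longitudinal study and record its ground truth:
# a 90-region bilateral parcellation, 150 subjects scanned in up to three
# yearly waves (ages 6-13), distance-dependent connectomes carrying a smooth
# planted slope field, coupled expression, cell-class annotations and
# cortical maps.

source("analysis/00_config.R")

inp <- study_inputs()

write_region_table(inp$regions, results_path("regions.tsv"))
write_expression(inp$expr$expression, results_path("expression.tsv"))
utils::write.table(inp$ann$cell_annotation, results_path("cell_annotation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_gmt(inp$ann$categories, results_path("categories.gmt"))
utils::write.table(data.frame(region_id = inp$cmaps$region_ids, inp$cmaps$maps,
                              check.names = FALSE),
                   results_path("cortical_maps.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(latent_field = inp$sim$truth$latent_field,
       strength_slope = inp$sim$truth$strength_slope,
       truncation_rate = inp$sim$truth$truncation_rate,
       true_gene_weights = inp$expr$truth$true_weights,
       enriched_class = inp$ann$enriched_class,
       planted_map_correlations = as.list(inp$cmaps$target_rhos)),
  results_path("ground_truth.json"), auto_unbox = TRUE, digits = NA)

scans <- inp$sim$cohort$scans
cat(sprintf("cohort: %d subjects, %d scans; ages %.1f-%.1f\n",
            length(unique(scans$subject)), nrow(scans),
            min(scans$age), max(scans$age)))
cat(sprintf("edge-weight truncation rate: %.2e (kept below 1%%)\n",
            inp$sim$truth$truncation_rate))
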