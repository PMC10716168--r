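# Shared study configuration for the analysis scripts. Every script
# re-creates the synthetic inputs deterministically from MASTER_SEED (a
# couple of seconds) instead of serialising hundreds of connectome matrices.

library(connectodev)

MASTER_SEED <- 20240915
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

study_inputs <- function() {
  set.seed(MASTER_SEED)
  seeds <- sample.int(2^31 - 2, 8)
  regions <- make_regions(90, seed = seeds[1])
  sim <- simulate_cohort(regions, n_subjects = 150, seed = seeds[2])
  expr <- simulate_expression(regions, sim$truth$latent_field, coupling_r = 0.5,
                              seed = seeds[3])
  ann <- simulate_annotations(expr$expression$gene_ids, expr$truth, seed = seeds[4])
  cmaps <- simulate_cortical_maps(regions, sim$truth$latent_field, seed = seeds[5])
  list(regions = regions, sim = sim, expr = expr, ann = ann, cmaps = cmaps,
       seeds = seeds)
}

results_path <- function(...) file.path(RESULTS_DIR, ...)
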