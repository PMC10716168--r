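#' Default pipeline configuration
#'
#' Every stochastic stage receives its own sub-seed derived from the master
#' seed and logged, so a full run is reproducible end to end.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @return named config list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "pipeline_out") {
  list(
    seed = seed,
    out_dir = out_dir,
    n_regions = 90,
    n_subjects = 120,
    n_nulls = 100,     # matched random networks for small-worldness
    n_surr = 500,      # SAC surrogates
    n_boot = 500,      # bootstrap replicates for gene weights
    n_perm = 2000,     # cell-type resamples
    n_genes = 500,
    n_true_genes = 50,
    coupling_r = 0.5,
    prevalence = 0.75,
    stages = c("simulate", "metrics", "slopes", "edges", "pls", "enrich", "cortical")
  )
}

stage_seeds <- function(master, stages) {
  set.seed(master)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

#' Run the full developmental-connectome analysis pipeline
#'
#' Simulates a synthetic input bundle (or consumes one), computes network
#' metrics, developmental slope maps and edge taxonomies, runs the
#' PLS-transcriptomic association with SAC permutation inference, cell-type
#' and category enrichment, and cytoarchitecture correlations. All outputs
#' are tab-delimited tables or JSON summaries under `config$out_dir`; the
#' resolved config (with sub-seeds) is serialised next to them.
#'
#' @param config list from [pipeline_config()] (or a YAML file path); missing
#'   entries are filled with defaults.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(cfg$seed, cfg$stages)
  cfg$stage_seeds <- as.list(seeds)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat(sprintf("run_pipeline: seed %d\n", cfg$seed), file = log_path)
  res <- list(config = cfg)

  run_stage <- function(name, body) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    logf("stage %s: seed %d", name, seeds[[name]])
    tryCatch(body(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    regions <- make_regions(cfg$n_regions, seed = seeds[["simulate"]])
    sim <- simulate_cohort(regions, n_subjects = cfg$n_subjects,
                           seed = seeds[["simulate"]])
    expr <- simulate_expression(regions, sim$truth$latent_field,
                                G = cfg$n_genes, n_true = cfg$n_true_genes,
                                coupling_r = cfg$coupling_r,
                                seed = seeds[["simulate"]] %% 100000L + 1L)
    ann <- simulate_annotations(expr$expression$gene_ids, expr$truth,
                                seed = seeds[["simulate"]] %% 100000L + 2L)
    cmaps <- simulate_cortical_maps(regions, sim$truth$latent_field,
                                    seed = seeds[["simulate"]] %% 100000L + 3L)
    write_region_table(regions, file.path(cfg$out_dir, "regions.tsv"))
    write_expression(expr$expression, file.path(cfg$out_dir, "expression.tsv"))
    write_tsv_full(ann$cell_annotation, file.path(cfg$out_dir, "cell_annotation.tsv"))
    write_gmt(ann$categories, file.path(cfg$out_dir, "categories.gmt"))
    write_tsv_full(data.frame(region_id = cmaps$region_ids, cmaps$maps,
                              check.names = FALSE),
                   file.path(cfg$out_dir, "cortical_maps.tsv"))
    jsonlite::write_json(
      list(latent_field = sim$truth$latent_field,
           strength_slope = sim$truth$strength_slope,
           truncation_rate = sim$truth$truncation_rate,
           true_gene_weights = expr$truth$true_weights,
           true_support = expr$truth$support,
           enriched_class = ann$enriched_class,
           planted_map_correlations = as.list(cmaps$target_rhos)),
      file.path(cfg$out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    res$regions <<- regions; res$sim <<- sim; res$expr <<- expr
    res$ann <<- ann; res$cmaps <<- cmaps
  })

  if (is.null(res$regions)) {
    stop("pipeline config: no inputs available; enable the 'simulate' stage")
  }
  regions <- res$regions
  cohort <- res$sim$cohort
  distmat_cortical <- as.matrix(stats::dist(
    as.matrix(regions[regions$cortical, c("x", "y", "z")])))

  run_stage("metrics", function() {
    group <- group_average_network(cohort, cfg$prevalence)
    ens <- random_ensemble(group, n = cfg$n_nulls, seed = seeds[["metrics"]])
    gm <- global_metrics(group, ens)
    jsonlite::write_json(gm, file.path(cfg$out_dir, "group_global_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    per_scan <- do.call(rbind, lapply(seq_along(cohort$connectomes), function(k) {
      g <- global_metrics(cohort$connectomes[[k]])
      data.frame(scan = k, cohort$scans[k, c("subject", "wave", "age")], g)
    }))
    write_tsv_full(per_scan, file.path(cfg$out_dir, "scan_global_metrics.tsv"))
    write_tsv_full(nodal_metrics(group), file.path(cfg$out_dir, "group_nodal_metrics.tsv"))
    res$group <<- group; res$scan_global <<- per_scan
  })

  run_stage("slopes", function() {
    gfit <- fit_lmm(res$scan_global$e_glob, cohort, "linear")
    jsonlite::write_json(
      list(metric = "global_efficiency", beta_age = gfit$beta_age,
           t = gfit$t_age, p = gfit$p_age, ci = gfit$ci_age, aic = gfit$aic),
      file.path(cfg$out_dir, "global_efficiency_trajectory.json"),
      auto_unbox = TRUE, digits = NA)
    smap <- fit_slope_map(cohort, "n_eglob")
    write_tsv_full(smap, file.path(cfg$out_dir, "slope_map.tsv"))
    res$slope_map <<- smap; res$global_fit <<- gfit
  })

  run_stage("edges", function() {
    cls <- classify_edges(res$group, regions)
    write_tsv_full(cls, file.path(cfg$out_dir, "edge_classification.tsv"))
    ets <- cohort_edge_type_strength(cohort, cls)
    write_tsv_full(ets, file.path(cfg$out_dir, "edge_type_strength.tsv"))
    res$edge_classes <<- cls
  })

  run_stage("pls", function() {
    al <- align_expression(res$slope_map, res$expr$expression, regions)
    ens <- make_surrogates(al$y, distmat_cortical, n = cfg$n_surr,
                           seed = seeds[["pls"]])
    pls <- pls_fit(al$X, al$y, n_components = min(15, nrow(al$X) - 1))
    test <- pls_sac_test(al$X, al$y, ens)
    gw <- bootstrap_gene_weights(al$X, al$y, n_boot = cfg$n_boot,
                                 seed = seeds[["pls"]] %% 100000L + 1L)
    jsonlite::write_json(
      list(r1 = test$r1, p_sac = test$p_sac,
           explained = pls$explained, r = pls$r,
           n_positive = sum(gw$selected == "positive"),
           n_negative = sum(gw$selected == "negative")),
      file.path(cfg$out_dir, "pls_summary.json"), auto_unbox = TRUE, digits = NA)
    write_tsv_full(gw, file.path(cfg$out_dir, "gene_weights.tsv"))
    res$align <<- al; res$pls <<- pls; res$pls_test <<- test
    res$gene_weights <<- gw; res$surrogates <<- ens
  })

  run_stage("enrich", function() {
    sel <- select_genes(res$gene_weights)
    ct <- cell_type_test(c(sel$positive, sel$negative), res$ann$cell_annotation,
                         res$align$gene_ids, n_perm = cfg$n_perm,
                         seed = seeds[["enrich"]])
    write_tsv_full(ct, file.path(cfg$out_dir, "cell_type_enrichment.tsv"))
    w <- stats::setNames(res$gene_weights$weight, res$gene_weights$gene)
    cat_res <- category_enrichment_sa(w, res$ann$categories, res$align$X,
                                      res$align$y, res$surrogates)
    write_tsv_full(cat_res, file.path(cfg$out_dir, "category_enrichment.tsv"))
    res$cell_types <<- ct; res$categories <<- cat_res
  })

  run_stage("cortical", function() {
    slope_c <- res$slope_map$beta_age[regions$cortical]
    tab <- cortical_map_correlations(slope_c, res$cmaps$maps, distmat_cortical,
                                     n_surr = cfg$n_surr, seed = seeds[["cortical"]])
    write_tsv_full(tab, file.path(cfg$out_dir, "cortical_map_correlations.tsv"))
    res$cortical <<- tab
  })

  logf("done")
  invisible(res)
}
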