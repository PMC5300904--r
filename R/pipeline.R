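# End-to-end orchestration on the bundled synthetic scenario: knockdown
# screen -> per-target DE -> specificity null -> phenotype correlation /
# clustering -> expression-matched GSEA -> cohort co-expression modules
# with annotation enrichment -> cis-pair scan -> disease-count DE.

#' Default pipeline configuration
#'
#' Collects every stage threshold at its analysis default (knockdown DE
#' gate 1e-3, module-annotation gate 1e-2, cis-candidate gate 1e-7,
#' disease adjusted-p gate 0.05, knockdown-efficiency gate 50%, major
#' module size > 100 genes, 10 expression-matched control sets) together
#' with scaled-down simulation sizes suitable for interactive runs.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return A nested list of stage parameters.
#' @export
default_pipeline_config <- function(seed = 1L) {
  seed <- check_count(seed, "seed", min = 0L)
  list(
    seed = seed,
    de_alpha = 1e-3,
    module_alpha = 1e-2,
    cis_p_threshold = 1e-7,
    disease_padj = 0.05,
    efficiency_gate = 50,
    major_module_size = 100L,
    n_control_sets = 10L,
    knockdown = list(n_genes = 4000L, n_targets = 4L, regulon_size = 150L,
                     effect = -1.5, noise_sd = 0.25, overlap = 0.5),
    cohort = list(n_genes = 1200L, n_samples = 64L,
                  module_sizes = c(150L, 120L, 120L, 110L),
                  noise_sd = 1, n_cis_pairs = 20L, cis_weight = 0.9),
    counts = list(n_genes = 2000L, n_control = 50L, n_case = 15L,
                  n_de = 100L, de_log2fc = 2)
  )
}

build_knockdown_scenario <- function(cfg) {
  kd <- cfg$knockdown
  regulons <- lapply(seq_len(kd$n_targets), function(i)
    ((i - 1) * kd$regulon_size + 1):(i * kd$regulon_size))
  # mixed-sign effects: knockdowns both up- and downregulate their regulon
  targets <- lapply(seq_len(kd$n_targets), function(i)
    list(name = sprintf("t%d", i), n_amirnas = 2L, regulon = regulons[[i]],
         effect = rep_len(c(kd$effect, -kd$effect), kd$regulon_size)))
  # plant a shared program between targets 1 and 2 (lncRNA/TF pair)
  shared <- if (kd$n_targets >= 2L)
    list(list(a = "t1", b = "t2", overlap = kd$overlap)) else list()
  knockdown_sim_config(
    n_genes = kd$n_genes, targets = targets, n_controls = 5L,
    replicates_per_amirna = 3L, noise_sd = kd$noise_sd,
    shared_regulon_pairs = shared, seed = cfg$seed)
}

#' Run the full synthetic-scenario analysis pipeline
#'
#' Simulates a knockdown screen, an islet co-expression cohort, and a
#' disease count cohort from one master seed, then runs every analysis
#' stage in dependency order and returns a structured report. Identical
#' configuration gives an identical report.
#'
#' @param config Configuration list from [default_pipeline_config()]
#'   (possibly modified).
#' @param out_dir Optional directory; when given, the resolved
#'   configuration, the JSON report, and a human-readable summary are
#'   written there.
#' @return A list of per-stage results: `knockdown` (DE tables,
#'   specificity results), `phenotype` (correlations, clustering),
#'   `enrichment` (GSEA against the planted regulon set and matched
#'   control sets), `coexpression` (modules, eigengenes, annotation
#'   enrichment), `cis` (cis-pair scan), `disease` (size factors, NB DE),
#'   and `summary` (headline numbers).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ## Stage 1: knockdown screen DE + specificity null
  kd_cfg <- build_knockdown_scenario(config)
  sim <- simulate_knockdown_experiment(kd_cfg)
  control_samples <- unlist(sim$design$controls, use.names = FALSE)
  de_tables <- lapply(names(sim$design$targets), function(tn) {
    anova_de(sim$expr,
             unlist(sim$design$targets[[tn]], use.names = FALSE),
             control_samples, alpha = config$de_alpha)
  })
  names(de_tables) <- names(sim$design$targets)
  spec <- lapply(names(sim$design$targets), function(tn)
    specificity_null(sim$expr, sim$design, tn, alpha = config$de_alpha))
  names(spec) <- names(sim$design$targets)

  ## Stage 2: phenotype similarity
  fc <- build_foldchange_matrix(de_tables, alpha = config$de_alpha)
  phen_cor <- pairwise_phenotype_correlation(fc)
  tree <- cluster_contrasts(fc)

  ## Stage 3: enrichment of the first knockdown against its planted
  ## downregulated genes, with expression-matched control sets
  eff_t1 <- sim$truth$effects$t1
  target_set <- names(eff_t1)[eff_t1 < 0]
  mean_expr <- rowMeans(sim$expr[, control_samples, drop = FALSE])
  ranked <- de_tables$t1
  controls <- expression_matched_control_sets(
    target_set, mean_expr, n_sets = config$n_control_sets,
    seed = config$seed + 1L)
  gsea_target <- gsea_permutation_p(ranked$gene, ranked$log2fc, target_set,
                                    n_perm = 1000L, seed = config$seed + 2L)
  gsea_controls <- lapply(seq_along(controls), function(i)
    gsea_permutation_p(ranked$gene, ranked$log2fc, controls[[i]],
                       n_perm = 200L, seed = config$seed + 2L + i))

  ## Stage 4: cohort co-expression modules
  co <- config$cohort
  n_mod_genes <- sum(co$module_sizes)
  cis_pairs <- lapply(seq_len(co$n_cis_pairs), function(i)
    list(lnc = n_mod_genes + 2L * i - 1L, coding = n_mod_genes + 2L * i,
         weight = co$cis_weight))
  cohort_cfg <- cohort_sim_config(
    n_genes = co$n_genes, n_samples = co$n_samples,
    module_sizes = co$module_sizes, noise_sd = co$noise_sd,
    lncrna_fraction = 0.2, tf_per_module = 5L, cis_pairs = cis_pairs,
    seed = config$seed + 10L)
  cohort <- simulate_islet_cohort(cohort_cfg)
  sft <- pick_soft_threshold(cohort$expr)
  adj <- adjacency_matrix(stats::cor(t(cohort$expr)), sft$power)
  tom <- topological_overlap(adj)
  modules <- detect_modules(tom, min_module_size = 30L)
  module_ids <- setdiff(unique(modules), "unassigned")
  eigengenes <- lapply(module_ids, function(m)
    module_eigengene(cohort$expr, names(modules)[modules == m]))
  names(eigengenes) <- module_ids
  label_sets <- split(cohort$annotation$gene_id, cohort$annotation$biotype)
  mod_enrich <- module_annotation_enrichment(modules, label_sets,
                                             alpha = config$module_alpha)
  major <- names(which(table(modules[modules != "unassigned"]) >
                         config$major_module_size))

  ## Stage 5: cis-regulatory scan on the cohort
  cis <- cis_pair_scan(cohort$expr, cohort$annotation,
                       p_threshold = config$cis_p_threshold)

  ## Stage 6: disease-count DE
  ct <- config$counts
  count_cfg <- count_sim_config(
    n_genes = ct$n_genes, n_control = ct$n_control, n_case = ct$n_case,
    de_genes = seq_len(ct$n_de), de_log2fc = ct$de_log2fc,
    seed = config$seed + 20L)
  cc <- simulate_count_cohort(count_cfg)
  sf <- size_factors(cc$counts)
  disease_de <- nb_wald_de(cc$counts, cc$conditions, sf,
                           alpha = config$disease_padj)

  summary <- list(
    n_control_partitions = length(spec[[1]]$control_counts),
    median_control_de = stats::median(spec[[1]]$control_counts),
    specificity_p = vapply(spec, `[[`, numeric(1), "mw_p"),
    phenotype_r_t1_t2 = phen_cor$r["t1", "t2"],
    gsea_target_p = gsea_target$p,
    n_modules = length(module_ids),
    n_major_modules = length(major),
    n_cis_candidates = sum(cis$candidate),
    n_disease_significant = sum(disease_de$significant, na.rm = TRUE))

  report <- list(
    config = config,
    knockdown = list(de = de_tables, specificity = spec,
                     truth = sim$truth),
    phenotype = list(correlation = phen_cor, tree = tree),
    enrichment = list(target = gsea_target,
                      controls = gsea_controls),
    coexpression = list(power = sft$power, modules = modules,
                        eigengenes = eigengenes,
                        enrichment = mod_enrich, major_modules = major,
                        truth = cohort$truth),
    cis = cis,
    disease = list(size_factors = sf, de = disease_de,
                   truth = cc$truth),
    summary = summary)

  if (!is.null(out_dir)) {
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(c(
      "isletlncnet pipeline summary",
      sprintf("seed: %d", config$seed),
      sprintf("control 2-vs-3 partitions: %d", summary$n_control_partitions),
      sprintf("median control-split DE genes: %g", summary$median_control_de),
      sprintf("specificity Mann-Whitney p: %s",
              paste(signif(summary$specificity_p, 3), collapse = ", ")),
      sprintf("modules detected: %d (major > %d genes: %d)",
              summary$n_modules, config$major_module_size,
              summary$n_major_modules),
      sprintf("cis candidates at p < %g: %d", config$cis_p_threshold,
              summary$n_cis_candidates),
      sprintf("disease DE genes at padj < %g: %d", config$disease_padj,
              summary$n_disease_significant)),
      file.path(out_dir, "summary.txt"))
  }
  report
}
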