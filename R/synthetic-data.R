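# Synthetic-data generators: every input the analysis consumes can be
# simulated with known ground truth, so recovery of planted structure
# (regulons, co-expression modules, cis pairs, DE genes) is assertable.

#' Configuration for a simulated amiRNA knockdown screen
#'
#' Describes an array-style knockdown experiment in a beta-cell line:
#' a set of targets (lncRNAs or transcription factors), each silenced by
#' one or two independent artificial microRNAs (amiRNAs), alongside a
#' panel of non-targeting control amiRNAs. Expression is modelled on the
#' log2 scale as gene baseline + planted knockdown effect + Gaussian noise.
#'
#' @param n_genes Number of genes on the array.
#' @param targets List of target descriptors. Each descriptor is a list with
#'   elements `name`, `n_amirnas` (1 or 2), `regulon` (integer gene indices
#'   deregulated by the knockdown), `effect` (log2 fold change applied to
#'   regulon genes; scalar or one value per regulon gene), and optionally
#'   `self_index`/`self_effect` for the target's own transcript (default
#'   effect -1.5 log2, i.e. > 50% knockdown).
#' @param n_controls Number of non-targeting control amiRNA groups
#'   (default 5, the screen's control panel size).
#' @param replicates_per_amirna Replicate transductions per amiRNA.
#' @param noise_sd Replicate noise SD in log2 units (>= 0).
#' @param baseline_mean,baseline_sd Mean and SD of per-gene baseline
#'   log2 expression.
#' @param shared_regulon_pairs Optional list of lists with elements
#'   `a`, `b` (target names) and `overlap` in \[0, 1\]: a fraction of
#'   target `b`'s regulon is replaced by genes from target `a`'s regulon,
#'   planting a shared transcriptional program.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `knockdown_sim_config` list, validated.
#' @export
knockdown_sim_config <- function(n_genes, targets, n_controls = 5L,
                                 replicates_per_amirna = 3L,
                                 noise_sd = 0.25,
                                 baseline_mean = 8, baseline_sd = 1.5,
                                 shared_regulon_pairs = list(),
                                 seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_controls <- check_count(n_controls, "n_controls", min = 2L)
  replicates_per_amirna <- check_count(replicates_per_amirna,
                                       "replicates_per_amirna")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  baseline_sd <- check_number(baseline_sd, "baseline_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.list(targets) || length(targets) == 0L)
    stopf("`targets` must be a non-empty list of target descriptors")
  nm <- vapply(targets, function(t) as.character(t$name), character(1))
  if (anyDuplicated(nm)) stopf("duplicated target names")
  targets <- lapply(targets, function(t) {
    t$n_amirnas <- check_count(t$n_amirnas %||% 2L, "n_amirnas")
    if (!t$n_amirnas %in% 1:2) stopf("n_amirnas must be 1 or 2")
    t$regulon <- as.integer(t$regulon)
    if (length(t$regulon) && (min(t$regulon) < 1L || max(t$regulon) > n_genes))
      stopf("regulon indices of target '%s' out of range [1, %d]",
            t$name, n_genes)
    t$effect <- as.numeric(t$effect %||% -1.5)
    if (!length(t$effect) %in% c(1L, length(t$regulon)))
      stopf("effect of target '%s' must be scalar or per-regulon-gene", t$name)
    if (!is.null(t$self_index)) {
      t$self_index <- check_count(t$self_index, "self_index")
      if (t$self_index > n_genes) stopf("self_index out of range")
      t$self_effect <- check_number(t$self_effect %||% -1.5, "self_effect",
                                    max = -1, strict_max = FALSE)
    }
    t
  })
  names(targets) <- nm
  for (p in shared_regulon_pairs) {
    if (!all(c(p$a, p$b) %in% nm))
      stopf("shared_regulon_pairs refers to unknown targets")
    check_number(p$overlap, "overlap", min = 0, max = 1)
  }
  structure(list(n_genes = n_genes, targets = targets,
                 n_controls = n_controls,
                 replicates_per_amirna = replicates_per_amirna,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 shared_regulon_pairs = shared_regulon_pairs, seed = seed),
            class = "knockdown_sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plant shared regulons: replace the leading fraction of b's regulon with
# the leading genes of a's regulon (deterministic, so overlap is exact).
# Shared genes inherit the donor's per-gene effects, so both knockdowns
# move them in the same direction — the co-regulation the structure models.
apply_shared_regulons <- function(targets, pairs) {
  for (p in pairs) {
    ta <- targets[[p$a]]; tb <- targets[[p$b]]
    ra <- ta$regulon; rb <- tb$regulon
    ea <- rep_len(ta$effect, length(ra))
    eb <- rep_len(tb$effect, length(rb))
    n_shared <- round(p$overlap * length(rb))
    if (n_shared > length(ra))
      stopf("overlap between '%s' and '%s' exceeds donor regulon size",
            p$a, p$b)
    own <- which(!(rb %in% ra))
    n_keep <- min(length(own), length(rb) - n_shared)
    tb$regulon <- c(ra[seq_len(n_shared)], rb[own][seq_len(n_keep)])
    tb$effect <- c(ea[seq_len(n_shared)], eb[own][seq_len(n_keep)])
    targets[[p$b]] <- tb
  }
  targets
}

#' Simulate an amiRNA knockdown expression screen
#'
#' Generates a log2 expression matrix with planted knockdown regulons, the
#' corresponding knockdown design (which samples carry which amiRNA, which
#' are non-targeting controls), and the ground truth needed to score
#' downstream recovery.
#'
#' @param config A [knockdown_sim_config()].
#' @return A list with `expr` (genes x samples log2 matrix), `design`
#'   (list with `targets`: target -> list of amiRNA sample-id groups, and
#'   `controls`: list of control sample-id groups), and `truth` (per-target
#'   regulon gene ids and effects, per-gene baselines).
#' @export
simulate_knockdown_experiment <- function(config) {
  if (!inherits(config, "knockdown_sim_config"))
    stopf("`config` must come from knockdown_sim_config()")
  if (config$n_controls < 2L) stopf("need >= 2 control groups")
  targets <- apply_shared_regulons(config$targets, config$shared_regulon_pairs)
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  reps <- config$replicates_per_amirna

  control_groups <- lapply(seq_len(config$n_controls), function(i)
    sprintf("ctl%d_r%d", i, seq_len(reps)))
  names(control_groups) <- sprintf("ctl%d", seq_len(config$n_controls))
  target_groups <- lapply(targets, function(t) {
    g <- lapply(seq_len(t$n_amirnas), function(a)
      sprintf("%s_ami%d_r%d", t$name, a, seq_len(reps)))
    names(g) <- sprintf("%s_ami%d", t$name, seq_len(t$n_amirnas))
    g
  })

  sample_ids <- c(unlist(control_groups, use.names = FALSE),
                  unlist(lapply(target_groups, unlist), use.names = FALSE))
  set.seed(config$seed)
  baseline <- stats::rnorm(config$n_genes, config$baseline_mean,
                           config$baseline_sd)
  expr <- matrix(baseline, nrow = config$n_genes, ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (tn in names(targets)) {
    t <- targets[[tn]]
    cols <- unlist(target_groups[[tn]], use.names = FALSE)
    if (length(t$regulon))
      expr[t$regulon, cols] <- expr[t$regulon, cols] + t$effect
    if (!is.null(t$self_index))
      expr[t$self_index, cols] <- expr[t$self_index, cols] + t$self_effect
  }
  if (config$noise_sd > 0)
    expr <- expr + matrix(stats::rnorm(length(expr), 0, config$noise_sd),
                          nrow = nrow(expr))

  truth <- list(
    regulons = lapply(targets, function(t) gene_ids[t$regulon]),
    effects = lapply(targets, function(t)
      stats::setNames(rep_len(t$effect, length(t$regulon)),
                      gene_ids[t$regulon])),
    baseline = stats::setNames(baseline, gene_ids))
  list(expr = expr,
       design = list(targets = target_groups, controls = control_groups),
       truth = truth)
}

#' Configuration for a simulated islet expression cohort
#'
#' Latent-factor model of co-expression across a panel of islet donor
#' samples: each module m has a factor f_m per sample and member genes
#' follow x = lambda * f_m + noise. Genes outside modules are pure noise.
#' Declared cis pairs (an lncRNA and a protein-coding neighbour) instead
#' share a pair-specific factor u with x = sqrt(w) u + sqrt(1 - w) noise,
#' so their expected correlation equals the declared weight w, and the
#' gene annotation places the two records as immediate genomic neighbours.
#'
#' @param n_genes Total genes.
#' @param n_samples Cohort size (default 64 donors).
#' @param module_sizes Integer vector of planted module sizes
#'   (sum + cis-pair genes must be <= n_genes).
#' @param loading_mean,loading_sd Distribution of per-gene factor loadings
#'   (absolute value of a normal draw).
#' @param noise_sd Residual SD around the factor signal.
#' @param lncrna_fraction Fraction of each module's genes labelled lncRNA
#'   (recycled over modules).
#' @param tf_per_module Number of genes per module labelled TF (recycled).
#' @param cis_pairs List of lists with `lnc`, `coding` (gene indices not in
#'   any module) and `weight` in \[0, 1\].
#' @param gene_spacing,cis_gap,gene_length Base-pair layout of the synthetic
#'   chromosome; cis-pair partners sit `cis_gap` apart (< `gene_spacing`)
#'   so each pair is mutually nearest.
#' @param chrom Chromosome name for all records.
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_genes, n_samples = 64L, module_sizes,
                              loading_mean = 1, loading_sd = 0.2,
                              noise_sd = 1, lncrna_fraction = 0.15,
                              tf_per_module = 0L, cis_pairs = list(),
                              gene_spacing = 10000L, cis_gap = 500L,
                              gene_length = 1000L, chrom = "chrS",
                              seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_samples <- check_count(n_samples, "n_samples", min = 3L)
  module_sizes <- vapply(module_sizes, check_count, integer(1),
                         name = "module_sizes", min = 2L)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  if (sum(module_sizes) > n_genes)
    stopf("module sizes sum (%d) exceeds n_genes (%d)",
          sum(module_sizes), n_genes)
  in_module <- sum(module_sizes)
  for (p in cis_pairs) {
    check_number(p$weight, "weight", min = 0, max = 1)
    idx <- c(p$lnc, p$coding)
    if (any(idx < 1L | idx > n_genes)) stopf("cis-pair index out of range")
    if (any(idx <= in_module))
      stopf("cis-pair genes must lie outside planted modules")
  }
  cis_idx <- unlist(lapply(cis_pairs, function(p) c(p$lnc, p$coding)))
  if (anyDuplicated(cis_idx)) stopf("cis-pair gene indices must be distinct")
  if (cis_gap >= gene_spacing - gene_length)
    stopf("cis_gap must be smaller than the inter-gene gap")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 module_sizes = module_sizes, loading_mean = loading_mean,
                 loading_sd = loading_sd, noise_sd = noise_sd,
                 lncrna_fraction = lncrna_fraction,
                 tf_per_module = tf_per_module, cis_pairs = cis_pairs,
                 gene_spacing = as.integer(gene_spacing),
                 cis_gap = as.integer(cis_gap),
                 gene_length = as.integer(gene_length),
                 chrom = chrom, seed = seed),
            class = "cohort_sim_config")
}

#' Simulate an islet donor expression cohort with planted modules
#'
#' @param config A [cohort_sim_config()].
#' @return A list with `expr` (genes x samples matrix), `annotation`
#'   (a gene annotation data frame: chrom, start, end, strand, gene_id,
#'   biotype), and `truth` (module membership, latent factors, loadings,
#'   cis-pair table).
#' @export
simulate_islet_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config"))
    stopf("`config` must come from cohort_sim_config()")
  n_g <- config$n_genes; n_s <- config$n_samples
  sizes <- config$module_sizes
  n_mod <- length(sizes)
  gene_ids <- sprintf("g%05d", seq_len(n_g))
  sample_ids <- sprintf("islet%02d", seq_len(n_s))

  membership <- integer(n_g)  # 0 = unassigned
  membership[seq_len(sum(sizes))] <- rep(seq_len(n_mod), times = sizes)

  set.seed(config$seed)
  factors <- matrix(stats::rnorm(n_mod * n_s), nrow = n_mod,
                    dimnames = list(sprintf("M%d", seq_len(n_mod)),
                                    sample_ids))
  loadings <- abs(stats::rnorm(n_g, config$loading_mean, config$loading_sd))
  expr <- matrix(stats::rnorm(n_g * n_s, 0, config$noise_sd), nrow = n_g,
                 dimnames = list(gene_ids, sample_ids))
  for (m in seq_len(n_mod)) {
    rows <- which(membership == m)
    expr[rows, ] <- expr[rows, ] + loadings[rows] %o% factors[m, ]
  }
  for (p in config$cis_pairs) {
    u <- stats::rnorm(n_s)
    for (i in c(p$lnc, p$coding))
      expr[i, ] <- sqrt(p$weight) * u +
        sqrt(1 - p$weight) * stats::rnorm(n_s)
  }

  # Biotype labels: per module the leading genes are lncRNA, then TF,
  # remainder coding; cis-pair lnc members are lncRNA.
  biotype <- rep("coding", n_g)
  lnc_frac <- rep_len(config$lncrna_fraction, n_mod)
  tf_n <- rep_len(config$tf_per_module, n_mod)
  for (m in seq_len(n_mod)) {
    rows <- which(membership == m)
    n_lnc <- round(lnc_frac[m] * length(rows))
    if (n_lnc > 0) biotype[rows[seq_len(n_lnc)]] <- "lncRNA"
    if (tf_n[m] > 0)
      biotype[rows[n_lnc + seq_len(min(tf_n[m], length(rows) - n_lnc))]] <- "TF"
  }
  for (p in config$cis_pairs) biotype[p$lnc] <- "lncRNA"

  # Genomic layout: genes in index order along one synthetic chromosome,
  # each cis coding partner re-inserted immediately 3' of its lncRNA with
  # a reduced gap so the pair are mutual nearest neighbours.
  order_idx <- seq_len(n_g)
  for (p in config$cis_pairs) {
    order_idx <- order_idx[order_idx != p$coding]
    pos <- match(p$lnc, order_idx)
    order_idx <- append(order_idx, p$coding, after = pos)
  }
  after_pair <- vapply(config$cis_pairs, function(p) p$lnc, integer(1))
  start <- integer(n_g); pos <- 0L
  for (k in seq_len(n_g)) {
    i <- order_idx[k]
    start[i] <- pos
    gap <- if (i %in% after_pair) config$cis_gap
           else config$gene_spacing - config$gene_length
    pos <- pos + config$gene_length + gap
  }
  annotation <- data.frame(chrom = config$chrom, start = start,
                           end = start + config$gene_length, strand = "+",
                           gene_id = gene_ids, biotype = biotype,
                           stringsAsFactors = FALSE)
  annotation <- annotation[order(annotation$start), , drop = FALSE]
  rownames(annotation) <- NULL

  cis_tab <- if (length(config$cis_pairs)) {
    data.frame(
      lnc = gene_ids[vapply(config$cis_pairs, `[[`, integer(1), "lnc")],
      coding = gene_ids[vapply(config$cis_pairs, `[[`, integer(1), "coding")],
      weight = vapply(config$cis_pairs, `[[`, numeric(1), "weight"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(lnc = character(), coding = character(), weight = numeric())
  }
  truth <- list(membership = stats::setNames(membership, gene_ids),
                factors = factors,
                loadings = stats::setNames(loadings, gene_ids),
                cis_pairs = cis_tab)
  list(expr = expr, annotation = annotation, truth = truth)
}

#' Configuration for a simulated disease count cohort
#'
#' Negative-binomial RNA-seq counts for a control-versus-disease islet
#' cohort (default 50 controls vs 15 cases, the impaired-glucose-tolerance
#' design): counts_gj ~ NB(mean = depth_j * mu_g * 2^(lfc_g * case_j),
#' dispersion alpha_g).
#'
#' @param n_genes Number of genes.
#' @param n_control,n_case Samples per condition.
#' @param mu_meanlog,mu_sdlog Log-normal parameters for baseline means.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters for
#'   per-gene NB dispersions (sdlog = 0 gives a fixed dispersion).
#' @param depth_factors Optional per-sample sequencing-depth multipliers
#'   (positive; default 1 for all samples).
#' @param de_genes Integer indices of differentially expressed genes.
#' @param de_log2fc Planted log2 fold changes (recycled over `de_genes`).
#' @param seed Integer seed.
#' @return A `count_sim_config` list.
#' @export
count_sim_config <- function(n_genes, n_control = 50L, n_case = 15L,
                             mu_meanlog = log(100), mu_sdlog = 1,
                             dispersion_meanlog = log(0.05),
                             dispersion_sdlog = 0.3,
                             depth_factors = NULL,
                             de_genes = integer(), de_log2fc = 2,
                             seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  n_control <- check_count(n_control, "n_control", min = 2L)
  n_case <- check_count(n_case, "n_case", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  n_samples <- n_control + n_case
  if (is.null(depth_factors)) depth_factors <- rep(1, n_samples)
  if (length(depth_factors) != n_samples || any(depth_factors <= 0))
    stopf("`depth_factors` must be %d positive values", n_samples)
  de_genes <- as.integer(de_genes)
  if (length(de_genes) && (min(de_genes) < 1L || max(de_genes) > n_genes))
    stopf("de_genes indices out of range")
  structure(list(n_genes = n_genes, n_control = n_control, n_case = n_case,
                 mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
                 dispersion_meanlog = dispersion_meanlog,
                 dispersion_sdlog = dispersion_sdlog,
                 depth_factors = as.numeric(depth_factors),
                 de_genes = de_genes,
                 de_log2fc = rep_len(as.numeric(de_log2fc),
                                     max(1L, length(de_genes))),
                 seed = seed),
            class = "count_sim_config")
}

#' Simulate a negative-binomial disease count cohort
#'
#' @param config A [count_sim_config()].
#' @return A list with `counts` (genes x samples integer matrix),
#'   `conditions` (factor with levels control/case), and `truth`
#'   (baseline means, dispersions, depth factors, DE gene ids and
#'   planted log2 fold changes).
#' @export
simulate_count_cohort <- function(config) {
  if (!inherits(config, "count_sim_config"))
    stopf("`config` must come from count_sim_config()")
  n_g <- config$n_genes
  n_s <- config$n_control + config$n_case
  gene_ids <- sprintf("g%05d", seq_len(n_g))
  sample_ids <- c(sprintf("ctl%02d", seq_len(config$n_control)),
                  sprintf("case%02d", seq_len(config$n_case)))
  case <- rep(c(0, 1), c(config$n_control, config$n_case))

  set.seed(config$seed)
  mu <- stats::rlnorm(n_g, config$mu_meanlog, config$mu_sdlog)
  alpha <- stats::rlnorm(n_g, config$dispersion_meanlog,
                         config$dispersion_sdlog)
  if (any(alpha <= 0)) stopf("non-positive dispersion")
  lfc <- numeric(n_g)
  if (length(config$de_genes)) lfc[config$de_genes] <- config$de_log2fc
  mean_mat <- outer(mu, config$depth_factors) *
    2 ^ (lfc %o% case)
  counts <- matrix(stats::rnbinom(n_g * n_s, mu = mean_mat,
                                  size = rep(1 / alpha, n_s)),
                   nrow = n_g, dimnames = list(gene_ids, sample_ids))
  truth <- list(mu = stats::setNames(mu, gene_ids),
                dispersion = stats::setNames(alpha, gene_ids),
                depth_factors = stats::setNames(config$depth_factors,
                                                sample_ids),
                de_genes = gene_ids[config$de_genes],
                log2fc = stats::setNames(lfc, gene_ids))
  list(counts = counts,
       conditions = factor(ifelse(case == 1, "case", "control"),
                           levels = c("control", "case")),
       truth = truth)
}
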