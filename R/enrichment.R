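# Gene-set enrichment of knockdown phenotypes: islet-enriched gene
# definition, expression-matched control sets, a weighted
# Kolmogorov-Smirnov (GSEA-style) running-sum statistic with a gene-set
# permutation null, and the hypergeometric test used to annotate
# co-expression modules.

#' Define islet-enriched genes against a tissue panel
#'
#' A gene is islet-enriched when its islet expression exceeds the panel
#' mean by more than two sample standard deviations across tissues
#' (strict inequality).
#'
#' @param focal_expr Named per-gene expression in the focal tissue.
#' @param panel Genes x tissues expression matrix (>= 2 tissues), same
#'   gene universe as `focal_expr`.
#' @param n_sd SD multiplier (default 2).
#' @return Character vector of enriched gene ids.
#' @export
islet_enriched_genes <- function(focal_expr, panel, n_sd = 2) {
  if (!is.matrix(panel) || ncol(panel) < 2L)
    stopf("`panel` must be a genes x tissues matrix with >= 2 tissues")
  if (is.null(names(focal_expr)) || is.null(rownames(panel)) ||
      !identical(sort(names(focal_expr)), sort(rownames(panel))))
    stopf("`focal_expr` and `panel` must share the same gene universe")
  panel <- panel[names(focal_expr), , drop = FALSE]
  mu <- rowMeans(panel)
  sdv <- apply(panel, 1, stats::sd)
  names(focal_expr)[focal_expr > mu + n_sd * sdv]
}

#' Expression-matched control gene sets
#'
#' Samples control sets that reproduce the target set's distribution of
#' mean expression: genes are binned into quantile bins of mean
#' expression and each control set draws (without replacement, excluding
#' target-set genes) the target set's per-bin counts. Within a bin each
#' target gene is matched by one of its `k_nearest` closest non-target
#' genes by expression, so set means track the target mean tightly even
#' in wide tail bins. When a bin lacks enough non-target genes the
#' shortfall is drawn from the nearest neighbouring bins, with a
#' message.
#'
#' @param target_set Character vector of target gene ids.
#' @param mean_expr Named per-gene mean expression over the universe.
#' @param n_sets Number of control sets (default 10).
#' @param n_bins Number of quantile bins (default 10, deciles).
#' @param k_nearest Per-target-gene candidate pool of expression-nearest
#'   non-target genes within the bin (default 10).
#' @param seed Integer seed.
#' @return List of `n_sets` character vectors, each of length
#'   `length(target_set)`, disjoint from the target set.
#' @export
expression_matched_control_sets <- function(target_set, mean_expr,
                                            n_sets = 10L, n_bins = 10L,
                                            k_nearest = 10L, seed = 1L) {
  n_sets <- check_count(n_sets, "n_sets")
  n_bins <- check_count(n_bins, "n_bins")
  k_nearest <- check_count(k_nearest, "k_nearest")
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(names(mean_expr))) stopf("`mean_expr` must be named by gene")
  target_set <- unique(as.character(target_set))
  if (!all(target_set %in% names(mean_expr)))
    stopf("target set contains genes outside the universe")
  brk <- unique(stats::quantile(mean_expr, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mean_expr, breaks = brk, include.lowest = TRUE, labels = FALSE)
  names(bin) <- names(mean_expr)
  target_bins <- table(factor(bin[target_set], levels = seq_along(brk[-1])))
  pool <- setdiff(names(mean_expr), target_set)
  pool_by_bin <- split(pool, factor(bin[pool], levels = seq_along(brk[-1])))

  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      picked <- character(0)
      for (b in which(target_bins > 0)) {
        need <- target_bins[[b]]
        avail <- setdiff(pool_by_bin[[b]], picked)
        tvals <- mean_expr[target_set[bin[target_set] == b]]
        take <- character(0)
        for (tv in sample(tvals)) {   # expression-nearest matching
          free <- setdiff(avail, take)
          if (!length(free)) break
          nn <- free[order(abs(mean_expr[free] - tv))]
          take <- c(take, sample(utils::head(nn, k_nearest), 1))
        }
        short <- need - length(take)
        if (short > 0) {
          message(sprintf(
            "control set %d: bin %d short by %d gene(s); borrowing from neighbouring bins",
            s, b, short))
          # widen symmetrically until the shortfall is covered
          radius <- 1L
          while (short > 0 && radius < length(pool_by_bin)) {
            for (nb in unique(c(b - radius, b + radius))) {
              if (short == 0 || nb < 1 || nb > length(pool_by_bin)) next
              extra <- setdiff(pool_by_bin[[nb]], c(picked, take))
              add <- sample(extra, min(short, length(extra)))
              take <- c(take, add)
              short <- short - length(add)
            }
            radius <- radius + 1L
          }
          if (short > 0) stopf("universe too small to match bin %d", b)
        }
        picked <- c(picked, take)
      }
      picked
    })
  })
}

#' GSEA-style weighted running-sum enrichment score
#'
#' Walks the ranked gene list; set members (hits) increment the running
#' sum by |score|^w normalised by the total hit weight, non-members
#' decrement by 1/(N - N_hits). The enrichment score is the signed
#' maximum deviation from zero. Positive ES: the set concentrates at the
#' top of the ranking; negative: at the bottom. If the set covers every
#' ranked gene the miss step is zero and ES = 1 (degenerate complement).
#'
#' @param genes Character vector of gene ids ordered by decreasing score
#'   (or unordered if `scores` given; sorted internally).
#' @param scores Numeric ranking scores (e.g. log2 fold changes), same
#'   length as `genes`.
#' @param gene_set Character vector; must intersect `genes`.
#' @param weight_exponent Hit-weight exponent w (default 1, classic
#'   weighted GSEA).
#' @return List with `es` and `running` (per-position running sum,
#'   ordered by decreasing score).
#' @export
gsea_enrichment_score <- function(genes, scores, gene_set,
                                  weight_exponent = 1) {
  if (length(genes) != length(scores)) stopf("genes/scores length mismatch")
  if (anyDuplicated(genes)) stopf("duplicate genes in ranked list")
  if (any(!is.finite(scores))) stopf("non-finite scores")
  ord <- order(scores, decreasing = TRUE)
  genes <- genes[ord]; scores <- scores[ord]
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0L) stopf("gene set does not intersect the ranked list")
  N <- length(genes)
  w <- abs(scores)^weight_exponent
  hit_w <- ifelse(hit, w, 0)
  denom <- sum(hit_w)
  if (denom == 0) { hit_w <- as.numeric(hit); denom <- n_hit }  # all-zero scores
  step <- hit_w / denom
  if (n_hit < N) step[!hit] <- -1 / (N - n_hit)
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, genes = genes)
}

#' Gene-set permutation p-value for a GSEA enrichment score
#'
#' Null: random gene sets of the same effective size drawn from the
#' ranked universe. One-sided p counts permuted scores at least as
#' extreme with matching sign; the normalised enrichment score divides
#' the observed ES by the mean |ES| of same-signed permutations.
#'
#' @inheritParams gsea_enrichment_score
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `es`, `nes`, `p`, `n_perm`.
#' @export
gsea_permutation_p <- function(genes, scores, gene_set, n_perm = 1000L,
                               weight_exponent = 1, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  if (n_perm < 100L) stopf("n_perm must be >= 100 for a usable null")
  seed <- check_count(seed, "seed", min = 0L)
  obs <- gsea_enrichment_score(genes, scores, gene_set, weight_exponent)
  size <- sum(genes %in% gene_set)
  perm_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    gsea_enrichment_score(genes, scores, sample(genes, size),
                          weight_exponent)$es
  }, numeric(1)))
  if (max(perm_es) - min(perm_es) < 1e-12)
    stopf("degenerate permutation null")
  same_sign <- sign(perm_es) == sign(obs$es)
  if (!any(same_sign)) {
    # no permuted score shares the observed sign: no comparable null
    # deviations, hence no evidence of enrichment in that direction
    message("no same-signed permutation scores; reporting p = 1")
    return(list(es = obs$es, nes = NA_real_, p = 1, n_perm = n_perm))
  }
  p <- (1 + sum(same_sign & abs(perm_es) >= abs(obs$es))) / (1 + n_perm)
  denom <- mean(abs(perm_es[same_sign]))
  list(es = obs$es, nes = obs$es / denom, p = p, n_perm = n_perm)
}

#' Hypergeometric enrichment (upper tail)
#'
#' P(X >= k) for the overlap k between a module and an annotation set
#' drawn from a finite universe, the module-annotation test of the
#' co-expression analysis.
#'
#' @param module_genes,annotation_set Character vectors, subsets of
#'   `universe`.
#' @param universe Character vector of all genes.
#' @return Upper-tail p-value.
#' @export
hypergeometric_enrichment <- function(module_genes, annotation_set, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("empty universe")
  module_genes <- unique(as.character(module_genes))
  annotation_set <- unique(as.character(annotation_set))
  if (!all(module_genes %in% universe) || !all(annotation_set %in% universe))
    stopf("module and annotation set must be subsets of the universe")
  N <- length(universe); K <- length(annotation_set); n <- length(module_genes)
  k <- length(intersect(module_genes, annotation_set))
  if (k > min(K, n)) stopf("impossible overlap")  # unreachable given subsets
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
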