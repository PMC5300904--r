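# Weighted co-expression network analysis: soft-threshold adjacency from
# pairwise correlations, topological overlap, average-linkage clustering
# with a static tree cut, module eigengenes, and hypergeometric module
# annotation. The implementation is self-contained so every matrix step
# can be checked against brute-force oracles.

#' Soft-threshold power selection by scale-free fit
#'
#' For each candidate power, builds the adjacency, bins the connectivity
#' distribution, and fits log10 p(k) against log10 k; returns the
#' smallest power whose signed R-squared (R^2 times the negated slope
#' sign, so only decreasing degree distributions count) reaches
#' `r2_target`, else the power maximising the signed fit (with a
#' message).
#'
#' @param expr Genes x samples matrix (>= 3 samples). Constant genes are
#'   dropped with a warning.
#' @param candidate_powers Powers to scan (default 1:10 and 12).
#' @param r2_target Scale-free fit target (default 0.8).
#' @param mode Adjacency mode, see [adjacency_matrix()].
#' @param n_breaks Connectivity histogram bins (default 10).
#' @return List with `power`, and a `fit` data frame
#'   (power, signed_r2, mean_k).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, 12),
                                r2_target = 0.8, mode = "unsigned",
                                n_breaks = 10L) {
  check_expression_matrix(expr)
  if (ncol(expr) < 3L) stopf("need >= 3 samples")
  if (any(candidate_powers < 1)) stopf("powers must be >= 1")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warnf("dropping %d constant gene(s)", sum(v == 0))
    expr <- expr[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(expr))
  fit <- lapply(candidate_powers, function(b) {
    a <- adjacency_matrix(r, b, mode)
    k <- rowSums(a)
    brk <- unique(seq(min(k), max(k), length.out = n_breaks + 1))
    if (length(brk) < 3L) return(list(signed_r2 = -Inf, mean_k = mean(k)))
    bin <- cut(k, brk, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    km <- tapply(k, bin, mean)
    ok <- !is.na(pk) & pk > 0 & km > 0
    if (sum(ok) < 3L) return(list(signed_r2 = -Inf, mean_k = mean(k)))
    fm <- stats::lm(log10(pk[ok]) ~ log10(km[ok]))
    r2 <- summary(fm)$r.squared
    list(signed_r2 = -sign(stats::coef(fm)[2]) * r2, mean_k = mean(k))
  })
  fit_df <- data.frame(power = candidate_powers,
                       signed_r2 = vapply(fit, `[[`, numeric(1), "signed_r2"),
                       mean_k = vapply(fit, `[[`, numeric(1), "mean_k"))
  hit <- which(fit_df$signed_r2 >= r2_target)
  if (length(hit)) {
    power <- fit_df$power[hit[1]]
  } else {
    power <- fit_df$power[which.max(fit_df$signed_r2)]
    message(sprintf(
      "no candidate reached signed R^2 >= %.2f; using power %g (best fit %.2f)",
      r2_target, power, max(fit_df$signed_r2)))
  }
  list(power = power, fit = fit_df)
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned: a = |r|^beta; signed: a = ((1 + r) / 2)^beta. The diagonal
#' is set to 0 so connectivity sums exclude self-edges.
#'
#' @param cor_matrix Symmetric correlation matrix, entries in \[-1, 1\].
#' @param beta Soft-threshold power (> 0).
#' @param mode "unsigned" (default) or "signed".
#' @return Adjacency matrix with entries in \[0, 1\] and zero diagonal.
#' @export
adjacency_matrix <- function(cor_matrix, beta, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  beta <- check_number(beta, "beta", min = 0, strict_min = TRUE)
  if (!is.matrix(cor_matrix) || nrow(cor_matrix) != ncol(cor_matrix))
    stopf("`cor_matrix` must be square")
  if (max(abs(cor_matrix)) > 1 + 1e-8) stopf("correlations outside [-1, 1]")
  a <- if (mode == "unsigned") abs(cor_matrix)^beta
       else ((1 + cor_matrix) / 2)^beta
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 - A_ij) for
#' i != j with k_i the connectivity of gene i; TOM_ii = 1. Measures how
#' much two genes share network neighbours beyond their direct edge.
#'
#' @param A Symmetric adjacency with zero diagonal, entries in \[0, 1\].
#' @return Symmetric TOM with unit diagonal, entries in \[0, 1\].
#' @export
topological_overlap <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stopf("`A` must be square")
  if (any(A < 0)) stopf("negative adjacency entries")
  if (any(abs(diag(A)) > 1e-12)) stopf("`A` must have zero diagonal")
  if (max(A) > 1 + 1e-8) stopf("adjacency entries above 1")
  k <- rowSums(A)
  L <- A %*% A
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on dissimilarity 1 - TOM with
#' a static cut; clusters below `min_module_size` are labelled
#' "unassigned", remaining modules are renamed M1, M2, ... by decreasing
#' size (ties by first appearance in the tree).
#'
#' @param tom Topological overlap matrix with gene dimnames.
#' @param cut_height Static cut height in (0, 1\]; by default the
#'   midpoint of the largest gap between consecutive sorted merge
#'   heights, i.e. the dissimilarity scale that best separates
#'   within-branch from between-branch merges (two-scale trees, as
#'   produced by modular networks, are cut between the scales).
#' @param min_module_size Minimum genes per reported module (default 30).
#' @return Named character vector gene -> "M1", ..., or "unassigned".
#' @export
detect_modules <- function(tom, cut_height = NULL, min_module_size = 30L) {
  min_module_size <- check_count(min_module_size, "min_module_size")
  if (is.null(rownames(tom))) stopf("`tom` must carry gene ids as dimnames")
  d <- stats::as.dist(1 - tom)
  h <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) {
    # Static cut at the widest gap between consecutive merge heights in
    # the upper half of the tree: for a modular network the few
    # between-module merges sit above a gap over the within-module
    # continuum. The lower half is ignored so tight outlier pairs do not
    # attract the cut.
    hs <- sort(h$height)
    if (length(hs) > 1L) {
      upper <- hs[hs >= stats::median(hs)]
      gaps <- diff(upper)
      i <- which.max(gaps)
      cut_height <- (upper[i] + upper[i + 1]) / 2
    } else cut_height <- hs
    cut_height <- min(cut_height, 1)
  }
  check_number(cut_height, "cut_height", min = 0, max = 1, strict_min = TRUE)
  cl <- stats::cutree(h, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  out <- rep("unassigned", length(cl))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep))
      out[cl == as.integer(keep[i])] <- sprintf("M%d", i)
  }
  stats::setNames(out, rownames(tom))
}

#' Module eigengene (first principal component summary)
#'
#' First principal component across samples of the per-gene z-scored
#' module submatrix, oriented so its mean correlation with member genes
#' is non-negative.
#'
#' @param expr Genes x samples matrix.
#' @param module_genes >= 2 gene ids present in `expr`; constant genes
#'   are an error.
#' @return Named per-sample numeric vector (unit length).
#' @export
module_eigengene <- function(expr, module_genes) {
  check_expression_matrix(expr)
  module_genes <- as.character(module_genes)
  if (length(module_genes) < 2L) stopf("need >= 2 module genes")
  if (!all(module_genes %in% rownames(expr)))
    stopf("module genes missing from the matrix")
  x <- expr[module_genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) stopf("constant gene row(s) in module")
  z <- (x - rowMeans(x)) / sds
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  # orientation: the eigengene tracks, not mirrors, its members; note
  # this makes the eigengene of sign-flipped data flip sign too
  if (mean(stats::cor(eg, t(z))) < 0) eg <- -eg
  stats::setNames(eg, colnames(expr))
}

#' Hypergeometric annotation enrichment of modules
#'
#' Tests each (module, annotation set) pair for overlap enrichment with
#' [hypergeometric_enrichment()]; modules are flagged enriched at
#' p < alpha (default 1e-2, the module-annotation gate).
#'
#' @param modules Named character vector gene -> module id (use
#'   "unassigned" for background genes); the names define the universe.
#' @param sets Named list of gene-id vectors (a gene-set collection);
#'   members outside the universe are dropped.
#' @param alpha Enrichment gate (default 1e-2).
#' @return Data frame: module, set, module_size, set_size, overlap, p,
#'   enriched.
#' @export
module_annotation_enrichment <- function(modules, sets, alpha = 1e-2) {
  if (is.null(names(modules))) stopf("`modules` must be named by gene")
  if (!is.list(sets) || is.null(names(sets)))
    stopf("`sets` must be a named list of gene vectors")
  universe <- names(modules)
  mods <- setdiff(unique(modules), "unassigned")
  rows <- list()
  for (m in mods) {
    mg <- universe[modules == m]
    if (!length(mg)) { message(sprintf("module %s empty; skipped", m)); next }
    for (s in names(sets)) {
      sg <- intersect(sets[[s]], universe)
      p <- hypergeometric_enrichment(mg, sg, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = s, module_size = length(mg),
        set_size = length(sg), overlap = length(intersect(mg, sg)),
        p = p, enriched = p < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
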