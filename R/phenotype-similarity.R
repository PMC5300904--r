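# Shared-program analysis across knockdowns: fold-change profiles of
# genes dysregulated in at least one knockdown are correlated and
# clustered to reveal lncRNA/TF pairs regulating common genes.

#' Assemble a fold-change matrix over significant genes
#'
#' Rows are the union of genes significant (p < alpha) in at least one
#' contrast; columns are contrasts; values are each contrast's log2 fold
#' change. Mirrors the screen's convention of correlating knockdown
#' phenotypes only over genes dysregulated somewhere.
#'
#' @param de_tables Named list of DE tables from [anova_de()], all on the
#'   same gene universe.
#' @param alpha Significance gate (default 1e-3).
#' @return A list with `fc` (genes x contrasts matrix; zero rows when no
#'   gene is significant anywhere, with `status = "empty"`), `significant`
#'   (logical matrix of the same shape recording which contrast made each
#'   gene significant), and `status` ("ok"/"empty").
#' @export
build_foldchange_matrix <- function(de_tables, alpha = 1e-3) {
  if (!is.list(de_tables) || length(de_tables) < 2L)
    stopf("need >= 2 DE tables")
  if (is.null(names(de_tables)) || any(names(de_tables) == ""))
    stopf("`de_tables` must be named by contrast")
  universe <- de_tables[[1]]$gene
  for (nm in names(de_tables)) {
    if (!identical(sort(de_tables[[nm]]$gene), sort(universe)))
      stopf("contrast '%s' has a different gene universe", nm)
  }
  sig <- vapply(de_tables, function(d)
    d$p[match(universe, d$gene)] < alpha, logical(length(universe)))
  fc <- vapply(de_tables, function(d)
    d$log2fc[match(universe, d$gene)], numeric(length(universe)))
  if (length(universe) == 1L) {  # vapply drops to vector
    sig <- matrix(sig, nrow = 1); fc <- matrix(fc, nrow = 1)
    colnames(sig) <- colnames(fc) <- names(de_tables)
  }
  rownames(sig) <- rownames(fc) <- universe
  keep <- rowSums(sig) > 0
  list(fc = fc[keep, , drop = FALSE],
       significant = sig[keep, , drop = FALSE],
       status = if (any(keep)) "ok" else "empty")
}

#' Pairwise Pearson correlation of knockdown phenotypes
#'
#' Correlates every pair of contrasts' log2 fold changes over the retained
#' genes; p-values from the t transform with n - 2 degrees of freedom.
#'
#' @param fc A fold-change matrix result from [build_foldchange_matrix()],
#'   or a plain genes x contrasts matrix.
#' @return A list with symmetric matrices `r` (unit diagonal) and `p`.
#' @export
pairwise_phenotype_correlation <- function(fc) {
  m <- if (is.list(fc)) fc$fc else fc
  if (!is.matrix(m) || nrow(m) < 3L)
    stopf("need >= 3 retained genes to correlate phenotypes")
  v <- apply(m, 2, stats::var)
  if (any(v == 0))
    stopf("zero-variance contrast(s): %s",
          paste(colnames(m)[v == 0], collapse = ", "))
  r <- stats::cor(m)
  n <- nrow(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(r) <- 1; diag(p) <- 0
  list(r = r, p = p, n = n)
}

#' Unsupervised clustering of knockdown contrasts
#'
#' Average-linkage hierarchical clustering of contrasts on distance
#' 1 - Pearson r of their fold-change profiles.
#'
#' @param fc As for [pairwise_phenotype_correlation()].
#' @return An [stats::hclust] object (leaf order deterministic given the
#'   input; contrasts are taken in sorted label order before clustering).
#' @export
cluster_contrasts <- function(fc) {
  m <- if (is.list(fc)) fc$fc else fc
  if (!is.matrix(m) || ncol(m) < 2L) stopf("need >= 2 contrasts")
  m <- m[, order(colnames(m)), drop = FALSE]
  cc <- pairwise_phenotype_correlation(m)
  stats::hclust(stats::as.dist(1 - cc$r), method = "average")
}

#' Union of the most regulated genes of two contrasts
#'
#' The k genes with largest absolute log2 fold change in each contrast
#' (ties broken by smaller p, then lexicographic gene id), unioned.
#' Mirrors plotting the "top 100 most regulated" genes of two knockdowns.
#'
#' @param de_a,de_b DE tables on a common gene universe.
#' @param k Genes per contrast (default 100).
#' @return Character vector of gene ids (sorted); a warning is issued and
#'   all genes returned if `k` exceeds the universe.
#' @export
top_regulated_union <- function(de_a, de_b, k = 100L) {
  k <- check_count(k, "k")
  if (!identical(sort(de_a$gene), sort(de_b$gene)))
    stopf("DE tables have different gene universes")
  if (k >= nrow(de_a)) {
    if (k > nrow(de_a)) warnf("k = %d exceeds the %d-gene universe; returning all genes",
                              k, nrow(de_a))
    return(sort(de_a$gene))
  }
  top_k <- function(d) {
    ord <- order(-abs(d$log2fc), d$p, d$gene)
    d$gene[ord][seq_len(k)]
  }
  sort(union(top_k(de_a), top_k(de_b)))
}
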