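# Cis-regulatory lncRNA scan (nearest protein-coding neighbour plus
# expression correlation across a cohort) and negative-binomial Wald
# differential expression for disease count cohorts, with
# median-of-ratios size factors and BH adjustment.

interval_distance <- function(s1, e1, s2, e2) {
  # 0-based half-open intervals; 0 iff they overlap
  if (s2 >= e1) s2 - e1 else if (s1 >= e2) s1 - e2 else 0L
}

#' Nearest protein-coding gene to a lncRNA
#'
#' Scans the lncRNA's chromosome for the coding gene minimising the
#' interval distance (0 when overlapping) within `max_distance`. Ties
#' are broken toward the lncRNA's 5' side (lower coordinates on "+",
#' higher on "-"), then by lexicographic gene id.
#'
#' @param lnc_id Gene id of the lncRNA.
#' @param annot Gene annotation data frame with columns chrom, start,
#'   end (0-based half-open), strand, gene_id, biotype.
#' @param max_distance Search window in bp (default 1 Mb).
#' @return One-row data frame of the partner record with an added
#'   `distance` column, or `NULL` when no coding gene is in range.
#' @export
nearest_coding_gene <- function(lnc_id, annot, max_distance = 1e6) {
  i <- match(lnc_id, annot$gene_id)
  if (is.na(i)) stopf("lncRNA '%s' absent from annotation", lnc_id)
  lnc <- annot[i, ]
  cand <- annot[annot$chrom == lnc$chrom & annot$biotype == "coding" &
                  annot$gene_id != lnc_id, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  d <- mapply(interval_distance, lnc$start, lnc$end, cand$start, cand$end)
  cand <- cand[d <= max_distance, , drop = FALSE]
  d <- d[d <= max_distance]
  if (!nrow(cand)) return(NULL)
  # 5'-side indicator: on "+" the 5' side is lower coordinates
  mid_l <- (lnc$start + lnc$end) / 2
  mid_c <- (cand$start + cand$end) / 2
  five_prime <- if (identical(lnc$strand, "-")) mid_c > mid_l else mid_c < mid_l
  ord <- order(d, !five_prime, cand$gene_id)
  out <- cand[ord[1], , drop = FALSE]
  out$distance <- d[ord[1]]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a t-based p-value
#'
#' @param x,y Numeric vectors of equal length n >= 3, finite, each with
#'   non-zero variance.
#' @return List with `r` and two-sided `p` (t transform, n - 2 df;
#'   p = 0 at r = +/-1).
#' @export
correlation_pvalue <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stopf("need n >= 3 paired values")
  if (any(!is.finite(c(x, y)))) stopf("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0) stopf("zero-variance input")
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1 - 1e-15) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Scan for candidate cis-regulatory lncRNAs
#'
#' Pairs every lncRNA with its nearest protein-coding neighbour and
#' correlates their expression across the cohort; pairs with correlation
#' p below `p_threshold` (default 1e-7) are flagged candidate
#' cis-regulatory lncRNAs. lncRNAs with no coding gene within
#' `max_distance` are reported via message and excluded.
#'
#' @param expr Genes x samples expression matrix.
#' @param annot Gene annotation data frame (see [nearest_coding_gene()]).
#' @param p_threshold Candidate gate (default 1e-7).
#' @param max_distance Pairing window in bp (default 1 Mb).
#' @return Data frame: lnc, partner, distance, r, p, candidate.
#' @export
cis_pair_scan <- function(expr, annot, p_threshold = 1e-7,
                          max_distance = 1e6) {
  check_expression_matrix(expr)
  if (!any(annot$biotype == "coding")) stopf("no coding genes in annotation")
  lncs <- annot$gene_id[annot$biotype == "lncRNA"]
  lncs <- lncs[lncs %in% rownames(expr)]
  rows <- lapply(lncs, function(l) {
    partner <- nearest_coding_gene(l, annot, max_distance)
    if (is.null(partner) || !partner$gene_id %in% rownames(expr)) {
      message(sprintf("lncRNA %s: no coding partner within %g bp; excluded",
                      l, max_distance))
      return(NULL)
    }
    ct <- correlation_pvalue(expr[l, ], expr[partner$gene_id, ])
    data.frame(lnc = l, partner = partner$gene_id,
               distance = partner$distance, r = ct$r, p = ct$p,
               candidate = ct$p < p_threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(lnc = character(), partner = character(),
                      distance = numeric(), r = numeric(), p = numeric(),
                      candidate = logical())
  rownames(out) <- NULL
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-sample-expressed genes of the
#' ratio count / geometric mean across samples — the standard library
#' size normalisation for count differential expression.
#'
#' @param counts Genes x samples non-negative count matrix.
#' @return Named positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (!is.matrix(counts) || any(counts < 0)) stopf("`counts` must be a non-negative matrix")
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) stopf("no gene has nonzero counts in all samples")
  sf <- apply(counts, 2, function(col)
    exp(stats::median(log(col[usable]) - log_geo[usable])))
  stats::setNames(sf, colnames(counts))
}

#' Negative-binomial Wald differential expression
#'
#' Two-condition count model: normalised per-condition means, per-gene
#' dispersion by method of moments (floored at 1e-8), and a Wald test on
#' the log2 fold change with variance propagated from the NB mean-variance
#' relation Var(K) = mu + alpha mu^2. P-values are BH-adjusted; genes with
#' a condition entirely at zero counts are reported with NA statistics.
#'
#' @param counts Genes x samples integer matrix.
#' @param conditions Factor (2 levels; first level is the reference,
#'   e.g. control) aligned with columns.
#' @param sf Optional size factors (default [size_factors()] of `counts`).
#' @param alpha Significance gate on adjusted p (default 0.05).
#' @return Data frame: gene, baseMean, log2fc, stat, p, padj, significant.
#' @export
nb_wald_de <- function(counts, conditions, sf = NULL, alpha = 0.05) {
  if (!is.matrix(counts)) stopf("`counts` must be a matrix")
  conditions <- as.factor(conditions)
  if (nlevels(conditions) != 2L) stopf("exactly 2 conditions required")
  if (length(conditions) != ncol(counts)) stopf("conditions/columns mismatch")
  if (min(table(conditions)) < 2L) stopf("need >= 2 samples per condition")
  if (is.null(sf)) sf <- size_factors(counts)
  if (any(sf <= 0)) stopf("size factors must be positive")

  q <- sweep(counts, 2, sf, "/")
  ref <- levels(conditions)[1]
  idx0 <- which(conditions == ref); idx1 <- which(conditions != ref)
  n0 <- length(idx0); n1 <- length(idx1)
  m0 <- rowMeans(q[, idx0, drop = FALSE])
  m1 <- rowMeans(q[, idx1, drop = FALSE])
  v0 <- apply(q[, idx0, drop = FALSE], 1, stats::var)
  v1 <- apply(q[, idx1, drop = FALSE], 1, stats::var)

  # Method-of-moments dispersion on normalised counts:
  # Var(K/s) = mu/s + alpha mu^2, pooled over the two conditions.
  inv0 <- mean(1 / sf[idx0]); inv1 <- mean(1 / sf[idx1])
  num <- (n0 - 1) * (v0 - m0 * inv0) + (n1 - 1) * (v1 - m1 * inv1)
  den <- (n0 - 1) * m0^2 + (n1 - 1) * m1^2
  disp <- pmax(num / den, 1e-8)

  ok <- m0 > 0 & m1 > 0
  lfc <- stat <- p <- rep(NA_real_, nrow(counts))
  lfc[ok] <- log2(m1[ok] / m0[ok])
  # Var(mean_c of K/s) = sum_j (mu/s_j + alpha mu^2) / n_c^2
  var_m0 <- (m0 * sum(1 / sf[idx0]) + disp * m0^2 * n0) / n0^2
  var_m1 <- (m1 * sum(1 / sf[idx1]) + disp * m1^2 * n1) / n1^2
  se_lfc <- sqrt(var_m0 / m0^2 + var_m1 / m1^2) / log(2)
  stat[ok] <- lfc[ok] / se_lfc[ok]
  p[ok] <- 2 * stats::pnorm(-abs(stat[ok]))
  padj <- rep(NA_real_, length(p))
  padj[ok] <- bh_adjust(p[ok])
  data.frame(gene = rownames(counts), baseMean = rowMeans(q),
             log2fc = lfc, stat = stat, p = p, padj = padj,
             significant = !is.na(padj) & padj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (monotone, never below the
#' raw p); thin validating wrapper around the standard implementation.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
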