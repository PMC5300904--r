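# Per-target differential expression for the knockdown screen and the
# combinatorial control-split specificity null: pooled target replicates
# are compared with pooled non-targeting controls by a per-gene two-group
# one-way ANOVA, and DE counts from target-vs-control comparisons are
# ranked against DE counts from 2-vs-3 splits of the control panel.

#' Per-gene two-group ANOVA differential expression
#'
#' For each gene, compares pooled target samples against pooled control
#' samples with a one-way two-group F test (the pooled-variance t squared),
#' the screen's per-target DE test. Genes with zero within- and
#' between-group variance get F = 0, p = 1.
#'
#' @param expr Genes x samples log2 expression matrix with dimnames.
#' @param target_samples,control_samples Disjoint sample-id vectors,
#'   at least 2 samples each.
#' @param alpha Significance level for the `significant` flag
#'   (default 1e-3, the screen's DE gate).
#' @return A data frame (one row per gene): `gene`, `log2fc`
#'   (mean target - mean control), `F`, `p`, `significant`.
#' @export
anova_de <- function(expr, target_samples, control_samples, alpha = 1e-3) {
  check_expression_matrix(expr)
  alpha <- check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  target_samples <- as.character(target_samples)
  control_samples <- as.character(control_samples)
  missing <- setdiff(c(target_samples, control_samples), colnames(expr))
  if (length(missing))
    stopf("samples not in matrix: %s", paste(missing, collapse = ", "))
  if (length(intersect(target_samples, control_samples)))
    stopf("target and control sample sets overlap")
  nA <- length(target_samples); nB <- length(control_samples)
  if (nA < 2L || nB < 2L) stopf("need >= 2 samples per group")

  xa <- expr[, target_samples, drop = FALSE]
  xb <- expr[, control_samples, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  df2 <- nA + nB - 2L
  s2 <- (ssa + ssb) / df2
  d <- ma - mb
  Fs <- d^2 / (s2 * (1 / nA + 1 / nB))
  p <- stats::pf(Fs, 1, df2, lower.tail = FALSE)
  degenerate <- s2 == 0
  Fs[degenerate & d == 0] <- 0
  p[degenerate & d == 0] <- 1
  Fs[degenerate & d != 0] <- Inf
  p[degenerate & d != 0] <- 0
  data.frame(gene = rownames(expr), log2fc = d, F = Fs, p = p,
             significant = p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Enumerate 2-vs-complement splits of the control amiRNA panel
#'
#' All unordered 2-subsets of the control groups paired with their
#' complements, in deterministic lexicographic order. With the screen's
#' five control amiRNAs this yields the ten possible 2-vs-3 combinations.
#'
#' @param control_groups Character vector of >= 3 control group labels.
#' @return A list of lists, each with `pair` (2 labels) and
#'   `complement` (the remaining labels).
#' @export
enumerate_control_partitions <- function(control_groups) {
  control_groups <- sort(unique(as.character(control_groups)))
  n <- length(control_groups)
  if (n < 3L) stopf("need >= 3 control groups, got %d", n)
  pairs <- utils::combn(control_groups, 2L, simplify = FALSE)
  lapply(pairs, function(p)
    list(pair = p, complement = setdiff(control_groups, p)))
}

#' Control-split specificity null for one knockdown target
#'
#' Tests whether a target's two independent amiRNAs deregulate more genes
#' than expected from amiRNA-to-amiRNA variation alone. DE-gene counts
#' from every 2-vs-3 split of the control panel form the null; the fixed
#' target amiRNA pair is compared against every control triple; a
#' one-sided exact Mann-Whitney test asks whether target counts are
#' stochastically larger.
#'
#' @param expr Genes x samples log2 matrix.
#' @param design Knockdown design as produced by
#'   [simulate_knockdown_experiment()]: `targets` maps target name to a
#'   list of amiRNA sample-id groups; `controls` is a list of control
#'   sample-id groups.
#' @param target Target name; must have exactly two amiRNA groups
#'   (targets with a single efficient amiRNA are outside this analysis).
#' @param alpha Per-gene DE significance gate (default 1e-3).
#' @return A list with `control_counts` (named by "pairAB" split),
#'   `target_counts` (named by control triple), `mw_p`, `median_control`,
#'   `iqr_control`.
#' @export
specificity_null <- function(expr, design, target, alpha = 1e-3) {
  check_expression_matrix(expr)
  if (!target %in% names(design$targets))
    stopf("unknown target '%s'", target)
  tg <- design$targets[[target]]
  if (length(tg) != 2L)
    stopf("target '%s' has %d amiRNA group(s); the specificity null needs exactly 2 (skipped)",
          target, length(tg))
  controls <- design$controls
  if (length(controls) < 3L) stopf("need >= 3 control groups")
  if (length(controls) < 5L)
    warnf("fewer than 5 control groups; the null is coarse")

  cg <- sort(names(controls))
  partitions <- enumerate_control_partitions(cg)
  control_counts <- vapply(partitions, function(pt) {
    de <- anova_de(expr,
                   unlist(controls[pt$pair], use.names = FALSE),
                   unlist(controls[pt$complement], use.names = FALSE),
                   alpha = alpha)
    sum(de$significant)
  }, numeric(1))
  names(control_counts) <- vapply(partitions, function(pt)
    paste(pt$pair, collapse = "+"), character(1))

  triple_size <- length(cg) - 2L
  triples <- utils::combn(cg, triple_size, simplify = FALSE)
  target_samples <- unlist(tg, use.names = FALSE)
  target_counts <- vapply(triples, function(tr) {
    de <- anova_de(expr, target_samples,
                   unlist(controls[tr], use.names = FALSE), alpha = alpha)
    sum(de$significant)
  }, numeric(1))
  names(target_counts) <- vapply(triples, paste, character(1), collapse = "+")

  list(control_counts = control_counts,
       target_counts = target_counts,
       mw_p = mann_whitney_one_sided(control_counts, target_counts),
       median_control = stats::median(control_counts),
       iqr_control = unname(stats::quantile(control_counts, c(0.25, 0.75))))
}

#' One-sided Mann-Whitney test (second sample stochastically larger)
#'
#' Exact permutation p-value by enumeration of all rank assignments when
#' the pooled sample size is at most `exact_max` (ties handled by
#' mid-ranks, so the enumeration is the exact conditional null given the
#' tie pattern); otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param a Numeric reference sample (e.g. control DE counts).
#' @param b Numeric comparison sample; alternative is that `b` tends to
#'   exceed `a`.
#' @param exact_max Pooled-size cutoff for exact enumeration (default 20).
#' @return A single p-value in (0, 1\].
#' @export
mann_whitney_one_sided <- function(a, b, exact_max = 20L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  if (any(!is.finite(c(a, b)))) stopf("non-finite values")
  nA <- length(a); nB <- length(b); N <- nA + nB
  r <- rank(c(a, b))
  w_obs <- sum(r[(nA + 1):N])
  if (N <= exact_max) {
    picks <- combn_cached(N, nB)
    w_perm <- colSums(matrix(r[picks], nrow = nB))
    # >= with a numeric tolerance: midranks are halves, exact in binary
    mean(w_perm >= w_obs - 1e-9)
  } else {
    u <- w_obs - nB * (nB + 1) / 2
    mu <- nA * nB / 2
    ties <- table(r)
    sigma2 <- nA * nB / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- (u - mu - 0.5) / sqrt(sigma2)
    stats::pnorm(z, lower.tail = FALSE)
  }
}
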