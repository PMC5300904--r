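# Shared fixture builders and independent oracles used across test files.

# Minimal two-target knockdown config on a small array. Effects are
# mixed-sign (up- and downregulation) by default, as real knockdown
# phenotypes are; direction = "down" plants a purely downregulated
# regulon for enrichment-sign tests.
small_knockdown_config <- function(n_genes = 400, effect = -2,
                                   noise_sd = 0.2, seed = 1,
                                   regulon_size = 40, overlap = NULL,
                                   direction = c("mixed", "down")) {
  direction <- match.arg(direction)
  eff <- if (direction == "mixed")
    rep_len(c(effect, -effect), regulon_size) else rep(-abs(effect), regulon_size)
  targets <- list(
    list(name = "t1", n_amirnas = 2L, regulon = 1:regulon_size,
         effect = eff),
    list(name = "t2", n_amirnas = 2L,
         regulon = (regulon_size + 1):(2 * regulon_size), effect = eff))
  shared <- if (is.null(overlap)) list()
            else list(list(a = "t1", b = "t2", overlap = overlap))
  knockdown_sim_config(n_genes = n_genes, targets = targets,
                       n_controls = 5L, replicates_per_amirna = 3L,
                       noise_sd = noise_sd,
                       shared_regulon_pairs = shared, seed = seed)
}

# Adjusted Rand index from the contingency-table formula (independent of
# any clustering package).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Brute-force TOM oracle: triple loop over the definition.
tom_bruteforce <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + A[i, u] * A[u, j]
    out[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  out
}

# Exhaustive hypergeometric upper tail by enumerating all n-subsets of a
# universe of size N with K marked elements.
hyper_enumeration <- function(N, K, n, k) {
  subsets <- utils::combn(N, n, simplify = FALSE)
  marked <- seq_len(K)
  hits <- vapply(subsets, function(s) sum(s %in% marked), numeric(1))
  mean(hits >= k)
}

# Exact one-sided Mann-Whitney oracle: recursive enumeration over which
# pooled positions belong to sample b (independent of combn-based path).
mw_oracle <- function(a, b) {
  r <- rank(c(a, b))
  nB <- length(b); N <- length(r)
  w_obs <- sum(r[(length(a) + 1):N])
  count <- 0L; total <- 0L
  rec <- function(start, left, acc) {
    if (left == 0L) {
      total <<- total + 1L
      if (acc >= w_obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    for (i in start:(N - left + 1L)) rec(i + 1L, left - 1L, acc + r[i])
  }
  rec(1L, nB, 0)
  count / total
}
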