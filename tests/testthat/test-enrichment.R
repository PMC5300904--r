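test_that("islet-enriched definition is strict mean + 2 SD across tissues", {
  genes <- c("a", "b", "c")
  panel <- matrix(rep(c(3, 4, 5), each = 4), nrow = 3, byrow = TRUE,
                  dimnames = list(genes, paste0("t", 1:4)))
  panel["a", ] <- c(3, 5, 3, 5)     # mean 4, sd ~1.155
  panel["b", ] <- c(4, 4, 4, 4)     # constant: sd 0
  panel["c", ] <- c(2, 6, 4, 4)     # mean 4, sd ~1.633
  focal <- c(a = 6.5, b = 4, c = 5.9)
  enr <- islet_enriched_genes(focal, panel)
  expect_true("a" %in% enr)                 # 6.5 > 4 + 2*1.155
  expect_false("b" %in% enr)                # equality is not enrichment
  expect_false("c" %in% enr)                # 5.9 < 4 + 2*1.633
  focal2 <- c(a = 6.5, b = 4.01, c = 5.9)
  expect_true("b" %in% islet_enriched_genes(focal2, panel))  # sd 0 edge
  expect_error(islet_enriched_genes(c(x = 1), panel), "universe")
})

test_that("expression-matched control sets reproduce the target bin profile", {
  set.seed(1)
  universe <- sprintf("g%04d", 1:2000)
  mean_expr <- setNames(rnorm(2000, 8, 2), universe)
  target <- sample(universe, 130)
  sets <- expression_matched_control_sets(target, mean_expr, n_sets = 10,
                                          n_bins = 10, seed = 99)
  expect_length(sets, 10)
  brk <- unique(quantile(mean_expr, probs = seq(0, 1, 0.1)))
  bin <- cut(mean_expr, brk, include.lowest = TRUE, labels = FALSE)
  names(bin) <- universe
  target_profile <- table(factor(bin[target], levels = 1:10))
  for (s in sets) {
    expect_length(s, length(target))
    expect_length(intersect(s, target), 0)
    expect_equal(table(factor(bin[s], levels = 1:10)), target_profile)
    expect_lt(abs(mean(mean_expr[s]) - mean(mean_expr[target])), 0.1)
  }
  # same seed, same sets
  expect_identical(sets, expression_matched_control_sets(
    target, mean_expr, n_sets = 10, n_bins = 10, seed = 99))
})

test_that("control-set sampling borrows from neighbouring bins when a bin is exhausted", {
  universe <- sprintf("g%03d", 1:40)
  mean_expr <- setNames(c(rep(0, 10), seq(1, 3, length.out = 30)), universe)
  target <- universe[1:9]  # nearly exhausts the bottom bin
  expect_message(
    sets <- expression_matched_control_sets(target, mean_expr, n_sets = 2,
                                            n_bins = 4, seed = 3),
    "borrowing")
  for (s in sets) {
    expect_length(s, 9)
    expect_length(intersect(s, target), 0)
  }
})

test_that("GSEA running sum matches the hand-walked example and sign convention", {
  g <- paste0("g", 1:5); s <- c(3, 2, 1, -1, -2)
  top <- gsea_enrichment_score(g, s, "g1")
  expect_equal(top$es, 1)
  expect_equal(top$running, c(1, 0.75, 0.5, 0.25, 0))
  bottom <- gsea_enrichment_score(g, s, c("g4", "g5"))
  expect_lt(bottom$es, 0)
  all_hits <- gsea_enrichment_score(g, s, g)
  expect_equal(all_hits$es, 1)  # degenerate complement: pure hit walk
  expect_error(gsea_enrichment_score(g, s, "zz"), "intersect")
})

test_that("GSEA running sum starts at 0 and returns to 0 for proper subsets", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    g <- paste0("g", 1:n)
    s <- rnorm(n)
    set <- sample(g, sample(2:(n - 1), 1))
    w <- sample(c(0, 0.5, 1, 2), 1)
    run <- gsea_enrichment_score(g, s, set, weight_exponent = w)$running
    expect_lt(abs(run[length(run)]), 1e-9)
  }
})

test_that("gene-set permutation p detects a planted downregulated set and errors at n_perm = 0", {
  cfg <- small_knockdown_config(n_genes = 1000, effect = -2,
                                noise_sd = 0.3, seed = 4,
                                direction = "down")
  sim <- simulate_knockdown_experiment(cfg)
  de <- anova_de(sim$expr,
                 unlist(sim$design$targets$t1, use.names = FALSE),
                 unlist(sim$design$controls, use.names = FALSE))
  res <- gsea_permutation_p(de$gene, de$log2fc, sim$truth$regulons$t1,
                            n_perm = 1000, seed = 2)
  expect_lt(res$es, 0)      # knockdown pushes the set down the ranking
  expect_lt(res$p, 0.01)
  expect_error(gsea_permutation_p(de$gene, de$log2fc,
                                  sim$truth$regulons$t1, n_perm = 0),
               "n_perm")
})

test_that("random sets give roughly uniform permutation p under the null", {
  set.seed(10)
  g <- paste0("g", 1:300)
  s <- rnorm(300)
  ps <- replicate(40, {
    gsea_permutation_p(g, s, sample(g, 25), n_perm = 200,
                       seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps < 0.1), 0)    # some small p occur
  expect_lt(mean(ps < 0.05), 0.2) # but not anti-conservative in bulk
  expect_gt(median(ps), 0.2)
})

test_that("hypergeometric tail is exact against enumeration for small universes", {
  expect_equal(hypergeometric_enrichment(paste0("g", 1:4), paste0("g", 1:5),
                                         paste0("g", 1:10)),
               5 / 210, tolerance = 1e-12)
  # brute-force enumeration oracle over all draws, N <= 12
  cases <- list(c(10, 5, 4, 4), c(12, 6, 5, 3), c(9, 3, 4, 1), c(8, 4, 4, 0))
  for (cs in cases) {
    N <- cs[1]; K <- cs[2]; n <- cs[3]; k <- cs[4]
    u <- paste0("u", 1:N)
    p_pkg <- hypergeometric_enrichment(u[1:n][seq_len(n)],
                                       u[1:K], u)
    # build a module with exactly k overlap
    module <- c(u[seq_len(k)], u[K + seq_len(n - k)])
    p_pkg <- hypergeometric_enrichment(module, u[1:K], u)
    expect_equal(p_pkg, hyper_enumeration(N, K, n, k), tolerance = 1e-12)
  }
  expect_equal(hypergeometric_enrichment(character(0), paste0("g", 1:3),
                                         paste0("g", 1:10)), 1)
  expect_error(hypergeometric_enrichment("x", "y", character(0)),
               "empty universe")
})
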