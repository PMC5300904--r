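test_that("adjacency transform follows the unsigned and signed formulas", {
  r <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(adjacency_matrix(r, 1)[1, 2], 0.5)           # beta = 1: |r|
  expect_equal(adjacency_matrix(r, 2, "signed")[1, 2], 0.0625)
  expect_equal(diag(adjacency_matrix(r, 3)), c(0, 0))
  set.seed(2)
  rr <- cor(matrix(rnorm(100), 10, 10))
  a <- adjacency_matrix(rr, 6)
  expect_true(all(a >= 0 & a <= 1))
  expect_error(adjacency_matrix(rr, 0), "beta")
})

test_that("TOM matches hand computation and a triple-loop brute force", {
  A3 <- matrix(0.5, 3, 3); diag(A3) <- 0
  dimnames(A3) <- list(letters[1:3], letters[1:3])
  tom3 <- topological_overlap(A3)
  expect_equal(tom3[1, 2], 0.5)  # (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_equal(diag(tom3), setNames(rep(1, 3), letters[1:3]))

  # pair with no edges and no shared neighbours
  A0 <- matrix(0, 4, 4); A0[3, 4] <- A0[4, 3] <- 0.9
  dimnames(A0) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_equal(topological_overlap(A0)[1, 2], 0)

  set.seed(7)
  A <- matrix(runif(64), 8, 8); A <- (A + t(A)) / 2; diag(A) <- 0
  dimnames(A) <- list(paste0("g", 1:8), paste0("g", 1:8))
  tom <- topological_overlap(A)
  expect_lt(max(abs(tom - tom_bruteforce(A))), 1e-12)
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("soft-threshold selection honours its contract on edge cases", {
  set.seed(3)
  expr <- matrix(rnorm(50 * 10), 50, 10,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  expect_equal(pick_soft_threshold(expr, r2_target = 0)$power, 1)
  expect_equal(suppressMessages(
    pick_soft_threshold(expr, candidate_powers = 7)$power), 7)
  expr2 <- rbind(expr, konst = rep(1, 10))
  expect_warning(suppressMessages(pick_soft_threshold(expr2)), "constant")
})

test_that("soft power lands in a stable band on planted-module data", {
  powers <- vapply(1:3, function(seed) {
    cfg <- cohort_sim_config(n_genes = 300, n_samples = 40,
                             module_sizes = c(100, 100, 100),
                             loading_mean = 1, loading_sd = 0,
                             noise_sd = 1, seed = seed)
    sim <- simulate_islet_cohort(cfg)
    suppressMessages(pick_soft_threshold(sim$expr)$power)
  }, numeric(1))
  expect_true(all(powers >= 3 & powers <= 12))
})

test_that("module detection recovers planted blocks and respects min size", {
  blocks <- matrix(0.05, 9, 9)
  blocks[1:4, 1:4] <- 0.9; blocks[5:9, 5:9] <- 0.9
  diag(blocks) <- 1
  dimnames(blocks) <- list(paste0("g", 1:9), paste0("g", 1:9))
  mods <- detect_modules(blocks, cut_height = 0.5, min_module_size = 3)
  expect_length(unique(mods[1:4]), 1)
  expect_length(unique(mods[5:9]), 1)
  expect_false(mods[1] == mods[5])
  expect_identical(unname(mods[5]), "M1")  # larger block named first
  all_un <- detect_modules(blocks, cut_height = 0.5, min_module_size = 100)
  expect_true(all(all_un == "unassigned"))
  expect_error(detect_modules(blocks, cut_height = 2), "cut_height")
})

test_that("module detection is invariant to gene order", {
  cfg <- cohort_sim_config(n_genes = 120, n_samples = 30,
                           module_sizes = c(40, 40), loading_sd = 0,
                           noise_sd = 0.5, seed = 5)
  sim <- simulate_islet_cohort(cfg)
  tom <- topological_overlap(adjacency_matrix(cor(t(sim$expr)), 6))
  mods <- detect_modules(tom, min_module_size = 10)
  perm <- sample(nrow(tom))
  mods_p <- detect_modules(tom[perm, perm], min_module_size = 10)
  # same partition up to relabelling
  expect_equal(adjusted_rand_index(mods, mods_p[names(mods)]), 1)
})

test_that("module eigengene summarises a rank-1 module and is sign-stable", {
  s <- seq(-2, 2, length.out = 12)
  expr <- rbind(a = 3 + 2 * s, b = 5 + 0.5 * s, c = -1 + s)
  colnames(expr) <- paste0("smp", 1:12)
  eg <- module_eigengene(expr, c("a", "b", "c"))
  z <- scale(s)[, 1]
  expect_equal(abs(cor(eg, z)), 1, tolerance = 1e-12)
  expect_gt(cor(eg, expr["a", ]), 0)  # oriented with members
  # orientation is deterministic: flipping the data flips members and
  # hence the oriented eigengene
  eg_flip <- module_eigengene(-expr, c("a", "b", "c"))
  expect_equal(eg, -eg_flip, tolerance = 1e-8)
  expect_error(module_eigengene(rbind(expr, k = rep(1, 12)),
                                c("a", "k")), "constant")
})

test_that("eigengene recovers the planted latent factor", {
  cfg <- cohort_sim_config(n_genes = 80, n_samples = 40, module_sizes = 80L,
                           loading_sd = 0, noise_sd = 0.5, seed = 8)
  sim <- simulate_islet_cohort(cfg)
  eg <- module_eigengene(sim$expr, rownames(sim$expr))
  expect_gt(abs(cor(eg, sim$truth$factors[1, ])), 0.9)
})

test_that("module annotation enrichment flags planted label concentration", {
  modules <- setNames(rep(c("M1", "M2", "unassigned"), times = c(30, 30, 40)),
                      paste0("g", 1:100))
  lnc_set <- paste0("g", c(1:20, 95:99))  # 20 of 30 in M1
  sets <- list(lncRNA = lnc_set)
  tab <- module_annotation_enrichment(modules, sets, alpha = 1e-2)
  expect_true(tab$enriched[tab$module == "M1"])
  expect_false(tab$enriched[tab$module == "M2"])
  expect_equal(tab$overlap[tab$module == "M1"], 20)
  # module equal to its annotation set reaches that geometry's minimum p
  m_eq <- setNames(rep(c("M1", "unassigned"), c(10, 40)), paste0("g", 1:50))
  tab_eq <- module_annotation_enrichment(m_eq, list(s = paste0("g", 1:10)))
  expect_equal(tab_eq$p, dhyper(10, 10, 40, 10), tolerance = 1e-12)
})
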