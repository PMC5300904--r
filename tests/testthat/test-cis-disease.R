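toy_annot <- function() {
  data.frame(
    chrom = "chr1",
    start = c(1000, 12000, 30000, 30500, 60000, 2e6),
    end = c(2000, 13000, 30800, 31500, 61000, 2e6 + 1000),
    strand = c("+", "+", "+", "-", "+", "+"),
    gene_id = c("lncA", "codB", "codC", "lncD", "codE", "codFar"),
    biotype = c("lncRNA", "coding", "coding", "lncRNA", "coding", "coding"),
    stringsAsFactors = FALSE)
}

test_that("nearest coding gene minimises interval distance within the window", {
  ann <- toy_annot()
  hit <- nearest_coding_gene("lncA", ann)
  expect_identical(hit$gene_id, "codB")
  expect_equal(hit$distance, 10000)
  # overlap gives distance 0
  hit2 <- nearest_coding_gene("lncD", ann)
  expect_identical(hit2$gene_id, "codC")
  expect_equal(hit2$distance, 0)
  # outside the window: none
  ann_far <- ann[ann$gene_id %in% c("lncA", "codFar"), ]
  expect_null(nearest_coding_gene("lncA", ann_far, max_distance = 1e6))
  expect_error(nearest_coding_gene("nope", ann), "absent")
})

test_that("equidistant coding genes break ties toward the lncRNA 5' side", {
  ann <- data.frame(
    chrom = "chr2",
    start = c(0, 5000, 10000), end = c(1000, 6000, 11000),
    strand = c("+", "+", "+"),
    gene_id = c("codLeft", "lnc", "codRight"),
    biotype = c("coding", "lncRNA", "coding"), stringsAsFactors = FALSE)
  expect_identical(nearest_coding_gene("lnc", ann)$gene_id, "codLeft")
  ann$strand[2] <- "-"   # 5' side flips to higher coordinates
  expect_identical(nearest_coding_gene("lnc", ann)$gene_id, "codRight")
})

test_that("nearest coding gene matches an exhaustive distance-scan oracle", {
  ann <- toy_annot()
  dist_oracle <- function(s1, e1, s2, e2)
    if (s2 >= e1) s2 - e1 else if (s1 >= e2) s1 - e2 else 0
  for (lnc in c("lncA", "lncD")) {
    li <- match(lnc, ann$gene_id)
    cand <- ann[ann$biotype == "coding", ]
    d <- mapply(dist_oracle, ann$start[li], ann$end[li],
                cand$start, cand$end)
    best <- min(d)
    got <- nearest_coding_gene(lnc, ann)
    expect_equal(got$distance, best)
    expect_true(got$gene_id %in% cand$gene_id[d == best])
  }
})

test_that("correlation p-value follows the t transform and its edge cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation_pvalue(x, x), list(r = 1, p = 0, n = 4))
  ct <- correlation_pvalue(x, c(2, 4, 5, 4))
  expect_equal(ct$r, 0.7181848, tolerance = 1e-6)
  expect_equal(ct$p, 0.2818, tolerance = 1e-3)
  # orthogonal profiles: r = 0 gives p = 1
  y <- c(1, -1, -1, 1)
  ct0 <- correlation_pvalue(x, y)
  expect_equal(ct0$r, 0, tolerance = 1e-12)
  expect_equal(ct0$p, 1, tolerance = 1e-12)
  expect_error(correlation_pvalue(x, rep(1, 4)), "zero-variance")
  expect_error(correlation_pvalue(1:2, 1:2), "n >= 3")
})

test_that("cis scan recalls planted pairs and stays silent under the null", {
  pairs <- lapply(1:15, function(i)
    list(lnc = 100L + 2L * i - 1L, coding = 100L + 2L * i, weight = 0.9))
  cfg <- cohort_sim_config(n_genes = 400, n_samples = 64,
                           module_sizes = c(50, 50), lncrna_fraction = 0,
                           cis_pairs = pairs, seed = 12)
  sim <- simulate_islet_cohort(cfg)
  scan <- cis_pair_scan(sim$expr, sim$annotation)
  truth <- sim$truth$cis_pairs
  hit <- scan$candidate[match(truth$lnc, scan$lnc)] &
    scan$partner[match(truth$lnc, scan$lnc)] == truth$coding
  expect_gt(mean(hit), 0.9)

  # null: independent profiles, no candidates expected at 1e-7
  cfg0 <- cohort_sim_config(n_genes = 400, n_samples = 64,
                            module_sizes = c(10, 10), lncrna_fraction = 0,
                            cis_pairs = lapply(1:15, function(i)
                              list(lnc = 100L + 2L * i - 1L,
                                   coding = 100L + 2L * i, weight = 0)),
                            seed = 13)
  sim0 <- simulate_islet_cohort(cfg0)
  scan0 <- cis_pair_scan(sim0$expr, sim0$annotation)
  expect_equal(sum(scan0$candidate), 0)
})

test_that("cis scan excludes lncRNAs with no coding gene in range", {
  ann <- toy_annot()
  ann$start[ann$gene_id == "lncA"] <- 5e6
  ann$end[ann$gene_id == "lncA"] <- 5e6 + 1000
  set.seed(1)
  expr <- matrix(rnorm(6 * 10), 6, 10,
                 dimnames = list(ann$gene_id, paste0("s", 1:10)))
  expect_message(scan <- cis_pair_scan(expr, ann), "excluded")
  expect_false("lncA" %in% scan$lnc)
})

test_that("size factors match the hand-worked example and scale equivariantly", {
  K <- matrix(c(2, 3, 4, 6), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  sf <- size_factors(K)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(unname(sf), c(0.7071, 1.4142), tolerance = 1e-4)
  # identical columns: equal factors
  K2 <- cbind(s1 = c(5, 9), s2 = c(5, 9)); rownames(K2) <- c("a", "b")
  expect_equal(unname(size_factors(K2)), c(1, 1))
  # gene order invariance; column scaling scales its factor
  set.seed(4)
  K3 <- matrix(rpois(60, 50) + 1, 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_equal(size_factors(K3), size_factors(K3[sample(10), ]))
  K4 <- K3; K4[, 2] <- K4[, 2] * 3
  expect_equal(unname(size_factors(K4)[2] / size_factors(K3)[2]),
               3 * unname(size_factors(K4)[1] / size_factors(K3)[1]),
               tolerance = 1e-10)
  expect_error(size_factors(matrix(0, 2, 2)), "no gene")
})

test_that("size factors recover simulated depths within 5%", {
  depths <- rep(c(1, 2, 4), each = 10)
  cfg <- count_sim_config(n_genes = 3000, n_control = 15, n_case = 15,
                          depth_factors = depths,
                          dispersion_meanlog = log(0.02),
                          dispersion_sdlog = 0, seed = 6)
  sim <- simulate_count_cohort(cfg)
  sf <- size_factors(sim$counts)
  ratio <- sf / depths
  expect_lt(max(ratio) / min(ratio) - 1, 0.05)
})

test_that("NB Wald test is calibrated under the null and powered for planted effects", {
  cfg0 <- count_sim_config(n_genes = 3000, n_control = 50, n_case = 15,
                           seed = 7)
  sim0 <- simulate_count_cohort(cfg0)
  de0 <- nb_wald_de(sim0$counts, sim0$conditions)
  expect_lte(mean(de0$significant, na.rm = TRUE), 0.05 + 0.01)

  cfg1 <- count_sim_config(n_genes = 1000, n_control = 50, n_case = 15,
                           de_genes = 1:50, de_log2fc = 2, seed = 8)
  sim1 <- simulate_count_cohort(cfg1)
  de1 <- nb_wald_de(sim1$counts, sim1$conditions)
  power <- mean(de1$significant[de1$gene %in% sim1$truth$de_genes])
  expect_gt(power, 0.8)
  sign_ok <- de1$log2fc[de1$gene %in% sim1$truth$de_genes] > 0
  expect_gt(mean(sign_ok), 0.95)
})

test_that("NB Wald p approaches a Poisson Wald oracle at vanishing dispersion", {
  cfg <- count_sim_config(n_genes = 400, n_control = 30, n_case = 30,
                          mu_meanlog = log(200), mu_sdlog = 0.2,
                          dispersion_meanlog = log(1e-7),
                          dispersion_sdlog = 0, seed = 9)
  sim <- simulate_count_cohort(cfg)
  de <- nb_wald_de(sim$counts, sim$conditions, sf = rep(1, 60))
  m0 <- rowMeans(sim$counts[, sim$conditions == "control"])
  m1 <- rowMeans(sim$counts[, sim$conditions == "case"])
  # Poisson Wald on log2 ratio: Var(log2 m_c) = 1 / (n mu (ln 2)^2)
  se <- sqrt(1 / (30 * m0) + 1 / (30 * m1)) / log(2)
  p_oracle <- 2 * pnorm(-abs(log2(m1 / m0) / se))
  keep <- p_oracle > 1e-6   # avoid ratio blow-up at tiny p
  rel <- abs(de$p[keep] - p_oracle[keep]) / p_oracle[keep]
  # agreement is limited only by moment-based dispersion noise, so the
  # typical (median) relative error is what the limit pins down
  expect_lt(stats::median(rel), 0.1)
})

test_that("genes with an all-zero condition are reported as NA", {
  K <- matrix(c(0, 0, 0, 5, 6, 7,
                10, 12, 9, 11, 10, 12), 2, 6, byrow = TRUE,
              dimnames = list(c("zero_ctl", "ok"), paste0("s", 1:6)))
  cond <- factor(rep(c("control", "case"), each = 3),
                 levels = c("control", "case"))
  de <- nb_wald_de(K, cond, sf = rep(1, 6))
  expect_true(is.na(de$p[1]))
  expect_false(is.na(de$p[2]))
  expect_false(de$significant[1])
})

test_that("BH adjustment matches the hand-applied step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(50)
  padj <- bh_adjust(p)
  expect_true(all(padj >= p))
  expect_true(all(diff(padj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
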