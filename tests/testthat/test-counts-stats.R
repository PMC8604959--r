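test_that("CPM/TPM/FPKM implement their defining formulas", {
  counts <- matrix(c(100L, 100L, 50L, 150L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lens <- c(1000, 2000)
  # two genes, counts (100,100), lengths (1kb,2kb) -> TPM (2/3, 1/3) * 1e6
  tp <- tpm(counts, lens)
  expect_equal(tp[, "s1"], c(g1 = 2e6 / 3, g2 = 1e6 / 3), tolerance = 1e-9)
  # TPM columns sum to 1e6
  expect_equal(unname(colSums(tp)), c(1e6, 1e6))
  # single gene: TPM = 1e6 whatever the count
  expect_equal(as.vector(tpm(matrix(7L, 1, 1), 500)), 1e6)
  # CPM columns sum to 1e6 when lib sizes are column sums
  expect_equal(unname(colSums(cpm(counts))), c(1e6, 1e6))
  # FPKM direct value: count 100, 1 kb, 1e6 reads -> 100
  expect_equal(fpkm(matrix(100L, 1, 1), 1000, lib_sizes = 1e6)[1, 1], 100)
  expect_error(cpm(counts, lib_sizes = c(0, 1)), "> 0")
  expect_error(fpkm(counts, c(0, 100)), "zero-length")
})

test_that("TMM factors are 1 for identical or depth-scaled libraries", {
  set.seed(3)
  base <- rnbinom(500, mu = 200, size = 10) + 1L
  m <- cbind(a = base, b = base)
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  # pure depth scaling: M is identically 0, factors stay 1
  m2 <- cbind(a = base, b = 2L * base)
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches the direct-formula oracle and edgeR on shifted data", {
  set.seed(17)
  n <- 200
  mu <- rgamma(n, shape = 2, rate = 0.01) + 10
  mu2 <- mu
  mu2[1:10] <- mu2[1:10] * 8             # composition shift in one sample
  counts <- cbind(ref = rnbinom(n, mu = mu, size = 15) + 1L,
                  shift = rnbinom(n, mu = mu2, size = 15) + 1L)
  libs <- colSums(counts)
  got <- tmm_factors(counts, ref_sample = 1L)
  oracle_raw <- oracle_tmm_pair(counts[, 2], counts[, 1], libs[2], libs[1])
  oracle <- c(1, oracle_raw) / exp(mean(log(c(1, oracle_raw))))
  expect_equal(unname(got), oracle, tolerance = 1e-6)
  er <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = 1)
  expect_equal(unname(got), unname(er), tolerance = 1e-6)
})

test_that("background-bin factors cancel depth and track composition", {
  set.seed(8)
  bins <- matrix(rnbinom(400, mu = 50, size = 20), 200, 2,
                 dimnames = list(NULL, c("a", "b")))
  f <- background_bin_factors(bins)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  # globally doubled bin counts, identical composition -> factors 1
  b2 <- cbind(a = bins[, 1], b = bins[, 1] * 2L)
  expect_equal(unname(background_bin_factors(b2)), c(1, 1), tolerance = 1e-12)
  # matches the TMM oracle applied to the bin matrix
  expect_equal(background_bin_factors(bins, ref_sample = 1L),
               tmm_factors(bins[rowSums(bins) > 0, ], ref_sample = 1L))
  expect_error(background_bin_factors(matrix(0L, 3, 2)), "zero")
})

test_that("median-CPM filter keeps rows at the threshold", {
  libs <- c(1e6, 1e6, 1e6)
  counts <- rbind(at_07 = c(0.7, 0.7, 0.7), below = c(0.69, 0.69, 0.69),
                  zero = c(0, 0, 0), high = c(100, 100, 100))
  kept <- filter_by_median_cpm(counts, 0.7, lib_sizes = libs)
  expect_setequal(rownames(kept), c("at_07", "high"))
  kept2 <- filter_by_median_cpm(rbind(at_12 = c(1.2, 1.2, 1.2)), 1.2,
                                lib_sizes = libs[1:3])
  expect_equal(rownames(kept2), "at_12")
})

test_that("NB exact test is calibrated under the null and finds 4-fold rows", {
  set.seed(1234)
  groups <- rep(c("A", "B"), each = 3)
  null_counts <- matrix(rnbinom(2000 * 6, size = 1 / 0.05, mu = 100), 2000, 6)
  res <- differential_test(null_counts, groups, lib_sizes = rep(6e5, 6))
  t1 <- mean(res$p < 0.05)
  half_ci <- 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(t1, 0.05 - half_ci)
  expect_lt(t1, 0.05 + half_ci)
  expect_true(all(res$call == "ns" | res$fdr < 0.05))
  # planted 4-fold rows at n = 3 vs 3
  mu_b <- c(rep(100, 1800), rep(400, 200))
  c2 <- cbind(matrix(rnbinom(2000 * 3, size = 20, mu = 100), 2000, 3),
              matrix(rnbinom(2000 * 3, size = 20, mu = mu_b), 2000, 3))
  res2 <- differential_test(c2, groups, lib_sizes = rep(6e5, 6))
  expect_gte(mean(res2$call[1801:2000] == "up"), 0.9)
  # fdr is BH: monotone in p-rank
  ord <- order(res2$p)
  expect_true(all(diff(res2$fdr[ord]) >= -1e-12))
})

test_that("differential calls are invariant to per-sample depth rescaling", {
  set.seed(55)
  groups <- rep(c("A", "B"), each = 3)
  counts <- matrix(rnbinom(300 * 6, size = 20, mu = 150), 300, 6)
  libs <- rep(45000, 6)
  r1 <- differential_test(counts, groups, lib_sizes = libs)
  counts2 <- counts; counts2[, 1] <- counts2[, 1] * 3L
  libs2 <- libs; libs2[1] <- libs2[1] * 3
  r2 <- differential_test(counts2, groups, lib_sizes = libs2,
                          dispersion = attr(r1, "dispersion"))
  ## equalization to the common depth makes this invariance exact up to
  ## pseudo-count rounding: p-values agree closely and calls agree
  expect_equal(r1$p, r2$p, tolerance = 0.05)
  expect_equal(r1$call, r2$call)
})

test_that("identical group means give non-significant calls", {
  set.seed(2)
  counts <- matrix(rpois(100 * 4, 50), 100, 4)
  res <- differential_test(counts, rep(c("A", "B"), each = 2),
                           lib_sizes = rep(5000, 4), dispersion = 0)
  expect_true(all(res$call == "ns"))
  expect_gt(mean(res$p), 0.3)
  expect_error(differential_test(counts[, 1:3], c("A", "A", "B")),
               "at least two")
  expect_error(differential_test(counts, rep("A", 4)), "two groups")
})

test_that("trajectory clustering recovers planted archetypes", {
  set.seed(77)
  arch <- archetype_matrix(genes_per_cluster = 50L, sigma = 0.3)
  cl <- cluster_de_genes(arch$mat, k = 6)
  expect_equal(length(unique(cl$cluster)), 6L)
  expect_gte(ari(cl$cluster, arch$truth), 0.9)
  expect_equal(ari(cl$cluster, arch$truth),
               mclust::adjustedRandIndex(cl$cluster, arch$truth))
})

test_that("clustering z-scores rows and handles degenerate genes", {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 4, 6, 8, 10, 12),
             c = c(6, 5, 4, 3, 2, 1), d = c(9, 7, 5, 3, 1, -1),
             e = c(1, 1, 2, 2, 3, 3), f = c(5, 5, 5, 5, 5, 5))
  expect_warning(cl <- cluster_de_genes(m, k = 2), "constant")
  # identical standardized profiles cluster together
  expect_equal(cl$cluster[["a"]], cl$cluster[["b"]])
  expect_equal(cl$cluster[["c"]], cl$cluster[["d"]])
  # z-scored rows have mean 0 and sd 1
  z <- t(scale(t(m[1:5, ])))
  expect_equal(unname(rowMeans(z)), rep(0, 5))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5))
  expect_error(cluster_de_genes(m, k = 10), "at least k")
})

test_that("filter-then-test matches test-then-filter on surviving rows", {
  set.seed(31)
  counts <- matrix(rnbinom(400 * 6, size = 20, mu = 30), 400, 6,
                   dimnames = list(sprintf("r%03d", 1:400), NULL))
  groups <- rep(c("A", "B"), each = 3)
  libs <- rep(2e4, 6)
  kept <- filter_by_median_cpm(counts, 1000, lib_sizes = libs)
  disp <- 0.05
  p_direct <- differential_test(kept, groups, lib_sizes = libs,
                                dispersion = disp)$p
  all_p <- differential_test(counts, groups, lib_sizes = libs,
                             dispersion = disp)
  expect_equal(p_direct, all_p$p[match(rownames(kept), all_p$row_id)])
})
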