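test_that("QC keeps cells with strictly more than min_genes expressed genes", {
  v <- matrix(0, 3, 10)
  v[1, ] <- 1            # 10 expressed genes
  v[2, 1:5] <- 1         # exactly 5
  v[3, 1:6] <- 1         # 6
  em <- tiny_em(v, rep("sham", 3))
  kept <- qc_filter_cells(em, min_genes = 5, rpkm_floor = 0.1)
  expect_setequal(cell_ids(kept), c("c1", "c3"))
  expect_error(qc_filter_cells(em, min_genes = 10), "every cell")
})

test_that("one-way ANOVA matches the hand-computed two-group fixture", {
  em <- tiny_em(matrix(1:6, ncol = 1),
                c("sham", "sham", "sham", "D3", "D3", "D3"))
  res <- anova_screen(em)
  expect_equal(res$f_statistic, 13.5)
  expect_equal(res$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
})

test_that("constant genes get p = 1 and are never significant", {
  v <- cbind(rep(3, 8), rnorm(8)^2)
  em <- tiny_em(v, rep(c("sham", "D3"), each = 4))
  res <- anova_screen(em)
  expect_equal(res$p_value[1], 1)
  expect_equal(res$f_statistic[1], 0)
  expect_false(res$significant[1])
})

test_that("ANOVA F and p agree with lm()/anova() on random fixtures", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    n_per <- sample(2:6, k, replace = TRUE)
    g <- rep(timecourse_groups()[seq_len(k)], n_per)
    v <- matrix(rexp(sum(n_per) * 3), ncol = 3)
    em <- tiny_em(v, g)
    res <- anova_screen(em)
    for (j in 1:3) {
      fit <- anova(lm(v[, j] ~ factor(g)))
      expect_equal(res$f_statistic[j], fit$`F value`[1], tolerance = 1e-8)
      expect_equal(res$p_value[j], fit$`Pr(>F)`[1], tolerance = 1e-8)
    }
  }
})

test_that("ANOVA screen requires at least 2 cells per group", {
  em <- tiny_em(matrix(1:5, ncol = 1), c("sham", "sham", "D3", "D3", "W1"))
  expect_error(anova_screen(em), "W1")
})

test_that("BH adjustment is monotone and bounded below by raw p", {
  sim <- simulate_timecourse(sim_config(
    n_genes = 120, cells_per_group = rep(8L, 6), n_cluster1_genes = 10,
    n_pos_corr = 10, n_neg_corr = 10, seed = 6))
  res <- anova_screen(sim$matrix, correction = "BH", transform = "log2")
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
  ord <- order(res$p_value)
  expect_true(all(diff(res$adjusted_p[ord]) >= -1e-15))
})

test_that("profiles are z-scored group means with the documented conventions", {
  v <- matrix(rep(c(1, 1, 2, 2, 4, 4, 8, 8, 16, 16, 32, 32), 2), ncol = 2)
  v[, 2] <- 5  # constant gene
  em <- tiny_em(v, rep(timecourse_groups(), each = 2))
  prof <- profile_matrix(em)
  expect_equal(unname(prof["g2", ]), rep(0, 6))     # zero-variance -> zeros
  expect_true(all(diff(prof["g1", timecourse_groups()]) > 0))  # monotone
  expect_equal(sum(prof["g1", ]), 0, tolerance = 1e-12)
  # proportional genes give identical profiles (log offset is removed)
  v3 <- cbind(g1 = v[, 1], g3 = v[, 1])
  em3 <- tiny_em(v3, rep(timecourse_groups(), each = 2))
  p3 <- profile_matrix(em3)
  expect_equal(unname(p3["g1", ]), unname(p3["g3", ]), tolerance = 1e-12)
})

test_that("average-linkage clustering matches the 1-D hand example", {
  p <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("x", "y", "z"), "f"))
  ca <- hcluster_genes(p, h = 5)
  expect_equal(ca$hclust$height, c(1, 9.5))
  expect_equal(ca$k, 2)
  expect_equal(unname(ca$cluster[c("x", "y")]), c(1, 1))
  expect_equal(unname(ca$cluster["z"]), 2)
  # identical profiles merge at height 0
  q <- matrix(c(1, 1, 5), ncol = 1, dimnames = list(c("a", "b", "c"), "f"))
  expect_equal(min(hcluster_genes(q, k = 2)$hclust$height), 0)
})

test_that("clustering agrees with the brute-force agglomeration oracle", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- matrix(rnorm(n * 2), n, dimnames = list(paste0("it", 1:n), NULL))
    oracle <- avg_linkage_oracle(x)
    ca <- hcluster_genes(x, k = 2)
    expect_equal(sort(ca$hclust$height), sort(oracle$heights),
                 tolerance = 1e-10)
    for (k in 1:n) {
      expect_true(same_partition(cutree(ca$hclust, k = k),
                                 oracle$partitions[[k]]))
    }
  }
})

test_that("SSE curve is non-increasing, hits 0 at k = n, finds three blobs", {
  set.seed(5)
  blobs <- rbind(matrix(rnorm(20, 0, 0.1), 10),
                 matrix(rnorm(20, 5, 0.1), 10),
                 matrix(rnorm(20, 10, 0.1), 10))
  rownames(blobs) <- paste0("b", 1:30)
  res <- sse_select_k(blobs, k_range = 1:30)
  expect_true(all(diff(res$curve$sse) <= 1e-9))
  expect_equal(res$curve$sse[res$curve$k == 30], 0, tolerance = 1e-12)
  grand <- colMeans(blobs)
  expect_equal(res$curve$sse[res$curve$k == 1],
               sum(sweep(blobs, 2, grand)^2), tolerance = 1e-10)
  expect_equal(res$recommended_k, 3)
  expect_error(sse_select_k(blobs, integer(0)), "empty")
})

test_that("fold-change ranking follows the pseudocount rules", {
  v <- cbind(gA = c(10, 10, 0.5, 0.5), gB = c(2, 2, 2, 2),
             gC = c(1, 1, 0, 0))
  em <- tiny_em(v, c("D3", "D3", "sham", "sham"))
  fc <- rank_fold_change(em, numerator_group = "D3",
                         denominator_group = "sham")
  # zero denominator for gC triggers fallback pseudocount = min(pos)/2 = 0.25
  expect_equal(fc$fold_change[fc$gene == "gA"], 10.25 / 0.75)
  expect_equal(fc$fold_change[fc$gene == "gB"], 1)
  expect_equal(fc$fold_change[fc$gene == "gC"], 1.25 / 0.25)
  # without zero denominators the default pseudocount is 0
  fc2 <- rank_fold_change(em, genes = c("gA", "gB"),
                          numerator_group = "D3", denominator_group = "sham")
  expect_equal(fc2$fold_change[fc2$gene == "gA"], 20)
  expect_equal(fc2$log2_fc[fc2$gene == "gA"], log2(20), tolerance = 1e-12)
  expect_equal(fc2$gene[1], "gA")  # descending order
})
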