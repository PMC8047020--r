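test_that("marker split uses the strict mean-threshold rule", {
  v <- cbind(mk = c(1, 0, 0, 10, 10), other = 1:5)
  em <- tiny_em(v, c("sham", "D3", "D3", "W1", "W1"))
  part <- split_by_marker(em, "mk")
  expect_equal(part$threshold, 5)    # mean over the four TAC cells
  expect_equal(sum(part$label == "high"), 2)
  expect_equal(sum(part$label == "low"), 2)
  expect_false("c1" %in% names(part$label))  # sham cells not labelled
  # all-equal marker -> zero high cells (strict >)
  v2 <- cbind(mk = rep(4, 4), other = 1:4)
  em2 <- tiny_em(v2, c("D3", "D3", "W1", "W1"))
  expect_equal(sum(split_by_marker(em2, "mk")$label == "high"), 0)
  expect_error(split_by_marker(em, "absent"), "absent")
})

test_that("per-time-point counts sum to the TAC cell counts", {
  sim <- simulate_timecourse(sim_config(
    n_genes = 150, n_cluster1_genes = 15, n_pos_corr = 15, n_neg_corr = 15,
    seed = 12))
  part <- split_by_marker(sim$matrix, "MarkerA")
  tac_n <- table(factor(as.character(sim$matrix$cell_groups), tac_groups()))
  expect_equal(part$counts$n_high + part$counts$n_low, as.vector(tac_n))
  # per-timepoint scope yields one threshold per time point
  p2 <- split_by_marker(sim$matrix, "MarkerA", scope = "per_timepoint")
  expect_length(p2$threshold, 5)
})

test_that("DEG test matches t.test on random data and applies both gates", {
  set.seed(33)
  v <- matrix(rexp(20 * 5), 20, 5)
  em <- tiny_em(v, rep(c("sham", "D3"), each = 10))
  grp <- cell_ids(em)[11:20]; ref <- cell_ids(em)[1:10]
  tab <- deg_test(em, grp, ref, correction = "none")
  for (j in 1:5) {
    tt <- t.test(log2(v[11:20, j] + 1), log2(v[1:10, j] + 1),
                 var.equal = TRUE)
    expect_equal(tab$t_statistic[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p_value[j], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(tab$log2_fc,
               log2((colMeans(v[11:20, ]) + 1) / (colMeans(v[1:10, ]) + 1)),
               ignore_attr = TRUE)
})

test_that("identical groups yield no DEGs; the FC gate vetoes tiny effects", {
  v <- matrix(rep(rexp(8), each = 10), nrow = 10) +
    matrix(rnorm(80, sd = 1e-4), 10)
  v <- abs(v)
  em <- tiny_em(v, rep(c("sham", "D3"), each = 5))
  tab <- deg_test(em, cell_ids(em)[6:10], cell_ids(em)[1:5])
  expect_equal(sum(tab$significant), 0)

  # constant 2-fold-below-threshold shift: p ~ 0 but |log2FC| < 1
  v2 <- cbind(g1 = c(rep(1, 6), rep(1.8, 6)))
  em2 <- tiny_em(v2, rep(c("sham", "D3"), each = 6))
  tab2 <- deg_test(em2, cell_ids(em2)[7:12], cell_ids(em2)[1:6])
  expect_lt(tab2$p_value, 1e-10)
  expect_lt(abs(tab2$log2_fc), 1)
  expect_false(tab2$significant)

  expect_error(deg_test(em2, cell_ids(em2)[1], cell_ids(em2)[2:4]),
               "at least 2")
})

test_that("a planted strong shift is detected at moderate group sizes", {
  set.seed(44)
  base <- rexp(30, 1 / 4)
  v <- cbind(hit = c(base, base * 4), null = c(base, base))
  v <- v * exp(rnorm(length(v), sd = 0.1))
  em <- tiny_em(v, rep(c("sham", "D3"), each = 30))
  tab <- deg_test(em, cell_ids(em)[31:60], cell_ids(em)[1:30])
  expect_true(tab$significant[tab$gene == "hit"])
  expect_false(tab$significant[tab$gene == "null"])
})

test_that("common DEG partition is disjoint set arithmetic", {
  mk <- function(sig) {
    d <- data.frame(gene = c("A", "B", "C", "D"), log2_fc = 2,
                    t_statistic = 1, p_value = 0.01, adjusted_p = 0.01,
                    significant = c("A", "B", "C", "D") %in% sig)
    class(d) <- c("DegTable", "data.frame")
    d
  }
  out <- common_degs(mk(c("A", "B", "C")), mk(c("B", "C", "D")))
  expect_setequal(out$common, c("B", "C"))
  expect_equal(out$high_only, "A")
  expect_equal(out$low_only, "D")
  expect_equal(unname(out$counts), c(1, 1, 2))
  out2 <- common_degs(mk(c("A")), mk(c("B")))
  expect_length(out2$common, 0)
  out3 <- common_degs(mk(c("A", "B")), mk(c("A", "B")))
  expect_length(out3$high_only, 0)
  d2 <- mk("A"); d2$gene <- c("A", "B", "C", "E")
  expect_error(common_degs(mk("A"), d2), "universe")
})

test_that("pseudo-sample clustering separates marker-high samples", {
  sim <- simulate_timecourse(sim_config(
    n_genes = 300, n_cluster1_genes = 20, n_pos_corr = 60, n_neg_corr = 60,
    marker_effect = 16, dropout_rate = 0, noise_sd = 0.5, seed = 21))
  part <- split_by_marker(sim$matrix, "MarkerA")
  res <- hcluster_samples(sim$matrix, part)
  expect_equal(nrow(res$profiles), 11)  # sham + 2 x 5 pseudo-samples
  cl <- cutree(res$hclust, k = 2)
  high <- grepl("_high$", names(cl))
  # the five marker-high pseudo-samples form one clade
  expect_equal(length(unique(cl[high])), 1)
  expect_false(unique(cl[high]) %in% cl[!high])
  # deterministic under fixed input
  res2 <- hcluster_samples(sim$matrix, part)
  expect_identical(res$profiles, res2$profiles)
})
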