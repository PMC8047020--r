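test_that("peak-to-gene assignment respects window edges and the score gate", {
  ann <- tiny_tss(tss = 10000L, strand = "+")
  bound_at <- function(start, end, score = 150) {
    ps <- list(peakset("T", "chr1", start, end, score))
    length(assign_peaks_to_genes(ps, ann)$T) > 0
  }
  expect_true(bound_at(9900L, 10100L))        # covers the TSS
  expect_true(bound_at(14900L, 15001L))       # last covered base = 15000
  expect_false(bound_at(15001L, 15100L))      # starts beyond TSS+5000
  expect_true(bound_at(4900L, 5001L))         # reaches down to TSS-5000
  expect_false(bound_at(4900L, 5000L))        # stops one base short
  expect_false(bound_at(9900L, 10100L, score = 99))  # below the gate
  expect_true(bound_at(9900L, 10100L, score = 100))  # gate is inclusive
  expect_error(assign_peaks_to_genes(list(), ann, window = 0), "window")
})

test_that("minus-strand genes are windowed at their transcription end", {
  ann <- tiny_tss(tss = 50000L, strand = "-")
  ps <- list(peakset("T", "chr1", 54000L, 54200L, 200))
  expect_equal(assign_peaks_to_genes(ps, ann)$T, "G1")
})

test_that("contingency tables satisfy the margin identities", {
  tab <- build_contingency(c("A", "B"), c("C", "D"), c("A", "C"))
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  tab0 <- build_contingency(c("A", "B"), c("C", "D", "E"), character(0))
  expect_equal(unlist(tab0[c("a", "b", "c", "d")]),
               c(a = 0, b = 2, c = 0, d = 3))
  set.seed(8)
  for (i in 1:20) {
    uni <- paste0("g", 1:40)
    q <- sample(uni, 10); bgp <- setdiff(uni, q)
    bound <- sample(uni, sample(0:40, 1))
    tab <- build_contingency(q, bgp, bound)
    expect_equal(tab$a + tab$b, 10)
    expect_equal(tab$c + tab$d, 30)
    expect_equal(tab$n, 40)
  }
  expect_error(build_contingency(c("A"), c("A", "B"), character(0)),
               "disjoint")
})

test_that("two-tailed Fisher matches the enumeration oracle and fisher.test", {
  expect_equal(fisher_two_tailed(list(a = 1, b = 1, c = 1, d = 1)), 1)
  expect_equal(fisher_two_tailed(list(a = 5, b = 0, c = 0, d = 5)), 2 / 252,
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:50) {
    tab <- as.list(stats::setNames(sample(0:12, 4, replace = TRUE),
                                   c("a", "b", "c", "d")))
    p <- fisher_two_tailed(tab)
    expect_equal(p, fisher_enum_oracle(tab$a, tab$b, tab$c, tab$d),
                 tolerance = 1e-12)
    if (tab$a + tab$b > 0 && tab$c + tab$d > 0)
      expect_equal(p, fisher.test(matrix(unlist(tab), 2, byrow = TRUE))$p.value,
                   tolerance = 1e-7)
  }
})

test_that("Fisher p is invariant under simultaneous row and column swaps", {
  set.seed(3)
  for (i in 1:20) {
    t0 <- sample(0:15, 4, replace = TRUE)
    p1 <- fisher_two_tailed(list(a = t0[1], b = t0[2], c = t0[3], d = t0[4]))
    p_rows <- fisher_two_tailed(list(a = t0[3], b = t0[4], c = t0[1], d = t0[2]))
    p_cols <- fisher_two_tailed(list(a = t0[2], b = t0[1], c = t0[4], d = t0[3]))
    p_t <- fisher_two_tailed(list(a = t0[1], b = t0[3], c = t0[2], d = t0[4]))
    expect_equal(p1, p_rows, tolerance = 1e-12)
    expect_equal(p1, p_cols, tolerance = 1e-12)
    expect_equal(p1, p_t, tolerance = 1e-12)
  }
})

test_that("TF enrichment handles empty binding and small backgrounds", {
  ann <- make_annotation(60, c(chr1 = 10e6), seed = 6)
  ps <- list(peakset("T", "chr1", 100L, 300L, 50))  # below score gate
  res <- tf_enrichment(ann$gene[1:20], ann, ps, seed = 1)
  expect_equal(res$p, 1)
  expect_false(res$significant)
  expect_error(tf_enrichment(ann$gene[1:50], ann, ps, seed = 1), "background")
  expect_error(tf_enrichment(ann$gene[1:5], ann, list(), seed = 1), "peak")
})

test_that("gene-set ORA ranks a covering set first and validates inputs", {
  uni <- paste0("g", 1:50)
  q <- paste0("g", 1:10)
  sets <- structure(list(all_query = q,
                         random = paste0("g", c(5, 20, 30, 40)),
                         off_universe = paste0("h", 1:5)),
                    class = "GeneSetCollection")
  expect_warning(res <- gene_set_ora(q, sets, uni), "disjoint")
  expect_equal(res$set[1], "all_query")
  expect_equal(res$overlap[res$set == "all_query"], 10)
  expect_false("off_universe" %in% res$set)
  expect_true(all(res$adjusted_p >= res$p - 1e-15))
  expect_error(gene_set_ora(c("zz"), sets, uni), "subset")
})
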