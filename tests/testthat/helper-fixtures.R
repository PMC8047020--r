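# Small fixture builders and independent oracles shared across test files.

# Tiny expression matrix from a plain matrix and group labels.
tiny_em <- function(values, groups) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%d", seq_len(ncol(values)))
  expression_matrix(values, groups)
}

# Independent two-tailed Fisher oracle: enumerate all tables with the
# observed margins via dhyper and sum probabilities <= observed.
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  if (m + n_ == 0 || k == 0 || k == m + n_ || m == 0 || n_ == 0) return(1)
  x <- max(0, k - n_):min(m, k)
  probs <- stats::dhyper(x, m, n_, k)
  p0 <- stats::dhyper(a, m, n_, k)
  min(sum(probs[probs <= p0 * (1 + 1e-7)]), 1)
}

# Brute-force O(n^3) average-linkage agglomeration. Returns merge heights
# and the partition after each merge (list of membership vectors indexed by
# number of clusters). Ties broken by smallest (i, j) cluster-index pair.
avg_linkage_oracle <- function(x) {
  d0 <- as.matrix(stats::dist(x))
  n <- nrow(d0)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  membership <- seq_len(n)
  partitions[[n]] <- membership
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- mean(d0[clusters[[i]], clusters[[j]]])
      if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    heights <- c(heights, best_d)
    membership <- integer(n)
    for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
    partitions[[length(clusters)]] <- membership
  }
  list(heights = heights, partitions = partitions)
}

# TRUE iff two cluster membership vectors describe the same partition.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Edge list: two 4-cliques a1..a4 and b1..b4 joined through a degree-2
# linker vertex X.
two_clique_linker_edges <- function() {
  clique <- function(v) {
    p <- t(utils::combn(v, 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2], stringsAsFactors = FALSE)
  }
  el <- rbind(clique(paste0("a", 1:4)), clique(paste0("b", 1:4)),
              data.frame(gene_a = c("a1", "b1"), gene_b = c("X", "X")))
  el$score <- 900
  class(el) <- c("EdgeList", "data.frame")
  el
}

edgelist_from_df <- function(df) {
  df$score <- df$score %||% 900
  class(df) <- c("EdgeList", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny TSS annotation with known coordinates.
tiny_tss <- function(tss = c(10000L, 50000L, 90000L),
                     strand = rep_len(c("+", "-"), length(tss))) {
  ann <- data.frame(gene = sprintf("G%d", seq_along(tss)), chrom = "chr1",
                    strand = strand, tss = tss, stringsAsFactors = FALSE)
  class(ann) <- c("TssAnnotation", "data.frame")
  ann
}

peakset <- function(tf, chrom, start, end, score) {
  structure(list(tf_name = tf,
                 peaks = data.frame(chrom = chrom, start = start, end = end,
                                    score = score, stringsAsFactors = FALSE)),
            class = "PeakSet")
}
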