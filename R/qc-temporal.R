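#' Filter cells by the number of expressed genes
#'
#' Keeps cells expressing strictly more than `min_genes` genes, where a gene
#' counts as expressed when its value exceeds `rpkm_floor`. Matches the
#' study's QC rule (more than 5,000 genes at RPKM > 0.1).
#'
#' @param x An `ExpressionMatrix`.
#' @param min_genes Minimum expressed-gene count; a cell with exactly this
#'   many is dropped (strict >).
#' @param rpkm_floor Expression floor; a gene is expressed when value > floor.
#' @return Filtered `ExpressionMatrix`.
#' @export
qc_filter_cells <- function(x, min_genes = 5000, rpkm_floor = 0.1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  n_expr <- rowSums(x$values > rpkm_floor)
  keep <- n_expr > min_genes
  if (!any(keep))
    stop("QC removed every cell (min_genes = ", min_genes, ")")
  log_info("qc_filter_cells: kept %d / %d cells", sum(keep), length(keep))
  subset_cells(x, which(keep))
}

#' One-way ANOVA screen for temporally regulated genes
#'
#' Per-gene one-way ANOVA of expression across the experimental groups,
#' computed from group sums of squares. Genes with zero total variance get
#' F = 0 and p = 1 by convention so downstream counts stay well-defined.
#'
#' @param x An `ExpressionMatrix`.
#' @param alpha Significance level (default 0.05).
#' @param correction `"none"` (raw p < alpha) or `"BH"`
#'   (Benjamini-Hochberg adjusted p < alpha).
#' @param transform `"none"` to test the values as given, `"log2"` to test
#'   log2(RPKM + 1).
#' @return Data frame with one row per gene: `gene`, `f_statistic`,
#'   `p_value`, `adjusted_p`, `significant`.
#' @export
anova_screen <- function(x, alpha = 0.05, correction = c("none", "BH"),
                         transform = c("none", "log2")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  correction <- match.arg(correction)
  transform <- match.arg(transform)
  groups <- droplevels(x$cell_groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  n_per <- tabulate(groups, nbins = k)
  small <- which(n_per < 2)
  if (length(small) > 0)
    stop("group with fewer than 2 cells: ", levels(groups)[small[1]])
  v <- x$values
  if (transform == "log2") v <- log2(v + 1)
  n <- nrow(v)
  grand <- colMeans(v)
  sst <- colSums(v^2) - n * grand^2
  gsum <- rowsum(v, groups)                     # k x genes
  ssb <- colSums(gsum^2 / n_per) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  # degenerate cases: no variance at all -> p = 1; perfect separation -> p = 0
  tol <- 1e-12 * pmax(colMeans(v^2), 1)
  zero_tot <- sst <= tol
  f[zero_tot] <- 0; p[zero_tot] <- 1
  exact <- !zero_tot & ssw <= tol
  f[exact] <- Inf; p[exact] <- 0
  adj <- if (correction == "BH") stats::p.adjust(p, "BH") else p
  data.frame(gene = colnames(v), f_statistic = unname(f),
             p_value = unname(p), adjusted_p = unname(adj),
             significant = unname(adj < alpha),
             stringsAsFactors = FALSE)
}

#' Standardized mean time-profiles per gene
#'
#' For each gene, the group means of log2(RPKM+1) over the six groups,
#' z-scored across groups. Zero-variance profiles map to all-zero vectors.
#'
#' @param x An `ExpressionMatrix`.
#' @param genes Genes to profile (default all).
#' @return Numeric matrix, genes x groups, in `timecourse_groups()` order.
#' @export
profile_matrix <- function(x, genes = gene_ids(x)) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  missing <- setdiff(genes, gene_ids(x))
  if (length(missing) > 0)
    stop("gene(s) not present: ", paste(utils::head(missing, 3), collapse = ", "))
  v <- log2(x$values[, genes, drop = FALSE] + 1)
  cnt <- table(droplevels(x$cell_groups))
  gsum <- rowsum(v, droplevels(x$cell_groups))
  means <- t(gsum / as.vector(cnt))             # genes x groups
  mu <- rowMeans(means)
  s <- apply(means, 1, stats::sd)
  prof <- (means - mu) / ifelse(s > 0, s, 1)
  prof[s == 0, ] <- 0
  colnames(prof) <- rownames(gsum)
  prof
}

#' Hierarchical clustering of gene profiles
#'
#' Agglomerative clustering with average linkage and Euclidean distance,
#' cut either at a height threshold or into an explicit number of clusters.
#'
#' @param profiles Numeric matrix, items (genes) x features, with rownames.
#' @param method Linkage method (default `"average"`).
#' @param metric Distance metric (default `"euclidean"`).
#' @param h Cut height; clusters are the subtrees below this merge height.
#' @param k Explicit cluster count (used when `h` is NULL).
#' @return A `ClusterAssignment` list: `cluster` (named integer vector),
#'   `k`, `centroids` (cluster x feature means), `hclust` (the tree),
#'   `linkage`, `cut`.
#' @export
hcluster_genes <- function(profiles, method = "average", metric = "euclidean",
                           h = NULL, k = NULL) {
  if (is.null(dim(profiles)) || nrow(profiles) < 2)
    stop("need at least 2 profiles")
  hc <- stats::hclust(stats::dist(profiles, method = metric), method = method)
  if (is.null(h) && is.null(k)) stop("supply a cut: `h` or `k`")
  cl <- if (!is.null(h)) stats::cutree(hc, h = h) else stats::cutree(hc, k = k)
  kk <- max(cl)
  cent <- rowsum(profiles, cl) / tabulate(cl, nbins = kk)
  structure(list(cluster = cl, k = kk, centroids = cent, hclust = hc,
                 linkage = list(method = method, metric = metric),
                 cut = if (!is.null(h)) list(h = h) else list(k = k)),
            class = "ClusterAssignment")
}

#' Intracluster SSE curve and recommended cluster count
#'
#' For each candidate k, the dendrogram is cut into k clusters and the
#' intracluster sum of squared errors (squared Euclidean distance of each
#' profile to its cluster centroid) is computed. The decrease rate between
#' consecutive k is (SSE[k-1] - SSE[k]) / SSE[k-1]; the recommended k is the
#' one whose decrease rate exceeds the next k's rate by the largest margin
#' (the elbow), ties resolved toward larger k.
#'
#' @param profiles Numeric matrix, items x features.
#' @param k_range Integer vector of candidate cluster counts.
#' @param method,metric Passed to [hcluster_genes()].
#' @return List with `curve` (data frame `k`, `sse`, `decrease_rate`) and
#'   `recommended_k`.
#' @export
sse_select_k <- function(profiles, k_range = 1:10,
                         method = "average", metric = "euclidean") {
  if (length(k_range) == 0) stop("empty k_range")
  if (any(k_range < 1 | k_range > nrow(profiles)))
    stop("k_range must lie within [1, number of profiles]")
  k_range <- sort(unique(as.integer(k_range)))
  hc <- stats::hclust(stats::dist(profiles, method = metric), method = method)
  sse <- vapply(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    cent <- rowsum(profiles, cl) / tabulate(cl, nbins = max(cl))
    sum((profiles - cent[cl, , drop = FALSE])^2)
  }, numeric(1))
  rate <- c(NA_real_, ifelse(sse[-length(sse)] > 0,
                             diff(-sse) / sse[-length(sse)], 0))
  margin <- rate - c(rate[-1], NA_real_)
  cand <- which(!is.na(margin))
  rec <- if (length(cand) == 0) k_range[which.max(rate)] else {
    best <- max(margin[cand])
    k_range[max(cand[margin[cand] >= best - 1e-12])]
  }
  list(curve = data.frame(k = k_range, sse = sse, decrease_rate = rate),
       recommended_k = rec)
}

#' Fold-change ranking of genes between two groups
#'
#' FC = (mean in numerator group + pseudocount) / (mean in denominator group
#' + pseudocount), computed on raw RPKM. With the default pseudocount of 0,
#' if any denominator mean is exactly 0 the pseudocount falls back to half
#' the smallest positive denominator-group gene mean, so fold changes stay
#' finite.
#'
#' @param x An `ExpressionMatrix`.
#' @param genes Genes to rank (default all).
#' @param numerator_group,denominator_group Group labels.
#' @param pseudocount Added to both means (default 0 with automatic
#'   fallback).
#' @return Data frame sorted by descending fold change: `gene`,
#'   `mean_numerator`, `mean_denominator`, `fold_change`, `log2_fc`.
#' @export
rank_fold_change <- function(x, genes = gene_ids(x),
                             numerator_group = "D3",
                             denominator_group = "sham",
                             pseudocount = 0) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!all(c(numerator_group, denominator_group) %in% as.character(x$cell_groups)))
    stop("both groups must be present in the matrix")
  v <- x$values[, genes, drop = FALSE]
  m_num <- colMeans(v[x$cell_groups == numerator_group, , drop = FALSE])
  m_den <- colMeans(v[x$cell_groups == denominator_group, , drop = FALSE])
  pc <- pseudocount
  if (pc == 0 && any(m_den == 0)) {
    pos <- m_den[m_den > 0]
    pc <- if (length(pos) > 0) min(pos) / 2 else 0.5
    log_info("rank_fold_change: zero denominator mean; pseudocount -> %g", pc)
  }
  fc <- (m_num + pc) / (m_den + pc)
  out <- data.frame(gene = genes, mean_numerator = unname(m_num),
                    mean_denominator = unname(m_den),
                    fold_change = unname(fc), log2_fc = unname(log2(fc)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_change, out$gene), ]
  rownames(out) <- NULL
  out
}
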