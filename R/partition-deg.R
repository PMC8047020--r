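#' Split TAC cells into marker-high and marker-low subgroups
#'
#' The threshold is the mean marker RPKM over the cells in scope (default:
#' all TAC cells pooled); a cell is marker-high iff its marker expression is
#' strictly greater than the threshold, so an all-equal marker yields zero
#' high cells.
#'
#' @param x An `ExpressionMatrix`.
#' @param marker Marker gene id (e.g. the natriuretic peptide gene).
#' @param scope `"global"`: one threshold from all TAC cells;
#'   `"per_timepoint"`: a separate mean within each TAC time point.
#' @return A `MarkerPartition` list: `marker`, `threshold` (named vector for
#'   per-timepoint scope), `label` (named character, `high`/`low`, TAC cells
#'   only) and `counts` (data frame per time point: `group`, `n_high`,
#'   `n_low`).
#' @export
split_by_marker <- function(x, marker, scope = c("global", "per_timepoint")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  scope <- match.arg(scope)
  if (!marker %in% gene_ids(x)) stop("marker gene not present: ", marker)
  idx <- tac_cell_idx(x)
  if (length(idx) == 0) stop("no TAC cells in the matrix")
  expr <- x$values[idx, marker]
  grp <- factor(as.character(x$cell_groups)[idx], levels = tac_groups())
  if (scope == "global") {
    thr <- mean(expr)
    high <- expr > thr
  } else {
    thr <- tapply(expr, grp, mean)
    high <- expr > thr[as.character(grp)]
  }
  label <- stats::setNames(ifelse(high, "high", "low"), cell_ids(x)[idx])
  counts <- data.frame(group = tac_groups(),
                       n_high = as.vector(tapply(high, grp, sum, default = 0L)),
                       n_low = as.vector(tapply(!high, grp, sum, default = 0L)),
                       stringsAsFactors = FALSE)
  counts$n_high[is.na(counts$n_high)] <- 0L
  counts$n_low[is.na(counts$n_low)] <- 0L
  structure(list(marker = marker, scope = scope, threshold = thr,
                 label = label, counts = counts),
            class = "MarkerPartition")
}

#' @export
print.MarkerPartition <- function(x, ...) {
  cat("MarkerPartition on", x$marker, "(", x$scope, "threshold )\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Differential expression between a cell subgroup and a reference
#'
#' Per-gene unpaired equal-variance two-tailed t-test on log2(RPKM+1) (or
#' raw values), with the fold change computed from raw group means using a
#' pseudocount of 1. A gene is significant iff |log2FC| >= `lfc_threshold`
#' AND adjusted p < `alpha`.
#'
#' @param x An `ExpressionMatrix`.
#' @param group_cells,reference_cells Character vectors of cell ids (each
#'   >= 2 cells).
#' @param lfc_threshold Absolute log2 fold-change gate (default 1).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param correction `"BH"` (default) or `"none"`.
#' @param scale `"log2"` (test on log2(RPKM+1), default) or `"raw"`.
#' @return A `DegTable` data frame: `gene`, `log2_fc`, `t_statistic`,
#'   `p_value`, `adjusted_p`, `significant`.
#' @export
deg_test <- function(x, group_cells, reference_cells, lfc_threshold = 1,
                     alpha = 0.05, correction = c("BH", "none"),
                     scale = c("log2", "raw")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  correction <- match.arg(correction)
  scale <- match.arg(scale)
  if (length(group_cells) < 2 || length(reference_cells) < 2)
    stop("both groups need at least 2 cells")
  if (!all(c(group_cells, reference_cells) %in% cell_ids(x)))
    stop("unknown cell id(s) in group definitions")
  v1r <- x$values[group_cells, , drop = FALSE]
  v2r <- x$values[reference_cells, , drop = FALSE]
  v1 <- if (scale == "log2") log2(v1r + 1) else v1r
  v2 <- if (scale == "log2") log2(v2r + 1) else v2r
  n1 <- nrow(v1); n2 <- nrow(v2)
  m1 <- colMeans(v1); m2 <- colMeans(v2)
  s1 <- colSums(v1^2) - n1 * m1^2
  s2 <- colSums(v2^2) - n2 * m2^2
  sp2 <- pmax(s1 + s2, 0) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m1 - m2) / se, ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
  lfc <- log2((colMeans(v1r) + 1) / (colMeans(v2r) + 1))
  adj <- if (correction == "BH") stats::p.adjust(p, "BH") else p
  out <- data.frame(gene = gene_ids(x), log2_fc = unname(lfc),
                    t_statistic = unname(t), p_value = unname(p),
                    adjusted_p = unname(adj),
                    significant = unname(abs(lfc) >= lfc_threshold & adj < alpha),
                    stringsAsFactors = FALSE)
  class(out) <- c("DegTable", "data.frame")
  out
}

#' Partition DEGs into subgroup-specific and common sets
#'
#' @param deg_high,deg_low `DegTable`s over the same gene universe (e.g.
#'   marker-high vs sham and marker-low vs sham).
#' @return List of gene sets `high_only`, `low_only`, `common`, plus
#'   `counts` (named integer vector).
#' @export
common_degs <- function(deg_high, deg_low) {
  if (!setequal(deg_high$gene, deg_low$gene))
    stop("DEG tables cover different gene universes")
  h <- deg_high$gene[deg_high$significant]
  l <- deg_low$gene[deg_low$significant]
  out <- list(high_only = setdiff(h, l), low_only = setdiff(l, h),
              common = intersect(h, l))
  out$counts <- c(high_only = length(out$high_only),
                  low_only = length(out$low_only),
                  common = length(out$common))
  out
}

#' Hierarchical clustering of subgroup x time-point pseudo-samples
#'
#' Mean log2(RPKM+1) profiles are built for each (marker subgroup, TAC time
#' point) pair plus one sham profile, then clustered with average linkage
#' and Euclidean distance. Pseudo-samples with no cells are dropped with a
#' warning.
#'
#' @param x An `ExpressionMatrix`.
#' @param partition A `MarkerPartition` covering the matrix's TAC cells.
#' @param genes Genes used for the profiles (default all).
#' @param method,metric Linkage and distance (defaults average/Euclidean).
#' @return List with `hclust` (tree over pseudo-samples), `profiles`
#'   (samples x genes matrix).
#' @export
hcluster_samples <- function(x, partition, genes = gene_ids(x),
                             method = "average", metric = "euclidean") {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(partition, "MarkerPartition"))
  v <- log2(x$values[, genes, drop = FALSE] + 1)
  grp <- as.character(x$cell_groups)
  samples <- list(sham = which(grp == "sham"))
  for (tp in tac_groups()) {
    for (lab in c("high", "low")) {
      ids <- names(partition$label)[partition$label == lab]
      idx <- which(grp == tp & cell_ids(x) %in% ids)
      nm <- paste0(tp, "_", lab)
      if (length(idx) == 0) {
        warning("no cells for pseudo-sample ", nm, "; dropped")
      } else samples[[nm]] <- idx
    }
  }
  prof <- t(vapply(samples, function(idx) colMeans(v[idx, , drop = FALSE]),
                   numeric(ncol(v))))
  hc <- stats::hclust(stats::dist(prof, method = metric), method = method)
  list(hclust = hc, profiles = prof)
}
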