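#' Pearson correlation of every gene with a marker gene
#'
#' Per-gene Pearson correlation of log2(RPKM+1) (or raw values) against the
#' marker over a chosen cell subset — by default the day-3 TAC cells.
#' Zero-variance genes are excluded and reported.
#'
#' @param x An `ExpressionMatrix`.
#' @param marker Marker gene id.
#' @param cells_subset Cell ids to use (default: all D3 cells). Needs >= 3
#'   cells and a non-constant marker.
#' @param scale `"log2"` (default) or `"raw"`.
#' @return A `CorrelationTable` data frame sorted by descending r: `gene`,
#'   `r`, `n_cells`; attribute `excluded` lists zero-variance genes.
#' @export
marker_correlation <- function(x, marker,
                               cells_subset = cell_ids(x)[x$cell_groups == "D3"],
                               scale = c("log2", "raw")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  scale <- match.arg(scale)
  if (!marker %in% gene_ids(x)) stop("marker gene not present: ", marker)
  if (length(cells_subset) < 3) stop("need at least 3 cells in the subset")
  if (!all(cells_subset %in% cell_ids(x))) stop("unknown cell id(s) in subset")
  v <- x$values[cells_subset, , drop = FALSE]
  if (scale == "log2") v <- log2(v + 1)
  mk <- v[, marker]
  if (stats::sd(mk) == 0) stop("marker is constant on the chosen subset")
  sds <- apply(v, 2, stats::sd)
  ok <- sds > 0
  r <- suppressWarnings(as.vector(stats::cor(mk, v[, ok, drop = FALSE])))
  excluded <- colnames(v)[!ok]
  if (length(excluded) > 0)
    log_info("marker_correlation: excluded %d zero-variance gene(s)",
             length(excluded))
  out <- data.frame(gene = colnames(v)[ok], r = r,
                    n_cells = length(cells_subset), stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$gene), ]
  rownames(out) <- NULL
  attr(out, "marker") <- marker
  attr(out, "excluded") <- excluded
  class(out) <- c("CorrelationTable", "data.frame")
  out
}

#' Top positively or negatively marker-correlated genes
#'
#' @param table A `CorrelationTable` from [marker_correlation()].
#' @param n Number of genes requested; if fewer are available the list is
#'   truncated with a warning.
#' @param sign `"positive"` (largest r first) or `"negative"` (most
#'   negative r first). Ties broken by gene id; the marker itself is
#'   excluded.
#' @return Character vector of gene ids.
#' @export
top_correlated <- function(table, n, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (nrow(table) == 0) stop("empty correlation table")
  tab <- table[table$gene != attr(table, "marker") %||% "", , drop = FALSE]
  ord <- if (sign == "positive") order(-tab$r, tab$gene) else order(tab$r, tab$gene)
  if (n > nrow(tab)) {
    warning("requested ", n, " genes but only ", nrow(tab), " available")
    n <- nrow(tab)
  }
  tab$gene[ord][seq_len(n)]
}
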