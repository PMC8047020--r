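#' Read an expression matrix with per-cell group labels
#'
#' Two interchange layouts are supported. `format = "tsv"` expects a single
#' tab-separated file whose first two columns are `cell_id` and `group`,
#' followed by one column per gene. `format = "mtx"` expects a MatrixMarket
#' file of cells x genes values plus two sidecar tables: `cell_file`
#' (tab-separated, columns `cell_id`, `group`) and `gene_file` (one column
#' `gene_id`).
#'
#' @param path Path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`.
#' @param cell_file,gene_file Sidecar metadata paths (MTX layout only).
#' @return A validated [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            cell_file = NULL, gene_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    if (length(hdr) < 3 || !identical(hdr[1:2], c("cell_id", "group")))
      stop("malformed expression TSV header: expected columns cell_id, group, <genes...>")
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    vals <- as.matrix(dt[, -(1:2), drop = FALSE])
    if (!is.numeric(vals)) stop("malformed expression TSV: non-numeric gene columns")
    rownames(vals) <- as.character(dt$cell_id)
    colnames(vals) <- hdr[-(1:2)]   # fread silently renames duplicates
    if (anyNA(dt$group) || any(dt$group == ""))
      stop("metadata error: unlabeled cell(s) in expression TSV")
    em <- expression_matrix(vals, dt$group)
  } else {
    if (is.null(cell_file) || is.null(gene_file))
      stop("mtx format requires `cell_file` and `gene_file` sidecars")
    m <- as.matrix(Matrix::readMM(path))
    cells <- utils::read.delim(cell_file, stringsAsFactors = FALSE)
    genes <- utils::read.delim(gene_file, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "group") %in% colnames(cells)))
      stop("cell sidecar must have columns cell_id, group")
    if (!"gene_id" %in% colnames(genes))
      stop("gene sidecar must have a gene_id column")
    if (nrow(m) != nrow(cells) || ncol(m) != nrow(genes))
      stop("MTX dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecar tables")
    if (anyNA(cells$group) || any(cells$group == ""))
      stop("metadata error: unlabeled cell(s) in cell sidecar")
    dimnames(m) <- list(as.character(cells$cell_id), as.character(genes$gene_id))
    em <- expression_matrix(m, cells$group)
  }
  log_info("read_expression: %d cells x %d genes from %s",
           nrow(em$values), ncol(em$values), path)
  em
}

#' Write an expression matrix
#'
#' The TSV layout round-trips exactly: values are written with 17 significant
#' digits so `read_expression()` recovers them bit-for-bit.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path (TSV) or MTX path.
#' @param format `"tsv"` or `"mtx"`.
#' @param cell_file,gene_file Sidecar paths (MTX layout only).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx"),
                             cell_file = NULL, gene_file = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (format == "tsv") {
    chr <- matrix(formatC(x$values, digits = 17, format = "g"),
                  nrow = nrow(x$values))
    header <- paste(c("cell_id", "group", colnames(x$values)), collapse = "\t")
    body <- paste(cell_ids(x), as.character(x$cell_groups),
                  apply(chr, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
  } else {
    if (is.null(cell_file) || is.null(gene_file))
      stop("mtx format requires `cell_file` and `gene_file` sidecars")
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    utils::write.table(
      data.frame(cell_id = cell_ids(x), group = as.character(x$cell_groups)),
      cell_file, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = gene_ids(x)),
                       gene_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read strand-resolved transcription start sites from a refFlat file
#'
#' refFlat columns are geneName, name, chrom, strand, txStart, txEnd, ...
#' (0-based coordinates as stored). The TSS is `txStart` for + strand
#' transcripts and `txEnd` for - strand transcripts. Transcripts of the same
#' gene sharing (chrom, strand, tss) collapse to one record.
#'
#' @param path Path to an uncompressed refFlat file (no header).
#' @return Data frame with columns `gene`, `chrom`, `strand`, `tss`
#'   (0-based), class `TssAnnotation`.
#' @export
read_refflat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rf <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(rf) < 6) stop("refFlat file must have at least 6 columns")
  strand <- rf[[4]]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop("unknown strand symbol '", strand[bad[1]], "' at line ", bad[1])
  tss <- ifelse(strand == "+", rf[[5]], rf[[6]])
  ann <- data.frame(gene = rf[[1]], chrom = rf[[3]], strand = strand,
                    tss = as.integer(tss), stringsAsFactors = FALSE)
  n0 <- nrow(ann)
  ann <- unique(ann)
  if (any(ann$tss < 0)) stop("negative TSS coordinate")
  rownames(ann) <- NULL
  class(ann) <- c("TssAnnotation", "data.frame")
  log_info("read_refflat: %d transcripts -> %d unique TSS records", n0, nrow(ann))
  ann
}

#' Write a TSS annotation back out in refFlat layout
#'
#' Emits one synthetic transcript per record (transcript name derived from
#' the gene symbol; a 1 kb body downstream of the TSS) so that
#' `read_refflat()` recovers the same (gene, chrom, strand, tss) records.
#'
#' @param ann A `TssAnnotation` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(ann, path) {
  tx_start <- ifelse(ann$strand == "+", ann$tss, pmax(ann$tss - 1000L, 0L))
  tx_end <- ifelse(ann$strand == "+", ann$tss + 1000L, ann$tss)
  df <- data.frame(ann$gene, paste0("TX_", seq_len(nrow(ann))), ann$chrom,
                   ann$strand, tx_start, tx_end, tx_start, tx_end, 1L,
                   paste0(tx_start, ","), paste0(tx_end, ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-TF ChIP-seq peak set from a BED file
#'
#' BED5 or wider; column 5 carries the MACS2 score, -10*log10 of the peak
#' Q-value. Intervals are 0-based half-open as in standard BED.
#'
#' @param path Path to an uncompressed BED file.
#' @param tf_name Transcription factor name to attach to the peak set.
#' @return A `PeakSet`: list with `tf_name` and data frame `peaks`
#'   (`chrom`, `start`, `end`, `score`).
#' @export
read_peaks_bed <- function(path, tf_name) {
  if (!file.exists(path)) stop("no such file: ", path)
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 5) stop("BED file must have at least 5 columns (BED5)")
  start <- as.integer(bed[[2]]); end <- as.integer(bed[[3]])
  score <- as.numeric(bed[[5]])
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop("invalid interval (start >= end) at line ", bad[1])
  if (any(score < 0)) stop("negative peak score")
  ps <- structure(list(tf_name = tf_name,
                       peaks = data.frame(chrom = bed[[1]], start = start,
                                          end = end, score = score,
                                          stringsAsFactors = FALSE)),
                  class = "PeakSet")
  log_info("read_peaks_bed: %d peaks for %s", nrow(ps$peaks), tf_name)
  ps
}

#' Write a peak set as BED5
#' @param ps A `PeakSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(ps, path) {
  df <- data.frame(ps$peaks$chrom, ps$peaks$start, ps$peaks$end,
                   paste0(ps$tf_name, "_p", seq_len(nrow(ps$peaks))),
                   ps$peaks$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-gene association edge list (STRING dialect)
#'
#' Whitespace- or tab-separated columns `protein1 protein2 combined_score`
#' (a header line with those names is skipped). Self-loops are dropped and
#' duplicate undirected pairs collapse keeping the maximum score.
#'
#' @param path Path to the edge list.
#' @param score_min Minimum combined score to keep (default 0: keep all).
#' @return Data frame `gene_a`, `gene_b`, `score`, class `EdgeList`.
#' @export
read_edges <- function(path, score_min = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 3) stop("edge list must have 3 columns")
  # skip a STRING-style header line, but only when it names the score column
  if (nrow(dt) >= 1 && is.na(suppressWarnings(as.numeric(dt[1, 3]))) &&
      grepl("score", tolower(as.character(dt[1, 3]))))
    dt <- dt[-1, , drop = FALSE]
  sc <- suppressWarnings(as.numeric(dt[[3]]))
  if (anyNA(sc)) stop("non-numeric combined score at line ", which(is.na(sc))[1])
  a <- as.character(dt[[1]]); b <- as.character(dt[[2]])
  n0 <- length(a)
  keep <- sc >= score_min & a != b
  a <- a[keep]; b <- b[keep]; sc <- sc[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key, -sc)
  first <- !duplicated(key[ord])
  el <- data.frame(gene_a = lo[ord][first], gene_b = hi[ord][first],
                   score = sc[ord][first], stringsAsFactors = FALSE)
  rownames(el) <- NULL
  class(el) <- c("EdgeList", "data.frame")
  log_info("read_edges: %d rows -> %d edges (dropped %d)", n0, nrow(el),
           n0 - nrow(el))
  el
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member gene symbols.
#'
#' @param path Path to a GMT file.
#' @return A `GeneSetCollection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names_))
    stop("duplicate set name: ", names_[duplicated(names_)][1])
  descs <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  empty <- lengths(sets) == 0
  if (any(empty)) stop("empty gene set: ", names_[empty][1])
  names(sets) <- names_
  structure(sets, descriptions = stats::setNames(descs, names_),
            class = "GeneSetCollection")
}

#' Write a GMT gene-set collection
#' @param sets A `GeneSetCollection` (or named list of character vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, descs[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Write an edge list as STRING-style TSV
#' @param el An `EdgeList`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(el, path) {
  utils::write.table(
    data.frame(protein1 = el$gene_a, protein2 = el$gene_b,
               combined_score = el$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
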