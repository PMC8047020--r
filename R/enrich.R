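#' Map TF peak sets to bound genes via TSS windows
#'
#' A gene is bound by a TF iff some peak of that TF with score >=
#' `score_min` overlaps the closed window [tss - window, tss + window]
#' around the gene's strand-resolved TSS. Peaks are 0-based half-open (BED);
#' the window is closed in 0-based coordinates. Overlap means a non-empty
#' intersection of the covered base positions.
#'
#' @param peak_sets List of `PeakSet`s (see [read_peaks_bed()]).
#' @param tss A `TssAnnotation`.
#' @param window Half-width of the promoter window in bp (default 5000).
#' @param score_min Minimum MACS2 score, -10*log10(Q), inclusive
#'   (default 100).
#' @return Named list, TF name -> character vector of bound gene symbols.
#' @export
assign_peaks_to_genes <- function(peak_sets, tss, window = 5000,
                                  score_min = 100) {
  stopifnot(inherits(tss, "TssAnnotation"))
  if (nrow(tss) == 0) stop("empty TSS annotation")
  if (window <= 0) stop("window must be positive")
  # windows: 0-based closed [tss-w, tss+w] -> 1-based [tss-w+1, tss+w+1]
  win <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(start = pmax(tss$tss - window, 0) + 1,
                     end = tss$tss + window + 1))
  out <- lapply(peak_sets, function(ps) {
    pk <- ps$peaks[ps$peaks$score >= score_min, , drop = FALSE]
    if (nrow(pk) == 0) return(character(0))
    # peaks: 0-based half-open [start, end) -> 1-based [start+1, end]
    gr <- GenomicRanges::GRanges(
      pk$chrom, IRanges::IRanges(start = pk$start + 1, end = pk$end))
    hits <- GenomicRanges::findOverlaps(gr, win)
    sort(unique(tss$gene[S4Vectors::subjectHits(hits)]))
  })
  stats::setNames(out, vapply(peak_sets, `[[`, character(1), "tf_name"))
}

#' Build the 2x2 contingency table for TF binding enrichment
#'
#' a = query genes bound, b = query genes not bound, c = background genes
#' bound, d = background genes not bound; n = a+b+c+d.
#'
#' @param query_genes,background_genes Disjoint non-empty gene sets.
#' @param bound_set Genes bound by the TF.
#' @return A `ContingencyTable` list `a`, `b`, `c`, `d`, `n`.
#' @export
build_contingency <- function(query_genes, background_genes, bound_set) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  if (length(query_genes) == 0 || length(background_genes) == 0)
    stop("query and background must be non-empty")
  if (length(intersect(query_genes, background_genes)) > 0)
    stop("query and background genes must be disjoint")
  a <- sum(query_genes %in% bound_set)
  c_ <- sum(background_genes %in% bound_set)
  tab <- list(a = a, b = length(query_genes) - a,
              c = c_, d = length(background_genes) - c_)
  tab$n <- tab$a + tab$b + tab$c + tab$d
  structure(tab, class = "ContingencyTable")
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' The point probability of a table with fixed margins is the
#' hypergeometric term (a+b)!(c+d)!(a+c)!(b+d)! / (n! a! b! c! d!),
#' evaluated in log-factorial space. The two-tailed p-value sums the point
#' probabilities of every table with the same margins whose probability
#' does not exceed that of the observed table (within relative tolerance
#' 1e-7).
#'
#' @param table A `ContingencyTable` (or list with fields `a`,`b`,`c`,`d`).
#' @return The two-tailed p-value in (0, 1].
#' @export
fisher_two_tailed <- function(table) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  n <- r1 + r2
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  logp <- lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) +
    lgamma(n - c1 + 1) - lgamma(n + 1) -
    (lgamma(x + 1) + lgamma(r1 - x + 1) + lgamma(c1 - x + 1) +
       lgamma(r2 - c1 + x + 1))
  p_obs <- logp[x == a]
  min(sum(exp(logp[logp <= p_obs + log1p(1e-7)])), 1)
}

#' Transcription factor enrichment over a query gene list
#'
#' For each TF, genes bound near TSSs are determined via
#' [assign_peaks_to_genes()], a 2x2 table of query vs background binding is
#' built, and a two-tailed Fisher's exact p-value computed. TFs are ranked
#' by -log10 p. The background is a seeded random sample of non-query
#' annotated genes of the same size as the query (`background = "random"`),
#' or all non-query annotated genes (`"all"`).
#'
#' @param query_genes Character vector of query gene symbols.
#' @param tss A `TssAnnotation` (its genes define the sampling universe).
#' @param peak_sets List of `PeakSet`s.
#' @param background `"random"` (default) or `"all"`.
#' @param alpha Significance level on the raw p (default 0.05).
#' @param seed Integer seed for the background draw.
#' @param window,score_min Passed to [assign_peaks_to_genes()].
#' @param correction `"none"` (default, raw p at alpha) or `"BH"`.
#' @return Data frame ranked by decreasing -log10 p: `tf`, `a`, `b`, `c`,
#'   `d`, `p`, `neg_log10_p`, `significant`.
#' @export
tf_enrichment <- function(query_genes, tss, peak_sets,
                          background = c("random", "all"), alpha = 0.05,
                          seed = 1L, window = 5000, score_min = 100,
                          correction = c("none", "BH")) {
  background <- match.arg(background)
  correction <- match.arg(correction)
  if (length(peak_sets) == 0) stop("no peak sets supplied")
  query_genes <- unique(query_genes)
  universe <- unique(tss$gene)
  pool <- setdiff(universe, query_genes)
  bg <- if (background == "random") {
    if (length(pool) < length(query_genes))
      stop("background pool smaller than the query (", length(pool), " < ",
           length(query_genes), ")")
    with_rng_seed(seed, sample(pool, length(query_genes)))
  } else pool
  bound <- assign_peaks_to_genes(peak_sets, tss, window = window,
                                 score_min = score_min)
  rows <- lapply(names(bound), function(tf) {
    tab <- build_contingency(query_genes, bg, bound[[tf]])
    p <- fisher_two_tailed(tab)
    data.frame(tf = tf, a = tab$a, b = tab$b, c = tab$c, d = tab$d, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$neg_log10_p <- -log10(out$p)
  adj <- if (correction == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- adj < alpha
  out <- out[order(-out$neg_log10_p, out$tf), ]
  rownames(out) <- NULL
  out
}

#' Gene-set overrepresentation analysis
#'
#' For each named set, a two-tailed Fisher's exact test of the query against
#' the rest of the universe (hypergeometric overrepresentation), with
#' Benjamini-Hochberg adjustment across sets. Sets disjoint from the
#' universe are skipped with a warning.
#'
#' @param query_genes Character vector, a subset of `universe`.
#' @param sets A `GeneSetCollection` (or named list of character vectors).
#' @param universe Character vector of all considered genes.
#' @return Data frame ranked by increasing p: `set`, `overlap`, `set_size`,
#'   `p`, `adjusted_p`.
#' @export
gene_set_ora <- function(query_genes, sets, universe) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (!all(query_genes %in% universe))
    stop("query genes must be a subset of the universe")
  bg <- setdiff(universe, query_genes)
  keep <- vapply(sets, function(s) length(intersect(s, universe)) > 0, logical(1))
  if (any(!keep))
    warning("skipping ", sum(!keep), " set(s) disjoint from the universe")
  sets <- sets[keep]
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    tab <- build_contingency(query_genes, bg, s)
    data.frame(set = nm, overlap = tab$a, set_size = length(s),
               p = fisher_two_tailed(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), p = numeric(0),
                      adjusted_p = numeric(0)))
  out$adjusted_p <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
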