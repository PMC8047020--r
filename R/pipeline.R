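#' Build a pipeline configuration
#'
#' Collects the input paths and stage parameters for [run_pipeline()].
#' Stages read the files produced by earlier stages, so a change to any
#' parameter invalidates that stage's cache and everything downstream.
#'
#' @param expression Path to the expression TSV (see [read_expression()]).
#' @param refflat Path to the refFlat annotation.
#' @param peaks_dir Directory of per-TF BED files (`<TF>.bed`).
#' @param edges Path to the gene-gene association edge list.
#' @param outdir Output directory (created if missing).
#' @param gmt Optional GMT file for module annotation.
#' @param marker Marker gene id; `NULL` picks the top fold-change gene of
#'   the rapidly-upregulated cluster.
#' @param min_genes,rpkm_floor QC parameters.
#' @param alpha,correction ANOVA screen parameters.
#' @param k Cluster count for the gene dendrogram cut.
#' @param lfc_threshold DEG fold-change gate.
#' @param n_corr_network Genes fed to the network stage (most negatively
#'   marker-correlated; default 500).
#' @param n_corr_enrich Genes fed to TF enrichment (default 1000).
#' @param window,score_min TSS window and MACS2 score gate.
#' @param edge_score_min Combined-score filter on the association edges.
#' @param seed Global seed; per-stage seeds derive from it by stable
#'   hashing of stage names.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(expression, refflat, peaks_dir, edges, outdir,
                            gmt = NULL, marker = NULL,
                            min_genes = 5000, rpkm_floor = 0.1,
                            alpha = 0.05, correction = "none", k = 6,
                            lfc_threshold = 1, n_corr_network = 500,
                            n_corr_enrich = 1000, window = 5000,
                            score_min = 100, edge_score_min = 0, seed = 1L) {
  for (p in c(expression, refflat, peaks_dir, edges, gmt))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(as.list(environment()), class = "PipelineConfig")
}

stage_params <- function(config, stage) {
  switch(stage,
    qc = config[c("min_genes", "rpkm_floor")],
    screen = config[c("alpha", "correction")],
    cluster = config["k"],
    rankfc = config["marker"],
    split = config["marker"],
    deg = config[c("lfc_threshold", "alpha")],
    correlate = config["n_corr_network"],
    modules = config["edge_score_min"],
    tfenrich = config[c("n_corr_enrich", "window", "score_min", "seed")])
}

stage_inputs <- function(config, stage, out) {
  f <- function(...) file.path(config$outdir, ...)
  switch(stage,
    qc = config$expression,
    screen = f("expression_qc.tsv"),
    cluster = c(f("expression_qc.tsv"), f("screen.tsv")),
    rankfc = c(f("expression_qc.tsv"), f("clusters.tsv")),
    split = c(f("expression_qc.tsv"), f("fold_change.tsv")),
    deg = c(f("expression_qc.tsv"), f("partition.tsv")),
    correlate = c(f("expression_qc.tsv"), f("partition.tsv")),
    modules = c(f("top_negative.txt"), config$edges),
    tfenrich = c(f("top_negative.txt"), config$refflat,
                 list.files(config$peaks_dir, "\\.bed$", full.names = TRUE)))
}

stage_outputs <- function(config, stage) {
  f <- function(...) file.path(config$outdir, ...)
  switch(stage,
    qc = f("expression_qc.tsv"),
    screen = f("screen.tsv"),
    cluster = c(f("clusters.tsv"), f("sse.tsv")),
    rankfc = f("fold_change.tsv"),
    split = c(f("partition.tsv"), f("split_counts.json")),
    deg = c(f("deg_high.tsv"), f("deg_low.tsv"), f("deg_summary.json")),
    correlate = c(f("correlation.tsv"), f("top_negative.txt")),
    modules = f("modules.tsv"),
    tfenrich = f("tf_enrichment.tsv"))
}

# A stage may be skipped iff a prior manifest records it with identical
# parameters and input hashes, and its outputs still exist.
stage_cache <- function(config, stage, manifest) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  ins <- stage_inputs(config, stage)
  outs <- stage_outputs(config, stage)
  if (!all(file.exists(c(ins, outs)))) return(FALSE)
  cur <- unname(tools::md5sum(ins))
  canon <- function(x) as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                     digits = NA, null = "null"))
  identical(unname(unlist(rec$input_md5)), cur) &&
    identical(canon(rec$params),
              canon(lapply(stage_params(config, stage),
                           function(v) if (is.null(v)) NA else v)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full trans-omics pipeline
#'
#' Executes qc -> screen -> cluster -> rankfc -> split -> deg -> correlate
#' -> modules -> tfenrich, writing each stage's tables under
#' `config$outdir` plus a `manifest.json` recording parameters, derived
#' seeds, input hashes and record counts. With `cache = TRUE`, stages whose
#' inputs and parameters are unchanged since the recorded run are skipped.
#'
#' @param config A [pipeline_config()].
#' @param cache Reuse unchanged stage outputs from a previous run
#'   (default TRUE).
#' @return The manifest, invisibly (list with per-stage records).
#' @export
run_pipeline <- function(config, cache = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$outdir, "manifest.json")
  prev <- if (cache && file.exists(manifest_path))
    tryCatch(jsonlite::read_json(manifest_path),
             error = function(e) {
               warning("corrupted manifest; recomputing all stages")
               list(stages = list())
             })
  else list(stages = list())
  manifest <- list(seed = config$seed, stages = list())
  f <- function(...) file.path(config$outdir, ...)
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, compute) {
    skipped <- stage_cache(config, stage, prev)
    if (!skipped) {
      log_info("pipeline: running stage %s", stage)
      tryCatch(compute(), error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    } else log_info("pipeline: stage %s cached, skipped", stage)
    manifest$stages[[stage]] <<- list(
      skipped = skipped,
      params = lapply(stage_params(config, stage),
                      function(v) if (is.null(v)) NA else v),
      seed = derive_seed(config$seed, stage),
      input_md5 = as.list(unname(tools::md5sum(stage_inputs(config, stage)))),
      outputs = as.list(stage_outputs(config, stage)))
  }

  run_stage("qc", function() {
    em <- read_expression(config$expression)
    em <- qc_filter_cells(em, config$min_genes, config$rpkm_floor)
    write_expression(em, f("expression_qc.tsv"))
  })
  em <- read_expression(f("expression_qc.tsv"))

  run_stage("screen", function() {
    scr <- anova_screen(em, alpha = config$alpha,
                        correction = config$correction, transform = "log2")
    write_tsv(scr, f("screen.tsv"))
  })
  scr <- utils::read.delim(f("screen.tsv"), stringsAsFactors = FALSE)
  sig_genes <- scr$gene[scr$significant]
  if (length(sig_genes) < 2)
    stop("stage 'screen' left fewer than 2 significant genes")

  run_stage("cluster", function() {
    prof <- profile_matrix(em, sig_genes)
    ca <- hcluster_genes(prof, k = config$k)
    sse <- sse_select_k(prof, k_range = seq_len(min(10, nrow(prof))))
    write_tsv(data.frame(gene = names(ca$cluster), cluster = ca$cluster),
              f("clusters.tsv"))
    write_tsv(sse$curve, f("sse.tsv"))
  })
  cl <- utils::read.delim(f("clusters.tsv"), stringsAsFactors = FALSE)

  run_stage("rankfc", function() {
    # the rapidly-upregulated cluster: lowest sham centroid z-score
    prof <- profile_matrix(em, cl$gene)
    cent <- rowsum(prof, cl$cluster) / tabulate(cl$cluster)
    up_cluster <- which.min(cent[, "sham"])
    fc <- rank_fold_change(em, cl$gene[cl$cluster == up_cluster],
                           numerator_group = "D3", denominator_group = "sham")
    write_tsv(fc, f("fold_change.tsv"))
  })
  fc <- utils::read.delim(f("fold_change.tsv"), stringsAsFactors = FALSE)
  marker <- config$marker %||% fc$gene[1]

  run_stage("split", function() {
    part <- split_by_marker(em, marker)
    write_tsv(data.frame(cell_id = names(part$label), label = part$label),
              f("partition.tsv"))
    jsonlite::write_json(
      list(marker = marker, threshold = part$threshold, counts = part$counts),
      f("split_counts.json"), auto_unbox = TRUE, digits = NA)
  })
  part_df <- utils::read.delim(f("partition.tsv"), stringsAsFactors = FALSE)
  sham_cells <- cell_ids(em)[em$cell_groups == "sham"]
  high_cells <- part_df$cell_id[part_df$label == "high"]
  low_cells <- part_df$cell_id[part_df$label == "low"]

  run_stage("deg", function() {
    dh <- deg_test(em, high_cells, sham_cells, config$lfc_threshold,
                   config$alpha)
    dl <- deg_test(em, low_cells, sham_cells, config$lfc_threshold,
                   config$alpha)
    cmn <- common_degs(dh, dl)
    write_tsv(dh, f("deg_high.tsv"))
    write_tsv(dl, f("deg_low.tsv"))
    jsonlite::write_json(as.list(cmn$counts), f("deg_summary.json"),
                         auto_unbox = TRUE)
  })

  run_stage("correlate", function() {
    ct <- marker_correlation(em, marker)
    neg <- top_correlated(ct, min(config$n_corr_network, nrow(ct) - 1),
                          "negative")
    write_tsv(ct, f("correlation.tsv"))
    writeLines(neg, f("top_negative.txt"))
  })
  neg_genes <- readLines(f("top_negative.txt"))

  run_stage("modules", function() {
    el <- read_edges(config$edges, score_min = config$edge_score_min)
    g <- induce_subgraph(el, neg_genes)
    mods <- mcode(g)
    df <- if (length(mods) == 0)
      data.frame(rank = integer(0), gene = character(0), score = numeric(0))
    else do.call(rbind, lapply(mods, function(m)
      data.frame(rank = m$rank, gene = m$members, score = m$score)))
    write_tsv(df, f("modules.tsv"))
  })

  run_stage("tfenrich", function() {
    tss <- read_refflat(config$refflat)
    bed_files <- list.files(config$peaks_dir, "\\.bed$", full.names = TRUE)
    if (length(bed_files) == 0)
      stop("no BED files found in ", config$peaks_dir)
    peak_sets <- lapply(bed_files, function(b)
      read_peaks_bed(b, sub("\\.bed$", "", basename(b))))
    ct <- utils::read.delim(f("correlation.tsv"), stringsAsFactors = FALSE)
    attr(ct, "marker") <- marker
    class(ct) <- c("CorrelationTable", "data.frame")
    query <- top_correlated(ct, min(config$n_corr_enrich, nrow(ct) - 1),
                            "negative")
    query <- intersect(query, tss$gene)
    if (length(query) == 0)
      stop("no query genes present in the annotation")
    res <- tf_enrichment(query, tss, peak_sets, window = config$window,
                         score_min = config$score_min,
                         seed = derive_seed(config$seed, "tfenrich"))
    write_tsv(res, f("tf_enrichment.tsv"))
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
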