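#' Configuration for the synthetic time-course generator
#'
#' Defaults mirror the study design: six groups (sham plus five post-TAC
#' time points) with 88/69/83/82/73/87 cells, a log-normal RPKM noise model
#' on the log2(RPKM+1) scale with independent per-gene dropout, a planted
#' rapidly-upregulated gene program ("cluster 1"), a bimodal marker gene
#' splitting TAC cells into latent high/low states, and gene programs
#' co-elevated / co-suppressed specifically in marker-high cells.
#'
#' @param n_genes Total number of genes (default 20000; tests may use fewer).
#' @param cells_per_group Integer vector of six cell counts, one per group
#'   in `timecourse_groups()` order.
#' @param marker_name Name given to the planted marker gene.
#' @param marker_high_fraction Probability a TAC cell is latently
#'   marker-high (default 0.35).
#' @param marker_effect Multiplicative induction factor (>= 1) applied to
#'   cluster-1 genes in TAC cells, to the marker in marker-high cells, and
#'   to the correlated programs. `marker_effect = 1` is the null model.
#' @param n_cluster1_genes,n_pos_corr,n_neg_corr Sizes of the planted
#'   programs.
#' @param dropout_rate Probability any value is zeroed (default 0.2).
#' @param noise_sd Cell-to-cell standard deviation on the log2(RPKM+1)
#'   scale (default 1).
#' @param seed Integer RNG seed; identical config + seed reproduces the
#'   matrix exactly.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(n_genes = 20000,
                       cells_per_group = c(88L, 69L, 83L, 82L, 73L, 87L),
                       marker_name = "MarkerA",
                       marker_high_fraction = 0.35,
                       marker_effect = 8,
                       n_cluster1_genes = 100,
                       n_pos_corr = 100,
                       n_neg_corr = 100,
                       dropout_rate = 0.2,
                       noise_sd = 1,
                       seed = 1L) {
  if (length(cells_per_group) != 6)
    stop("config error: cells_per_group must have six entries (",
         paste(timecourse_groups(), collapse = ", "), ")")
  if (any(cells_per_group < 1) || n_genes < 1 || n_cluster1_genes < 0 ||
      n_pos_corr < 0 || n_neg_corr < 0)
    stop("config error: counts must be positive")
  if (marker_high_fraction <= 0 || marker_high_fraction >= 1)
    stop("config error: marker_high_fraction must be in (0,1)")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("config error: dropout_rate must be in [0,1)")
  if (marker_effect < 1) stop("config error: marker_effect must be >= 1")
  if (noise_sd <= 0) stop("config error: noise_sd must be positive")
  needed <- 1 + n_cluster1_genes + n_pos_corr + n_neg_corr
  if (n_genes < needed)
    stop("config error: n_genes too small for the planted programs (need >= ",
         needed, ")")
  structure(list(n_genes = as.integer(n_genes),
                 cells_per_group = as.integer(cells_per_group),
                 marker_name = marker_name,
                 marker_high_fraction = marker_high_fraction,
                 marker_effect = marker_effect,
                 n_cluster1_genes = as.integer(n_cluster1_genes),
                 n_pos_corr = as.integer(n_pos_corr),
                 n_neg_corr = as.integer(n_neg_corr),
                 dropout_rate = dropout_rate,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a time-course single-cell expression matrix
#'
#' Baseline genes follow a log-normal model: log2(RPKM+1) = mu_g + noise,
#' truncated at zero, with independent dropout. Planted cluster-1 genes gain
#' log2(marker_effect) in every TAC group. The marker gene is bimodal within
#' TAC groups: a latent fraction of cells carries the induction, the rest
#' stay at baseline. Positively correlated program genes gain the induction
#' only in marker-high cells; negatively correlated program genes lose it
#' there.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`, a list
#'   recording `gene_roles` (named character: baseline / cluster1 / marker /
#'   pos_corr / neg_corr), `cell_state` (named character: high / low / sham)
#'   and the config used.
#' @export
simulate_timecourse <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_rng_seed(config$seed, {
    groups <- rep(timecourse_groups(), times = config$cells_per_group)
    n_cells <- length(groups)
    cell_id <- sprintf("cell_%03d", seq_len(n_cells))
    is_tac <- groups != "sham"

    roles <- rep("baseline", config$n_genes)
    roles[1] <- "marker"
    i <- 2L
    roles[seq_len(config$n_cluster1_genes) + i - 1L] <- "cluster1"
    i <- i + config$n_cluster1_genes
    roles[seq_len(config$n_pos_corr) + i - 1L] <- "pos_corr"
    i <- i + config$n_pos_corr
    roles[seq_len(config$n_neg_corr) + i - 1L] <- "neg_corr"
    gene_id <- sprintf("gene_%05d", seq_len(config$n_genes))
    gene_id[1] <- config$marker_name

    # latent marker state: Bernoulli(marker_high_fraction) for TAC cells
    state <- ifelse(is_tac,
                    ifelse(stats::runif(n_cells) < config$marker_high_fraction,
                           "high", "low"),
                    "sham")

    mu <- stats::runif(config$n_genes, min = 0.5, max = 6)  # baseline log2 level
    eff <- log2(config$marker_effect)

    # per-cell per-gene shift from the planted programs
    shift <- matrix(0, n_cells, config$n_genes)
    shift[is_tac, roles == "cluster1"] <- eff
    shift[state == "high", roles == "marker"] <- eff
    shift[state == "high", roles == "pos_corr"] <- eff
    shift[state == "high", roles == "neg_corr"] <- -eff

    logx <- matrix(mu, n_cells, config$n_genes, byrow = TRUE) + shift +
      matrix(stats::rnorm(n_cells * config$n_genes, sd = config$noise_sd),
             n_cells, config$n_genes)
    vals <- pmax(2^logx - 1, 0)
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n_cells * config$n_genes) < config$dropout_rate,
                     n_cells, config$n_genes)
      vals[drop] <- 0
    }
    dimnames(vals) <- list(cell_id, gene_id)
    em <- expression_matrix(vals, groups)
    list(matrix = em,
         truth = list(gene_roles = stats::setNames(roles, gene_id),
                      cell_state = stats::setNames(state, cell_id),
                      config = config))
  })
}

#' Simulate per-TF ChIP-seq peak sets around gene TSSs
#'
#' One designated "true" TF places score->=100 peaks inside the +/- `window`
#' bp promoter of each target gene with probability `frac_targets_bound` and
#' near background TSSs with probability `frac_background_bound`; decoy TFs
#' bind every gene uniformly at the background rate. Additional sub-threshold
#' peaks (scores in [50,100)) are scattered so score filtering is exercised.
#'
#' @param tss A `TssAnnotation` (see [make_annotation()]).
#' @param target_genes Character vector of target gene symbols (subset of
#'   `tss$gene`).
#' @param n_tfs Total number of TFs (>= 1); the first, `TF_true`, carries
#'   the planted signal.
#' @param frac_targets_bound,frac_background_bound Binding probabilities.
#' @param seed Integer RNG seed.
#' @param window Half-width of the promoter window in bp (default 5000).
#' @return Named list of `PeakSet` objects (`TF_true`, `TF_decoy1`, ...).
#' @export
simulate_peaks <- function(tss, target_genes, n_tfs = 3,
                           frac_targets_bound = 0.9,
                           frac_background_bound = 0.1,
                           seed = 1L, window = 5000L) {
  stopifnot(inherits(tss, "TssAnnotation"), n_tfs >= 1)
  if (!all(target_genes %in% tss$gene))
    stop("target_genes must all be present in the annotation")
  if (frac_targets_bound <= frac_background_bound)
    warning("frac_targets_bound <= frac_background_bound: enrichment unidentifiable")
  with_rng_seed(seed, {
    is_target <- tss$gene %in% target_genes
    tf_names <- c("TF_true",
                  if (n_tfs > 1) paste0("TF_decoy", seq_len(n_tfs - 1)))
    make_peaks <- function(bind) {
      idx <- which(bind)
      # binding peak: fully inside the promoter window, score >= 100
      offs <- sample(-(window - 200L):(window - 200L), length(idx), replace = TRUE)
      center <- pmax(tss$tss[idx] + offs, 100L)
      df <- data.frame(chrom = tss$chrom[idx],
                       start = center - 100L, end = center + 100L,
                       score = stats::runif(length(idx), 100, 500),
                       stringsAsFactors = FALSE)
      # sub-threshold decoy peaks near a random 10% of all TSSs
      sub <- which(stats::runif(nrow(tss)) < 0.1)
      center2 <- pmax(tss$tss[sub], 100L)
      df2 <- data.frame(chrom = tss$chrom[sub],
                        start = center2 - 100L, end = center2 + 100L,
                        score = stats::runif(length(sub), 50, 99.99),
                        stringsAsFactors = FALSE)
      rbind(df, df2)
    }
    sets <- lapply(seq_along(tf_names), function(k) {
      p <- if (k == 1)
        ifelse(is_target, frac_targets_bound, frac_background_bound)
      else frac_background_bound
      bind <- stats::runif(nrow(tss)) < p
      structure(list(tf_name = tf_names[k], peaks = make_peaks(bind)),
                class = "PeakSet")
    })
    stats::setNames(sets, tf_names)
  })
}

#' Simulate a gene association network with planted dense modules
#'
#' Erdos-Renyi background with planted near-cliques; optional sparse edges
#' between module vertices and the rest of the graph.
#'
#' @param n_background_nodes Number of background vertices.
#' @param planted_modules List of `c(size, density)` pairs; density is the
#'   within-module edge probability (1 plants a clique).
#' @param inter_module_edge_prob Probability of an edge between a module
#'   vertex and any vertex outside its module.
#' @param seed Integer RNG seed.
#' @param background_edge_prob Edge probability among background vertices
#'   (default 0.01: sparse).
#' @return List with `edges` (an `EdgeList`, scores all 900) and `truth`, a
#'   list of character vectors of module member names (`mod1`, `mod2`, ...).
#'   Vertices are named `g1`, `g2`, ...; module vertices come first.
#' @export
simulate_network <- function(n_background_nodes, planted_modules,
                             inter_module_edge_prob = 0, seed = 1L,
                             background_edge_prob = 0.01) {
  with_rng_seed(seed, {
    sizes <- vapply(planted_modules, `[`, numeric(1), 1)
    dens <- vapply(planted_modules, `[`, numeric(1), 2)
    n_mod <- sum(sizes)
    n <- n_mod + n_background_nodes
    nodes <- paste0("g", seq_len(n))
    membership <- rep(0L, n)
    off <- 0L
    truth <- list()
    for (m in seq_along(sizes)) {
      idx <- off + seq_len(sizes[m])
      membership[idx] <- m
      truth[[paste0("mod", m)]] <- nodes[idx]
      off <- off + as.integer(sizes[m])
    }
    pairs <- utils::combn(n, 2)
    i <- pairs[1, ]; j <- pairs[2, ]
    same_mod <- membership[i] > 0 & membership[i] == membership[j]
    both_bg <- membership[i] == 0 & membership[j] == 0
    p <- ifelse(same_mod, dens[pmax(membership[i], 1)],
                ifelse(both_bg, background_edge_prob, inter_module_edge_prob))
    keep <- stats::runif(length(p)) < p
    el <- data.frame(gene_a = nodes[i[keep]], gene_b = nodes[j[keep]],
                     score = 900, stringsAsFactors = FALSE)
    class(el) <- c("EdgeList", "data.frame")
    list(edges = el, truth = truth)
  })
}

#' Generate a synthetic TSS annotation
#'
#' TSSs are placed on a 30 kb grid with sub-10 kb jitter, guaranteeing all
#' pairwise distances >= 20 kb so default promoter windows never overlap.
#' Strands alternate + / -.
#'
#' @param n_genes Number of genes.
#' @param chromosome_lengths Named integer vector of chromosome lengths (bp).
#' @param seed Integer RNG seed.
#' @return A `TssAnnotation` data frame (`gene`, `chrom`, `strand`, `tss`).
#' @export
make_annotation <- function(n_genes,
                            chromosome_lengths = c(chr1 = 100e6),
                            seed = 1L) {
  with_rng_seed(seed, {
    spacing <- 30000L
    slots_per_chr <- pmax(as.integer(chromosome_lengths %/% spacing) - 1L, 0L)
    if (sum(slots_per_chr) < n_genes)
      stop("chromosomes too short for ", n_genes, " genes at 30 kb spacing")
    chr_of <- rep(names(chromosome_lengths), slots_per_chr)
    slot_of <- unlist(lapply(slots_per_chr, seq_len), use.names = FALSE)
    pick <- sort(sample(length(chr_of), n_genes))
    tss <- (slot_of[pick] - 1L) * spacing + 10000L +
      as.integer(floor(stats::runif(n_genes, 0, 9999)))
    ann <- data.frame(gene = sprintf("gene_%05d", seq_len(n_genes)),
                      chrom = chr_of[pick],
                      strand = rep_len(c("+", "-"), n_genes),
                      tss = tss, stringsAsFactors = FALSE)
    class(ann) <- c("TssAnnotation", "data.frame")
    ann
  })
}
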