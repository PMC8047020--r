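#' Induce the association subgraph on a gene list
#'
#' Builds an undirected simple igraph from the edge list and restricts it to
#' the given genes. Genes absent from the network are dropped (counts
#' logged); genes present in the network but without edges inside the
#' selection are retained as isolated vertices.
#'
#' @param edges An `EdgeList` (see [read_edges()]).
#' @param genes Character vector of gene ids.
#' @return An igraph object.
#' @export
induce_subgraph <- function(edges, genes) {
  if (length(genes) == 0) stop("gene list is empty")
  verts <- unique(c(edges$gene_a, edges$gene_b))
  mapped <- intersect(genes, verts)
  if (length(mapped) == 0)
    stop("none of the ", length(genes), " genes map to the network")
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = verts))
  g <- igraph::simplify(g)
  sub <- igraph::induced_subgraph(g, mapped)
  log_info("induce_subgraph: %d / %d genes mapped; %d edges",
           length(mapped), length(genes), igraph::ecount(sub))
  sub
}

#' Core numbers of every vertex
#'
#' Standard k-core decomposition by iterative minimum-degree peeling: the
#' core number of a vertex is the largest k such that it belongs to a
#' subgraph in which every vertex has degree >= k.
#'
#' @param graph An undirected simple igraph.
#' @return Named integer vector of core numbers.
#' @export
core_decomposition <- function(graph) {
  igraph::coreness(graph)
}

# density of a simple undirected graph: 2E / (V (V-1)); 0 for V <= 1
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n <= 1) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# MCODE vertex weight: highest k-core of the closed neighborhood of v,
# weight = core number x density of that core subgraph.
mcode_vertex_weights <- function(g, degree_cutoff) {
  n <- igraph::vcount(g)
  w <- numeric(n)
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, seq_len(n))
  for (v in which(deg >= degree_cutoff)) {
    nb <- c(v, as.integer(adj[[v]]))
    sg <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sg)
    kmax <- max(core)
    kc <- igraph::induced_subgraph(sg, which(core >= kmax))
    w[v] <- kmax * graph_density(kc)
  }
  names(w) <- igraph::V(g)$name
  w
}

#' MCODE-style dense-module detection
#'
#' Three stages. (1) Vertex weighting: each vertex with degree >=
#' `degree_cutoff` is scored by the highest k-core of the subgraph induced
#' on its closed neighborhood — weight = (core number) x (density of that
#' core subgraph); lower-degree vertices get weight 0. (2) Complex
#' prediction: the unvisited vertex of highest weight seeds a breadth-first
#' expansion (up to `max_depth` levels) that adds unvisited neighbors whose
#' weight is at least `seed_weight * (1 - node_score_cutoff)`. (3)
#' Post-processing: with `haircut`, singly-connected vertices are
#' iteratively trimmed; complexes lacking a `k_core`-core are discarded.
#' Modules are vertex-disjoint, each induces a connected subgraph, and are
#' ranked by score = density x vertex count. Ties on weight are broken by
#' vertex name, so results are deterministic and relabeling-invariant up to
#' that rule.
#'
#' @param graph An undirected simple igraph.
#' @param degree_cutoff Minimum degree for a vertex to be weighted
#'   (default 2).
#' @param node_score_cutoff Fraction of the seed weight a vertex may fall
#'   short by and still join (default 0.2).
#' @param k_core Minimum core a complex must contain (default 2).
#' @param max_depth Maximum breadth-first expansion depth (default 100).
#' @param haircut Trim singly-connected vertices from complexes
#'   (default TRUE).
#' @param fluff Unsupported flag kept for interface parity; must be FALSE.
#' @return List of `ModuleResult`s sorted by decreasing score, each a list
#'   `members` (sorted names), `seed`, `score`, `density`, `rank`.
#' @export
mcode <- function(graph, degree_cutoff = 2, node_score_cutoff = 0.2,
                  k_core = 2, max_depth = 100, haircut = TRUE, fluff = FALSE) {
  if (!isFALSE(fluff)) stop("fluff expansion is not implemented")
  g <- igraph::simplify(graph)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  n <- igraph::vcount(g)
  if (n == 0) return(list())
  w <- mcode_vertex_weights(g, degree_cutoff)
  nm <- igraph::V(g)$name
  adj <- igraph::adjacent_vertices(g, seq_len(n))
  visited <- logical(n)
  order_seeds <- order(-w, nm)
  complexes <- list()
  for (seed in order_seeds) {
    if (visited[seed] || w[seed] <= 0) next
    thr <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!visited[u] && w[u] >= thr) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    complexes[[length(complexes) + 1]] <- list(seed = seed, members = members)
  }
  results <- list()
  for (cx in complexes) {
    sg <- igraph::induced_subgraph(g, cx$members)
    if (haircut) {
      repeat {
        low <- which(igraph::degree(sg) < 2)
        if (length(low) == 0 || igraph::vcount(sg) - length(low) < 2) break
        sg <- igraph::induced_subgraph(
          sg, setdiff(seq_len(igraph::vcount(sg)), low))
      }
    }
    if (igraph::vcount(sg) < 2) next
    if (max(igraph::coreness(sg)) < k_core) next
    results[[length(results) + 1]] <- list(
      members = sort(igraph::V(sg)$name),
      seed = nm[cx$seed],
      score = graph_density(sg) * igraph::vcount(sg),
      density = graph_density(sg))
  }
  if (length(results) == 0) return(list())
  ord <- order(-vapply(results, `[[`, numeric(1), "score"),
               vapply(results, `[[`, character(1), "seed"))
  results <- results[ord]
  for (i in seq_along(results)) {
    results[[i]]$rank <- i
    class(results[[i]]) <- "ModuleResult"
  }
  results
}

#' Annotate detected modules against gene sets
#'
#' For each module, the overlap with every annotation set and a two-tailed
#' Fisher overrepresentation p-value within the graph's vertex universe
#' (delegating to [gene_set_ora()]).
#'
#' @param modules List of `ModuleResult`s from [mcode()].
#' @param annotations A `GeneSetCollection`.
#' @param universe Gene universe for the test (default: union of module
#'   members and all annotated genes).
#' @return Data frame: `module_rank`, `module_size`, `set`, `overlap`, `p`,
#'   `adjusted_p`, sorted by module then p.
#' @export
module_report <- function(modules, annotations, universe = NULL) {
  if (length(modules) == 0) stop("no modules to report")
  if (is.null(universe))
    universe <- unique(c(unlist(lapply(modules, `[[`, "members")),
                         unlist(annotations)))
  out <- do.call(rbind, lapply(modules, function(m) {
    if (length(annotations) == 0)
      return(data.frame(module_rank = m$rank, module_size = length(m$members),
                        set = character(0), overlap = integer(0),
                        p = numeric(0), adjusted_p = numeric(0)))
    ora <- gene_set_ora(m$members, annotations, universe)
    data.frame(module_rank = m$rank, module_size = length(m$members),
               set = ora$set, overlap = ora$overlap, p = ora$p,
               adjusted_p = ora$adjusted_p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
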