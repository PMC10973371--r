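# Hub-gene selection on a protein-interaction graph: exact shortest-path
# betweenness (unnormalized pair-count form) and radiality centrality,
# computed per connected component, then the union of the top-k genes under
# each score. STRING confidences act only as an ingestion filter; shortest
# paths are unweighted.

#' Build an interaction graph restricted to a gene list
#'
#' Induced subgraph on `restrict_to` intersected with the edge endpoints;
#' requested genes absent from any edge are retained as isolated degree-0
#' nodes. The number of requested genes not found among endpoints is logged.
#'
#' @param edges an [edge_list()].
#' @param restrict_to optional character vector of gene IDs; NULL keeps the
#'   whole edge list.
#' @return an igraph undirected simple graph.
#' @export
build_graph <- function(edges, restrict_to = NULL) {
  endpoints <- unique(c(edges$gene_a, edges$gene_b))
  if (is.null(restrict_to)) {
    nodes <- endpoints
    keep <- rep(TRUE, nrow(edges))
  } else {
    restrict_to <- unique(as.character(restrict_to))
    nodes <- restrict_to
    if (!length(intersect(restrict_to, endpoints))) {
      stop_sf("no requested gene appears in the edge list")
    }
    keep <- edges$gene_a %in% restrict_to & edges$gene_b %in% restrict_to
    sf_log("graph", length(setdiff(restrict_to, endpoints)),
           " requested gene(s) not found among edge endpoints (kept isolated)")
  }
  g <- igraph::graph_from_data_frame(
    edges[keep, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = nodes))
  igraph::simplify(g)
}

#' Betweenness centrality (unnormalized pair-count form)
#'
#' Exact shortest-path betweenness on the unweighted undirected graph with
#' fractional credit when several shortest paths exist; each unordered pair
#' counted once; no normalization. Isolated nodes score 0.
#'
#' @param graph an igraph graph from [build_graph()].
#' @return named numeric vector over nodes.
#' @export
betweenness_centrality <- function(graph) {
  igraph::betweenness(graph, directed = FALSE, normalized = FALSE)
}

#' Radiality centrality
#'
#' Per connected component with diameter `D` and size `m`:
#' `rad(v) = sum_{u != v, same component} (D + 1 - d(v, u)) / (m - 1)`.
#' Singleton components score 0; cross-component pairs contribute nothing.
#'
#' @param graph an igraph graph from [build_graph()].
#' @return named numeric vector over nodes.
#' @export
radiality_centrality <- function(graph) {
  comp <- igraph::components(graph)
  rad <- stats::setNames(numeric(igraph::vcount(graph)),
                         igraph::V(graph)$name)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    m <- length(members)
    if (m < 2) next
    d <- igraph::distances(graph, v = members, to = members)
    diam <- max(d)
    rad[members] <- (rowSums(diam + 1 - d) - (diam + 1)) / (m - 1)
  }
  rad
}

#' Centrality table for a graph
#'
#' @param graph an igraph graph.
#' @return data.frame: gene, betweenness, radiality, degree.
#' @export
centrality_table <- function(graph) {
  data.frame(gene = igraph::V(graph)$name,
             betweenness = unname(betweenness_centrality(graph)),
             radiality = unname(radiality_centrality(graph)),
             degree = unname(igraph::degree(graph)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select hub genes as the union of top-k by betweenness and by radiality
#'
#' Ties at the k-th rank are broken by the other centrality, then by
#' lexicographic gene ID, so selection is deterministic. Provenance records
#' which list(s) each hub came from.
#'
#' @param centralities data.frame from [centrality_table()].
#' @param k number of top genes per score (default 10).
#' @return a `hub_selection` data.frame: gene, betweenness, radiality,
#'   from_betweenness, from_radiality.
#' @export
select_hubs <- function(centralities, k = 10) {
  n <- nrow(centralities)
  if (k > n) stop_sf("k = %d exceeds node count %d", k, n)
  ord_b <- order(-centralities$betweenness, -centralities$radiality,
                 centralities$gene)
  ord_r <- order(-centralities$radiality, -centralities$betweenness,
                 centralities$gene)
  top_b <- centralities$gene[ord_b][seq_len(k)]
  top_r <- centralities$gene[ord_r][seq_len(k)]
  hubs <- sort(union(top_b, top_r))
  out <- centralities[match(hubs, centralities$gene),
                      c("gene", "betweenness", "radiality")]
  out$from_betweenness <- out$gene %in% top_b
  out$from_radiality <- out$gene %in% top_r
  rownames(out) <- NULL
  structure(out, class = c("hub_selection", "data.frame"), k = k)
}

#' Derive a hub gene signature from a DEG table
#'
#' Assigns hub genes up/down direction from their differential-expression
#' direction (a hub with `ns` direction is assigned by the sign of its
#' log2 fold change).
#'
#' @param hubs a `hub_selection`.
#' @param deg a `deg_table` covering the hub genes.
#' @param name signature name.
#' @return a `gene_signature`.
#' @export
hubs_to_signature <- function(hubs, deg, name = "hub_signature") {
  idx <- match(hubs$gene, deg$gene)
  if (anyNA(idx)) {
    stop_sf("hub gene(s) missing from the DEG table: %s",
            paste(utils::head(hubs$gene[is.na(idx)], 3), collapse = ", "))
  }
  up <- hubs$gene[deg$log2_fold_change[idx] > 0]
  down <- hubs$gene[deg$log2_fold_change[idx] <= 0]
  gene_signature(name, up, down,
                 provenance = "union of top-k betweenness and radiality hubs")
}
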