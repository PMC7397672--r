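#' Outdegree distribution of hidden nodes
#'
#' Outdegree in data-flow direction for every hidden node, plus the
#' empirical cumulative distribution over hidden nodes. Knowledge-derived
#' networks show approximately exponential outdegree distributions (hubs),
#' while layered artificial networks have constant outdegree per layer.
#'
#' @param g a [neural_graph()].
#' @return List with `outdegree` (named integer vector over hidden nodes)
#'   and `cdf` (data.frame: `outdegree`, `cumulative_fraction`).
#' @export
outdegree_distribution <- function(g) {
  hid <- hidden_nodes(g)
  deg <- igraph::degree(as_igraph(g), v = hid, mode = "out")
  vals <- sort(unique(deg))
  cdf <- data.frame(outdegree = vals,
                    cumulative_fraction = vapply(vals, function(v)
                      mean(deg <= v), 1))
  list(outdegree = deg, cdf = cdf)
}

#' Mean distance from hidden nodes to the input layer
#'
#' Shortest-path distance from each hidden node to every reachable input
#' node, traversed against the data-flow direction, averaged over the
#' reachable inputs. In a fully connected layered network this distance is
#' identical for all nodes of a layer; shortcut edges in knowledge-derived
#' networks spread it widely. A hidden node reaching no input yields `NA`.
#'
#' @param g a [neural_graph()].
#' @return Named numeric vector of mean distances per hidden node.
#' @export
distances_to_inputs <- function(g) {
  hid <- hidden_nodes(g)
  inp <- input_nodes(g)
  d <- igraph::distances(as_igraph(g), v = hid, to = inp, mode = "in")
  out <- apply(d, 1, function(r) {
    r <- r[is.finite(r)]
    if (!length(r)) NA_real_ else mean(r)
  })
  names(out) <- hid
  out
}

#' Reachability: input nodes accessible from each hidden node
#'
#' Counts, for every hidden node, the input nodes it can access through
#' directed paths (against data-flow). Sparse modular networks restrict
#' most hidden nodes to a small fraction of the inputs; fully connected
#' networks give every hidden node access to all of them.
#'
#' @param g a [neural_graph()].
#' @return Named integer vector of reachable-input counts per hidden node.
#' @export
reachability <- function(g) {
  hid <- hidden_nodes(g)
  inp <- input_nodes(g)
  d <- igraph::distances(as_igraph(g), v = hid, to = inp, mode = "in")
  out <- apply(d, 1, function(r) sum(is.finite(r)))
  names(out) <- hid
  out
}

#' Fragmentation under removal of high-betweenness edges
#'
#' Treats the network as undirected and iteratively removes the edge with
#' the highest edge betweenness (recomputed after every removal), recording
#' the number of connected components after each removal -- a probe of
#' network modularity: modular networks fragment quickly, homogeneous
#' layered networks resist fragmentation. Betweenness ties are broken by
#' lexicographic edge order for determinism.
#'
#' @param g a [neural_graph()].
#' @param n_removals number of edges to remove (at most the edge count).
#' @return data.frame with columns `removed` (1..n) and `components`.
#' @export
fragmentation_curve <- function(g, n_removals) {
  if (n_removals > nrow(g$edges))
    stop("n_removals exceeds the edge count")
  ig <- igraph::as_undirected(as_igraph(g), mode = "collapse")
  comps <- integer(n_removals)
  for (i in seq_len(n_removals)) {
    eb <- igraph::edge_betweenness(ig)
    ends <- igraph::ends(ig, igraph::E(ig))
    key <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
    best <- order(-eb, key)[1]
    ig <- igraph::delete_edges(ig, best)
    comps[i] <- igraph::components(ig)$no
  }
  data.frame(removed = seq_len(n_removals), components = comps)
}

#' Per-hidden-node structural report
#'
#' Combines outdegree, mean distance to inputs, and reachability into one
#' table for comparative analysis of network structure.
#'
#' @param g a [neural_graph()].
#' @return data.frame with columns `node`, `outdegree`, `mean_distance`,
#'   `reachability`.
#' @export
structure_report <- function(g) {
  deg <- outdegree_distribution(g)$outdegree
  data.frame(node = hidden_nodes(g),
             outdegree = as.integer(deg[hidden_nodes(g)]),
             mean_distance = distances_to_inputs(g)[hidden_nodes(g)],
             reachability = as.integer(reachability(g)[hidden_nodes(g)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
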