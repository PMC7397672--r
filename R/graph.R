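#' Directed acyclic neural-network graph
#'
#' A `neural_graph` is a directed acyclic graph in data-flow orientation
#' (input genes feed transcription factors, which feed signaling proteins,
#' which feed the output nodes). Input nodes are the nodes with indegree
#' zero, output nodes are the nodes with outdegree zero, everything in
#' between is a hidden node whose activity is inferred during training.
#'
#' @param edges data.frame with character columns `from` and `to`, one row
#'   per directed edge in data-flow orientation.
#' @param input_nodes,output_nodes optional character vectors naming the
#'   input/output nodes; by default derived as indegree-zero and
#'   outdegree-zero nodes.
#' @param validate check the structural invariants (acyclicity, every input
#'   with outdegree >= 1, every output with indegree >= 1, every hidden node
#'   on at least one input-to-output path).
#'
#' @return An object of class `neural_graph` with elements `nodes`
#'   (data.frame: `name`, `role`) and `edges` (data.frame: `from`, `to`).
#' @export
neural_graph <- function(edges, input_nodes = NULL, output_nodes = NULL,
                         validate = TRUE) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(paste0(edges$from, "\r", edges$to)))
    stop("duplicated edges in neural graph")
  nodes <- unique(c(edges$from, edges$to))
  indeg <- table(factor(edges$to, levels = nodes))
  outdeg <- table(factor(edges$from, levels = nodes))
  if (is.null(input_nodes)) input_nodes <- nodes[indeg == 0]
  if (is.null(output_nodes)) output_nodes <- nodes[outdeg == 0]
  role <- rep("hidden", length(nodes))
  role[nodes %in% input_nodes] <- "input"
  role[nodes %in% output_nodes] <- "output"
  g <- structure(
    list(nodes = data.frame(name = nodes, role = role,
                            stringsAsFactors = FALSE),
         edges = edges),
    class = "neural_graph")
  if (validate) validate_neural_graph(g)
  g
}

#' Validate the invariants of a neural graph
#'
#' Asserts acyclicity via Kahn's algorithm, that every input node has
#' outdegree at least one, that every output node has indegree at least one,
#' and that every hidden node lies on at least one input-to-output path.
#'
#' @param g a [neural_graph()].
#' @return `g`, invisibly; errors if an invariant is violated.
#' @export
validate_neural_graph <- function(g) {
  nodes <- g$nodes$name
  if (anyDuplicated(nodes)) stop("node identifiers must be unique")
  miss <- setdiff(c(g$edges$from, g$edges$to), nodes)
  if (length(miss)) stop("edge endpoints missing from node set: ",
                         paste(miss, collapse = ", "))
  ord <- topological_order(g)        # errors if cyclic
  ig <- as_igraph(g)
  inp <- input_nodes(g); out <- output_nodes(g)
  if (!length(inp)) stop("neural graph has no input nodes")
  if (!length(out)) stop("neural graph has no output nodes")
  if (any(igraph::degree(ig, inp, mode = "out") < 1))
    stop("every input node must have outdegree >= 1")
  if (any(igraph::degree(ig, out, mode = "in") < 1))
    stop("every output node must have indegree >= 1")
  hid <- hidden_nodes(g)
  if (length(hid)) {
    d_in <- igraph::distances(ig, v = hid, to = inp, mode = "in")
    d_out <- igraph::distances(ig, v = hid, to = out, mode = "out")
    bad <- hid[!(apply(is.finite(d_in), 1, any) &
                   apply(is.finite(d_out), 1, any))]
    if (length(bad))
      stop("hidden node(s) not on any input-to-output path: ",
           paste(bad, collapse = ", "))
  }
  invisible(g)
}

#' @export
print.neural_graph <- function(x, ...) {
  cat(sprintf(
    "<neural_graph> %d inputs, %d hidden, %d outputs, %d edges\n",
    length(input_nodes(x)), length(hidden_nodes(x)),
    length(output_nodes(x)), nrow(x$edges)))
  invisible(x)
}

#' Node accessors
#'
#' @param g a [neural_graph()].
#' @return Character vector of node names in the requested role.
#' @export
input_nodes <- function(g) g$nodes$name[g$nodes$role == "input"]

#' @rdname input_nodes
#' @export
output_nodes <- function(g) g$nodes$name[g$nodes$role == "output"]

#' @rdname input_nodes
#' @export
hidden_nodes <- function(g) g$nodes$name[g$nodes$role == "hidden"]

#' Convert a neural graph to an igraph object
#'
#' @param g a [neural_graph()].
#' @return A directed [igraph::igraph] with the same nodes and edges.
#' @export
as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = g$nodes$name)
}

#' Topological order via Kahn's algorithm
#'
#' Repeatedly removes indegree-zero nodes. Errors if the graph contains a
#' cycle. This is intentionally self-contained so it can serve as the
#' acyclicity assertion for every constructed network.
#'
#' @param g a [neural_graph()] or a data.frame of `from`/`to` edges.
#' @return Character vector: all node names in a topological order.
#' @export
topological_order <- function(g) {
  edges <- if (is.data.frame(g)) g else g$edges
  nodes <- if (is.data.frame(g)) unique(c(edges$from, edges$to)) else g$nodes$name
  indeg <- structure(integer(length(nodes)), names = nodes)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  children <- split(edges$to, factor(edges$from, levels = nodes))
  queue <- nodes[indeg == 0]
  ord <- character(0)
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    ord <- c(ord, n)
    for (ch in children[[n]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != length(nodes))
    stop("graph contains a cycle (no topological order exists)")
  ord
}

#' Node depths relative to the output layer
#'
#' Depth of a node is its distance in edges from the output layer, measured
#' against the data-flow direction. `mode = "longest"` gives the longest
#' path distance (the layering used to place nodes), `mode = "shortest"`
#' the shortest-path distance (the depth used when extending a network
#' acyclically).
#'
#' @param g a [neural_graph()].
#' @param mode `"longest"` or `"shortest"`.
#' @return Named numeric vector of depths; outputs have depth 0.
#' @export
node_depths <- function(g, mode = c("longest", "shortest")) {
  mode <- match.arg(mode)
  out <- output_nodes(g)
  if (mode == "shortest") {
    ig <- as_igraph(g)
    d <- igraph::distances(ig, v = g$nodes$name, to = out, mode = "out")
    depth <- apply(d, 1, min)
    names(depth) <- g$nodes$name
    return(depth)
  }
  ord <- topological_order(g)
  depth <- structure(rep(-Inf, length(ord)), names = ord)
  depth[out] <- 0
  children <- split(g$edges$to, factor(g$edges$from, levels = g$nodes$name))
  for (n in rev(ord)) {
    ch <- children[[n]]
    if (length(ch)) depth[n] <- max(depth[ch]) + 1
  }
  depth[g$nodes$name]
}

#' Read and write networks as tab-separated edge lists
#'
#' The on-disk format is tab-separated with two columns `parent` and
#' `child` (an optional third column carries a category or annotation);
#' lines starting with `#` are comments. The same format is used for prior
#' regulatory graphs and for constructed networks, with `parent` the
#' upstream node in data-flow orientation for constructed networks.
#'
#' @param path file path.
#' @param ... passed to [neural_graph()].
#' @return `read_edge_list()` returns a data.frame with columns `parent`,
#'   `child` and, when present in the file, `category`;
#'   `read_neural_graph()` returns a [neural_graph()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          fill = TRUE, colClasses = "character")
  if (ncol(df) < 2) stop("edge list needs two tab-separated columns: ", path)
  names(df)[1:2] <- c("parent", "child")
  if (ncol(df) >= 3) {
    names(df)[3] <- "category"
    df <- df[, 1:3]
    if (all(is.na(df$category) | df$category == "")) df$category <- NULL
  }
  df
}

#' @rdname read_edge_list
#' @param edges data.frame with columns `parent`/`child` (or `from`/`to`)
#'   and optionally `category`.
#' @export
write_edge_list <- function(edges, path) {
  if (all(c("from", "to") %in% names(edges)))
    edges <- data.frame(parent = edges$from, child = edges$to,
                        stringsAsFactors = FALSE)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_edge_list
#' @export
read_neural_graph <- function(path, ...) {
  df <- read_edge_list(path)
  neural_graph(data.frame(from = df$parent, to = df$child,
                          stringsAsFactors = FALSE), ...)
}

#' @rdname read_edge_list
#' @param g a [neural_graph()].
#' @export
write_neural_graph <- function(g, path) {
  write_edge_list(g$edges, path)
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
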