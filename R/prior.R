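#' Prior-knowledge regulatory graph
#'
#' A directed graph of documented regulatory relationships: signaling
#' interactions (receptor and signaling-protein nodes) and transcription
#' factor to target-gene relations. Cycles are permitted -- biological
#' networks contain feedback; acyclicity is only enforced on the neural
#' networks derived from the prior.
#'
#' @param edges data.frame with character columns `from` (regulator) and
#'   `to` (target); an optional `evidence` column is retained as an
#'   annotation.
#' @param categories named character vector mapping node names to one of
#'   `"gene"`, `"transcription_factor"`, `"signaling"`, `"receptor"`,
#'   `"output"`. Nodes absent from the map default to `"signaling"`.
#' @return An object of class `prior_graph`.
#' @export
prior_graph <- function(edges, categories = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      evidence = if ("evidence" %in% names(edges))
                        as.character(edges$evidence) else NA_character_,
                      stringsAsFactors = FALSE)
  nodes <- unique(c(edges$from, edges$to))
  cat_levels <- c("gene", "transcription_factor", "signaling", "receptor",
                  "output")
  category <- structure(rep("signaling", length(nodes)), names = nodes)
  if (!is.null(categories)) {
    bad <- setdiff(unique(categories), cat_levels)
    if (length(bad)) stop("unknown node categories: ",
                          paste(bad, collapse = ", "))
    known <- intersect(names(categories), nodes)
    category[known] <- categories[known]
  }
  structure(list(nodes = data.frame(name = nodes, category = unname(category),
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "prior_graph")
}

#' @export
print.prior_graph <- function(x, ...) {
  cat(sprintf("<prior_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$category))
  invisible(x)
}

prior_igraph <- function(prior) {
  igraph::graph_from_data_frame(prior$edges[c("from", "to")],
                                directed = TRUE, vertices = prior$nodes$name)
}

node_categories <- function(prior) {
  structure(prior$nodes$category, names = prior$nodes$name)
}

#' Read a prior graph from a tab-separated edge list
#'
#' @param path edge-list file (`parent<TAB>child`, optional third column);
#'   see [read_edge_list()].
#' @param categories optional named character vector of node categories,
#'   see [prior_graph()].
#' @return A [prior_graph()].
#' @export
read_prior_graph <- function(path, categories = NULL) {
  df <- read_edge_list(path)
  prior_graph(data.frame(from = df$parent, to = df$child,
                         stringsAsFactors = FALSE), categories = categories)
}

#' Read a transcription factor to target-gene map
#'
#' Expects a tab-separated file with columns `tf<TAB>gene`; returns the
#' named list representation used by [build_kpnn()].
#'
#' @param path file path.
#' @return Named list: one character vector of target genes per TF.
#' @export
read_tf_targets <- function(path) {
  df <- read_edge_list(path)
  split(df$child, df$parent)
}

#' Restrict target genes to those with few regulators
#'
#' Genes targeted by more than `max_regulators` transcription factors are
#' dropped from the map to avoid promiscuous or false-positive regulatory
#' relations dominating the network (the default of 25 mirrors the
#' promiscuity filter applied when compiling regulatory databases).
#'
#' @param tf_targets named list mapping TF name to character vector of
#'   target genes.
#' @param max_regulators maximum number of TFs allowed to target a gene.
#' @return Filtered named list of the same shape.
#' @export
filter_promiscuous_genes <- function(tf_targets, max_regulators = 25) {
  counts <- table(unlist(tf_targets, use.names = FALSE))
  keep <- names(counts)[counts <= max_regulators]
  out <- lapply(tf_targets, function(gs) gs[gs %in% keep])
  out[vapply(out, length, 1L) > 0]
}
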