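#' Build a knowledge-primed neural network by shortest paths
#'
#' Connects an output node (typically a cell-surface receptor) to all
#' reachable transcription factors through shortest paths in the prior
#' regulatory graph, then attaches each reachable TF to its target genes.
#' All equal-length shortest paths to a TF are retained. The assembled
#' graph is returned reversed into data-flow orientation: measured gene
#' expression (input nodes) feeds transcription factors, which feed
#' signaling proteins, which feed the output node.
#'
#' @param prior a [prior_graph()].
#' @param output_node name of the node (in `prior`) to use as network
#'   output; paths are traced from it along the prior's regulator-to-target
#'   edges.
#' @param tf_targets named list mapping transcription-factor node names to
#'   character vectors of target genes.
#' @param max_regulators promiscuity filter applied to `tf_targets`: genes
#'   targeted by more than this many TFs are dropped (default 25); `Inf`
#'   disables the filter.
#' @return A [neural_graph()] whose inputs are genes, whose hidden nodes are
#'   TFs and signaling proteins on shortest paths, and whose single output
#'   is `output_node`.
#' @export
build_kpnn <- function(prior, output_node, tf_targets, max_regulators = 25) {
  stopifnot(inherits(prior, "prior_graph"))
  if (!output_node %in% prior$nodes$name)
    stop("output node not found in prior graph: ", output_node)
  tfs <- names(tf_targets)
  bad <- setdiff(tfs, prior$nodes$name)
  if (length(bad))
    stop("tf_targets keys missing from prior graph: ",
         paste(bad, collapse = ", "))
  if (is.finite(max_regulators))
    tf_targets <- filter_promiscuous_genes(tf_targets, max_regulators)
  tfs <- names(tf_targets)
  ig <- prior_igraph(prior)
  d <- igraph::distances(ig, v = output_node, to = tfs, mode = "out")
  reachable <- tfs[is.finite(d[1, ])]
  if (!length(reachable))
    stop("no transcription factor is reachable from ", output_node,
         ": resulting network would be empty")
  edges <- list()
  for (tf in reachable) {
    paths <- igraph::all_shortest_paths(ig, from = output_node, to = tf,
                                        mode = "out")$res
    for (p in paths) {
      nm <- names(p)
      if (length(nm) > 1)
        edges[[length(edges) + 1L]] <-
          data.frame(from = nm[-length(nm)], to = nm[-1],
                     stringsAsFactors = FALSE)
    }
  }
  path_edges <- unique(do.call(rbind, edges))
  tf_gene <- do.call(rbind, lapply(reachable, function(tf) {
    gs <- tf_targets[[tf]]
    if (!length(gs)) return(NULL)
    data.frame(from = tf, to = gs, stringsAsFactors = FALSE)
  }))
  all_edges <- unique(rbind(path_edges, tf_gene))
  # reverse into data-flow orientation: gene -> TF -> signaling -> output
  neural_graph(data.frame(from = all_edges$to, to = all_edges$from,
                          stringsAsFactors = FALSE),
               output_nodes = output_node)
}

#' Extend a network acyclically with shortest paths from extra sources
#'
#' Adds shortest paths from additional source nodes (e.g., further cell
#' surface receptors) to all reachable transcription factors in the prior,
#' without introducing cycles. Candidate path edges, expressed in
#' output-rooted orientation (parent nearer the output), are admitted if
#' the parent's depth is smaller than the child's depth or if the child is
#' not yet part of the network; the depth of transcription factors and
#' their downstream gene nodes is forced above all non-TF depths so that
#' feedback from TFs into signaling is excluded. Passes over the candidate
#' list (in seeded random order) repeat until a full pass admits no edge.
#'
#' @param base a valid [neural_graph()] to extend.
#' @param prior a [prior_graph()]; node categories identify transcription
#'   factors and genes.
#' @param sources character vector of source node names in `prior`.
#' @param seed integer seed fixing the candidate processing order.
#' @return The extended [neural_graph()] (still acyclic).
#' @export
extend_acyclic <- function(base, prior, sources, seed = 1L) {
  validate_neural_graph(base)
  stopifnot(inherits(prior, "prior_graph"))
  bad <- setdiff(sources, prior$nodes$name)
  if (length(bad)) stop("source node(s) missing from prior graph: ",
                        paste(bad, collapse = ", "))
  cats <- node_categories(prior)
  tf_zone <- function(n) {
    cat <- cats[n]
    # TFs and genes sit below all signaling depths; nodes unknown to the
    # prior fall back on their role in the base network (inputs = genes)
    (!is.na(cat) & cat %in% c("transcription_factor", "gene")) |
      (is.na(cat) & n %in% input_nodes(base))
  }
  # depths from the output nodes (output-rooted orientation)
  depth <- node_depths(base, mode = "shortest")
  offset <- suppressWarnings(max(depth[!tf_zone(names(depth))], 0)) + 1
  depth[tf_zone(names(depth))] <- depth[tf_zone(names(depth))] + offset

  # candidate edges: all shortest paths source -> reachable TFs, in
  # output-rooted orientation (as in the prior graph)
  ig <- prior_igraph(prior)
  tfs <- prior$nodes$name[prior$nodes$category == "transcription_factor"]
  cand <- list()
  for (s in sources) {
    d <- igraph::distances(ig, v = s, to = tfs, mode = "out")
    for (tf in tfs[is.finite(d[1, ])]) {
      for (p in igraph::all_shortest_paths(ig, from = s, to = tf,
                                           mode = "out")$res) {
        nm <- names(p)
        if (length(nm) > 1)
          cand[[length(cand) + 1L]] <-
            data.frame(parent = nm[-length(nm)], child = nm[-1],
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(base)
  cand <- unique(do.call(rbind, cand))

  # current edge set in output-rooted orientation
  cur <- paste0(base$edges$to, "\r", base$edges$from)
  present <- unique(c(base$edges$from, base$edges$to))
  new_edges <- list()
  with_seed(seed, {
    repeat {
      added <- 0L
      for (i in sample.int(nrow(cand))) {
        p <- cand$parent[i]; ch <- cand$child[i]
        key <- paste0(p, "\r", ch)
        if (key %in% cur) next
        if (!p %in% present) next
        if (!ch %in% present) {
          depth[ch] <- unname(depth[p]) + 1 +
            if (tf_zone(ch) && !tf_zone(p)) offset else 0
          present <- c(present, ch)
        } else if (!(depth[p] < depth[ch])) next
        cur <- c(cur, key)
        new_edges[[length(new_edges) + 1L]] <- c(p, ch)
        added <- added + 1L
      }
      if (added == 0L) break
    }
  })
  if (!length(new_edges)) return(base)
  add <- do.call(rbind, new_edges)
  edges <- unique(rbind(base$edges,
                        data.frame(from = add[, 2], to = add[, 1],
                                   stringsAsFactors = FALSE)))
  neural_graph(edges, output_nodes = output_nodes(base))
}

#' Build a fully connected layered artificial neural network
#'
#' Hidden nodes are distributed as evenly as possible across the layers
#' (earlier layers take the remainder), adjacent layers are fully
#' connected, the first hidden layer is connected to all inputs and the
#' last hidden layer to all outputs. Used as a structural control with the
#' same node counts as a knowledge-derived network.
#'
#' @param n_inputs,n_hidden,n_layers,n_outputs node and layer counts;
#'   `n_hidden` must be at least `n_layers`.
#' @return A strictly layered [neural_graph()]; hidden nodes are named
#'   `h<layer>_<index>`.
#' @export
build_fann <- function(n_inputs, n_hidden, n_layers, n_outputs = 1) {
  stopifnot(n_inputs >= 1, n_outputs >= 1, n_layers >= 1)
  if (n_hidden < n_layers)
    stop("n_hidden must be >= n_layers (every layer needs a node)")
  sizes <- rep(n_hidden %/% n_layers, n_layers)
  rem <- n_hidden %% n_layers
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  layers <- c(list(paste0("in", seq_len(n_inputs))),
              lapply(seq_len(n_layers), function(l)
                paste0("h", l, "_", seq_len(sizes[l]))),
              list(paste0("out", seq_len(n_outputs))))
  edges <- do.call(rbind, lapply(seq_len(length(layers) - 1), function(i)
    expand.grid(from = layers[[i]], to = layers[[i + 1]],
                stringsAsFactors = FALSE)))
  neural_graph(edges)
}

# recover the strict layering of a fANN from longest-path depths
fann_layers <- function(fann) {
  depth <- node_depths(fann, mode = "longest")
  lv <- sort(unique(depth), decreasing = TRUE)   # inputs first
  lapply(lv, function(d) names(depth)[depth == d])
}

#' Build an edge-matched sparse artificial neural network
#'
#' Starting from a fully connected layered network, all edges are removed;
#' a minimal spanning step then connects every lower-layer node to one
#' random upper-layer node (with each upper-layer node guaranteed at least
#' one lower connection), and random absent edges between adjacent layers
#' are added back until the input-section edge count (input layer to first
#' hidden layer) and the hidden-section edge count (all remaining layers)
#' match the two targets -- typically the corresponding counts of a
#' knowledge-derived network.
#'
#' @param fann a strictly layered [neural_graph()] from [build_fann()].
#' @param target_edges_input desired number of input-to-hidden edges.
#' @param target_edges_hidden desired number of edges among hidden layers
#'   and from the last hidden layer to the outputs.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A [neural_graph()] with exactly the requested section edge
#'   counts and end-to-end connectivity.
#' @export
build_sann <- function(fann, target_edges_input, target_edges_hidden,
                       seed = 1L) {
  layers <- fann_layers(fann)
  n_pairs <- length(layers) - 1
  with_seed(seed, {
    span <- lapply(seq_len(n_pairs), function(i) {
      low <- layers[[i]]; up <- layers[[i + 1]]
      if (length(up) <= length(low)) {
        # each upper node takes one distinct lower node, remaining lower
        # nodes attach to random upper nodes
        first <- data.frame(from = sample(low, length(up)), to = up,
                            stringsAsFactors = FALSE)
        rest <- setdiff(low, first$from)
        if (length(rest))
          first <- rbind(first, data.frame(
            from = rest, to = sample(up, length(rest), replace = TRUE),
            stringsAsFactors = FALSE))
      } else {
        first <- data.frame(from = low, to = sample(up, length(low)),
                            stringsAsFactors = FALSE)
        rest <- setdiff(up, first$to)
        if (length(rest))
          first <- rbind(first, data.frame(
            from = sample(low, length(rest), replace = TRUE), to = rest,
            stringsAsFactors = FALSE))
      }
      first
    })
    fill_section <- function(pair_idx, target, have) {
      n_have <- sum(vapply(have, nrow, 1L))
      full <- do.call(rbind, lapply(pair_idx, function(i)
        expand.grid(from = layers[[i]], to = layers[[i + 1]],
                    stringsAsFactors = FALSE)))
      if (target < n_have)
        stop("target edge count (", target,
             ") below the spanning minimum (", n_have, ")")
      if (target > nrow(full))
        stop("target edge count (", target,
             ") exceeds full connectivity (", nrow(full), ")")
      cur <- do.call(rbind, have)
      key <- paste0(full$from, "\r", full$to)
      absent <- full[!key %in% paste0(cur$from, "\r", cur$to), , drop = FALSE]
      n_add <- target - nrow(cur)
      if (n_add > 0)
        cur <- rbind(cur, absent[sample.int(nrow(absent), n_add), ])
      cur
    }
    input_edges <- fill_section(1L, target_edges_input, span[1])
    hidden_edges <- fill_section(seq(2L, n_pairs), target_edges_hidden,
                                 span[-1])
  })
  neural_graph(rbind(input_edges, hidden_edges),
               input_nodes = layers[[1]],
               output_nodes = layers[[length(layers)]])
}

#' Section edge counts of a network
#'
#' Counts the edges leaving input nodes (input section) and all remaining
#' edges (hidden section), the two quantities matched when deriving a
#' sparse control network.
#'
#' @param g a [neural_graph()].
#' @return Named integer vector with elements `input` and `hidden`.
#' @export
section_edge_counts <- function(g) {
  is_input <- g$edges$from %in% input_nodes(g)
  c(input = sum(is_input), hidden = sum(!is_input))
}

#' Randomly shuffle a network while preserving degrees and acyclicity
#'
#' Generates a randomized control network by swapping pairs of edges.
#' Nodes are first grouped into layers by iteratively removing source
#' nodes, then each node receives a unique random index such that lower
#' layers hold smaller indices (so every edge runs from a smaller to a
#' larger index). Edge pairs `(a->b, c->d)` are swapped to `(a->d, c->b)`
#' only if both new edges respect the index ordering and exist neither in
#' the original nor in the current network. Each edge is considered for a
#' swap once; edges without an admissible partner are left unchanged. The
#' result preserves the node set, every node's indegree and outdegree, and
#' acyclicity.
#'
#' @param g an acyclic [neural_graph()].
#' @param seed integer seed.
#' @return A shuffled [neural_graph()].
#' @export
shuffle_network <- function(g, seed = 1L) {
  topological_order(g)   # errors on cyclic input
  # layers by iteratively peeling indegree-zero nodes (data-flow sources)
  edges <- g$edges
  nodes <- g$nodes$name
  layer <- structure(integer(length(nodes)), names = nodes)
  remaining <- nodes
  rem_edges <- edges
  l <- 0L
  while (length(remaining)) {
    srcs <- setdiff(remaining, rem_edges$to)
    layer[srcs] <- l
    remaining <- setdiff(remaining, srcs)
    rem_edges <- rem_edges[!(rem_edges$from %in% srcs), , drop = FALSE]
    l <- l + 1L
  }
  with_seed(seed, {
    idx <- integer(length(nodes)); names(idx) <- nodes
    nxt <- 1L
    for (lv in sort(unique(layer))) {
      members <- nodes[layer == lv]
      idx[sample(members, length(members))] <- seq(nxt, nxt + length(members) - 1L)
      nxt <- nxt + length(members)
    }
    from <- edges$from; to <- edges$to
    orig_keys <- paste0(from, "\r", to)
    cur_keys <- orig_keys
    swapped <- logical(length(from))
    for (i in seq_along(from)) {
      if (swapped[i]) next
      a <- from[i]; b <- to[i]
      cand <- which(!swapped)
      cand <- cand[cand != i]
      if (!length(cand)) next
      cand <- cand[sample.int(length(cand))]
      for (j in cand) {
        cc <- from[j]; d <- to[j]
        if (idx[a] >= idx[d] || idx[cc] >= idx[b]) next
        k1 <- paste0(a, "\r", d); k2 <- paste0(cc, "\r", b)
        if (k1 == k2) next
        if (k1 %in% orig_keys || k2 %in% orig_keys) next
        if (k1 %in% cur_keys || k2 %in% cur_keys) next
        to[i] <- d; to[j] <- b
        cur_keys[i] <- k1; cur_keys[j] <- k2
        swapped[i] <- TRUE; swapped[j] <- TRUE
        break
      }
    }
  })
  neural_graph(data.frame(from = from, to = to, stringsAsFactors = FALSE),
               input_nodes = input_nodes(g), output_nodes = output_nodes(g))
}
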