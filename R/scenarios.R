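#' Ground-truth toy scenarios
#'
#' Builds the small simulated networks used to validate the learning
#' method, together with matched training data in which designated inputs
#' are predictive, and a ground-truth annotation of every hidden node:
#'
#' * `single_node`: one predictive hidden node connected to several
#'   predictive input genes, next to non-predictive sibling hidden nodes
#'   connected to non-predictive genes. Node weights should single out the
#'   predictive node.
#' * `redundant_pair`: two hidden nodes A and B sharing the same
#'   predictive (and filler) input genes -- full redundancy. Trained
#'   without hidden dropout, replicates arbitrarily favor one of the two;
#'   with dropout both carry the signal.
#' * `weak_strong`: three strongly predictive hidden nodes (several
#'   predictive inputs each) and three weakly predictive ones (a single
#'   predictive input each). Input dropout makes node weights reflect the
#'   difference quantitatively.
#' * `uneven_connectivity`: two top-layer nodes over ten bottom-layer
#'   nodes, A parenting 2 of them and B parenting 8; predictive genes sit
#'   under both of A's children but only one of B's. Node weights mix
#'   signal with connectivity.
#' * `uneven_connectivity_control`: the same network trained on control
#'   inputs (every gene equally predictive), quantifying the
#'   connectivity-driven part of the weights.
#'
#' The scenario's input genes are drawn (seeded) from the expressed
#' (upper) half of the synthetic baseline profile so that fold changes are
#' carried by genes with measurable counts; predictive genes carry a
#' two-fold change by default.
#'
#' @param name scenario identifier (see above).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param n_filler_inputs non-predictive filler genes per hidden node
#'   where the scenario uses fillers (default 10).
#' @param n_genes genes in the simulated transcriptome (default 1000).
#' @param n_cells simulated cells (default 2000, half per class).
#' @param reads_per_cell per-cell read depth (default 10000).
#' @param fold_change expression ratio of predictive genes (default 2).
#' @return List with elements `graph` (a [neural_graph()]), `data` (an
#'   [expression_dataset()] of raw counts), `ground_truth` (data.frame:
#'   `node`, `role`, `n_children`), and `name`.
#' @export
toy_scenario <- function(name = c("single_node", "redundant_pair",
                                  "weak_strong", "uneven_connectivity",
                                  "uneven_connectivity_control"),
                         seed = 1L, n_filler_inputs = 10, n_genes = 1000,
                         n_cells = 2000, reads_per_cell = 10000,
                         fold_change = 2) {
  name <- match.arg(name)
  baseline <- default_baseline_profile(n_genes, seed = seed)
  # scenario genes come from the expressed (upper) half of the baseline so
  # that simulated fold changes are carried by genes with measurable counts
  pool <- names(baseline)[baseline >= stats::median(baseline)]
  take <- local({
    shuffled <- with_seed(seed + 1L, sample(pool))
    used <- 0L
    function(k) {
      out <- shuffled[used + seq_len(k)]
      used <<- used + k
      out
    }
  })
  edges <- list()
  add <- function(from, to)
    edges[[length(edges) + 1L]] <<- expand.grid(from = from, to = to,
                                                stringsAsFactors = FALSE)
  gt <- NULL
  predictive <- character(0)

  if (name == "single_node") {
    pred <- take(n_filler_inputs); add(pred, "A"); add("A", "out")
    sibs <- paste0("sib", 1:3)
    for (s in sibs) { add(take(n_filler_inputs), s); add(s, "out") }
    predictive <- pred
    gt <- data.frame(node = c("A", sibs),
                     role = c("predictive", rep("nonpredictive", 3)),
                     n_children = NA_integer_)
  } else if (name == "redundant_pair") {
    pred <- take(n_filler_inputs)
    fill <- take(n_filler_inputs)
    for (h in c("A", "B")) { add(c(pred, fill), h); add(h, "out") }
    predictive <- pred
    gt <- data.frame(node = c("A", "B"), role = "redundant_predictive",
                     n_children = NA_integer_)
  } else if (name == "weak_strong") {
    # equal fan-in: strong nodes carry five predictive inputs, weak nodes
    # one, topped up with non-predictive fillers to the same total
    strong <- c("A", "B", "C"); weak <- c("D", "E", "F")
    for (h in strong) {
      g <- take(5); add(c(g, take(n_filler_inputs)), h); add(h, "out")
      predictive <- c(predictive, g)
    }
    for (h in weak) {
      g <- take(1); add(c(g, take(n_filler_inputs + 4)), h); add(h, "out")
      predictive <- c(predictive, g)
    }
    gt <- data.frame(node = c(strong, weak),
                     role = rep(c("strong", "weak"), each = 3),
                     n_children = NA_integer_)
  } else {  # uneven_connectivity / uneven_connectivity_control
    bottom <- paste0("b", 1:10)
    bottom_genes <- lapply(bottom, function(b) take(n_filler_inputs))
    names(bottom_genes) <- bottom
    for (b in bottom) add(bottom_genes[[b]], b)
    add(bottom[1:2], "A"); add(bottom[3:10], "B")
    add(c("A", "B"), "out")
    predictive <- unlist(bottom_genes[c("b1", "b2", "b3")],
                         use.names = FALSE)
    gt <- data.frame(node = c("A", "B", bottom),
                     role = c("top_sparse", "top_hub",
                              rep("predictive_child", 3),
                              rep("nonpredictive_child", 7)),
                     n_children = c(2L, 8L, rep(NA_integer_, 10)))
  }

  graph <- neural_graph(do.call(rbind, edges), output_nodes = "out")
  spec <- simulation_spec(baseline, predictive, fold_change = fold_change,
                          n_cells = n_cells,
                          reads_per_cell = reads_per_cell,
                          seed = seed + 2L)
  data <- simulate_cells(spec)
  if (name == "uneven_connectivity_control")
    data <- make_control_inputs(data, class_of_reference = "0",
                                fold_change = fold_change, seed = seed + 3L)
  list(name = name, graph = graph, data = data, ground_truth = gt,
       predictive_genes = predictive)
}

#' Documented training presets for the toy scenarios
#'
#' Returns the hyperparameters used to train each simulated scenario:
#' learning rate 0.05 throughout, with L2 coefficient 0.1 for the
#' redundant pair and 0.2 otherwise; early stopping after 20 failed
#' epochs and checkpointing at 20% validation improvement. Where dropout
#' is requested it is applied at 30%.
#'
#' @param name scenario identifier as in [toy_scenario()].
#' @param hidden_dropout,input_dropout logical: apply 30% dropout to
#'   hidden and/or input nodes.
#' @param seed integer seed.
#' @return A [train_config()].
#' @export
scenario_train_config <- function(name, hidden_dropout = FALSE,
                                  input_dropout = FALSE, seed = 1L) {
  hp <- switch(name,
               single_node = c(alpha = 0.05, lambda = 0.2),
               redundant_pair = c(alpha = 0.05, lambda = 0.1),
               weak_strong = c(alpha = 0.05, lambda = 0.2),
               uneven_connectivity = c(alpha = 0.05, lambda = 0.2),
               uneven_connectivity_control = c(alpha = 0.05, lambda = 0.2),
               stop("unknown scenario: ", name))
  train_config(alpha = hp[["alpha"]], lambda = hp[["lambda"]],
               hidden_dropout = if (isTRUE(hidden_dropout)) 0.3 else 0,
               input_dropout = if (isTRUE(input_dropout)) 0.3 else 0,
               seed = seed)
}
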