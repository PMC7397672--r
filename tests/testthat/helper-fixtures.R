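# shared fixtures: built in code, deterministic

# hand-written prior: receptor R feeds TF1 via two equal-length signaling
# paths; TF2 reachable only through a longer detour
tiny_prior <- function() {
  edges <- data.frame(
    from = c("R", "R", "S1", "S2", "R", "S3", "S4", "S5", "S6"),
    to   = c("S1", "S2", "TF1", "TF1", "S3", "S4", "S5", "S6", "TF2"),
    stringsAsFactors = FALSE)
  prior_graph(edges, categories = c(
    R = "receptor", S1 = "signaling", S2 = "signaling", S3 = "signaling",
    S4 = "signaling", S5 = "signaling", S6 = "signaling",
    TF1 = "transcription_factor", TF2 = "transcription_factor"))
}

tiny_tf_targets <- function() list(TF1 = c("g1", "g2"), TF2 = c("g2", "g3"))

# independent breadth-first distances (queue implementation, no igraph)
bfs_dist <- function(edges, from) {
  adj <- split(edges$to, edges$from)
  dist <- c()
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    for (m in adj[[n]]) if (is.null(dist[m]) || is.na(dist[m])) {
      dist[m] <- dist[n] + 1
      queue <- c(queue, m)
    }
  }
  dist
}

# small, fast scenario for unit tests of the training engine
small_scenario <- function(name = "single_node", seed = 1) {
  toy_scenario(name, seed = seed, n_genes = 120, n_cells = 240,
               reads_per_cell = 3000, n_filler_inputs = 5)
}

# assemble an untrained model around a graph, with given or zero weights
manual_model <- function(graph, theta = NULL, data = NULL,
                         config = train_config()) {
  st <- kpnn:::compile_model(graph, config)
  if (is.null(theta)) theta <- numeric(st$n_param)
  structure(list(structure = st, graph = graph, theta = theta,
                 config = config, data = data, failed = FALSE),
            class = "kpnn_model")
}

# a fake node-weight table for statistics tests
fake_weight_table <- function(W, errors = rep(0, ncol(W)),
                              condition = "actual") {
  structure(list(weights = W,
                 metrics = data.frame(replicate = seq_len(ncol(W)),
                                      seed = seq_len(ncol(W)),
                                      test_error = errors,
                                      test_auc = 1,
                                      epochs = 10),
                 condition = condition,
                 dropout = c(hidden = 0, input = 0),
                 normalized = FALSE),
            class = "node_weight_table")
}
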