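#' Serialize a trained model as tab-separated tables
#'
#' Writes three TSV files: `<prefix>_edges.tsv` (parent, child, weight; in
#' data-flow orientation), `<prefix>_biases.tsv` (node, bias), and
#' `<prefix>_normalization.tsv` (gene, min, max from the training split).
#'
#' @param model a `kpnn_model`.
#' @param prefix output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_trained_model <- function(model, prefix) {
  st <- model$structure
  edges <- do.call(rbind, lapply(st$noninput, function(j)
    data.frame(parent = st$parents[[j]], child = j,
               weight = model$theta[st$idx_w[[j]]],
               stringsAsFactors = FALSE)))
  biases <- data.frame(node = st$noninput,
                       bias = model$theta[st$idx_b],
                       stringsAsFactors = FALSE)
  nm <- model$normalization
  norm <- data.frame(gene = names(nm$gene_min), min = nm$gene_min,
                     max = nm$gene_max, row.names = NULL,
                     stringsAsFactors = FALSE)
  paths <- paste0(prefix, c("_edges.tsv", "_biases.tsv",
                            "_normalization.tsv"))
  utils::write.table(edges, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(biases, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(norm, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write a reproducibility manifest for a run
#'
#' Records the command, a configuration snapshot, the seeds, MD5 digests
#' of input files, the package version, and a timestamp, so that a run can
#' be reproduced from the manifest alone.
#'
#' @param command character description of the command executed.
#' @param config a [train_config()] or any list of parameters.
#' @param seeds named or unnamed integer vector of seeds used.
#' @param input_files character vector of input file paths to digest.
#' @param path output file (JSON).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(command, config = list(), seeds = integer(0),
                               input_files = character(0), path) {
  digests <- if (length(input_files))
    as.list(tools::md5sum(input_files)) else list()
  manifest <- list(
    command = command,
    config = unclass(config),
    seeds = as.list(seeds),
    input_digests = digests,
    package_version = as.character(utils::packageVersion("kpnn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Deterministic example prior graph and TF-target map
#'
#' A small synthetic prior-knowledge graph (receptor, signaling layer with
#' feedback cycles, transcription factors, target genes) used in examples
#' and as the source of the bundled toy network fixtures. Built in code
#' with a fixed seed, so it is identical across installations.
#'
#' @param n_signaling,n_tfs,n_genes node counts per category.
#' @param seed integer seed.
#' @return List with `prior` (a [prior_graph()]), `tf_targets` (named
#'   list), and `receptor` (the designated output node).
#' @export
example_prior_graph <- function(n_signaling = 20, n_tfs = 10, n_genes = 40,
                                seed = 42L) {
  sig <- paste0("s", seq_len(n_signaling))
  tfs <- paste0("tf", seq_len(n_tfs))
  genes <- paste0("g", seq_len(n_genes))
  receptor <- "R0"
  with_seed(seed, {
    edges <- list()
    # receptor into a few entry kinases
    entry <- sample(sig, 4)
    edges[[1]] <- data.frame(from = receptor, to = entry,
                             stringsAsFactors = FALSE)
    # signaling cascade: forward edges plus a few feedback edges (cycles)
    for (i in seq_len(n_signaling)) {
      k <- sample(1:3, 1)
      targets <- sample(setdiff(sig, sig[i]), k)
      edges[[length(edges) + 1L]] <-
        data.frame(from = sig[i], to = targets, stringsAsFactors = FALSE)
    }
    # signaling proteins activate TFs
    for (tf in tfs) {
      parents <- sample(sig, sample(1:3, 1))
      edges[[length(edges) + 1L]] <-
        data.frame(from = parents, to = tf, stringsAsFactors = FALSE)
    }
    tf_targets <- lapply(tfs, function(tf) sort(sample(genes,
                                                       sample(4:10, 1))))
    names(tf_targets) <- tfs
  })
  edges <- unique(do.call(rbind, edges))
  categories <- c(stats::setNames(rep("receptor", 1), receptor),
                  stats::setNames(rep("signaling", n_signaling), sig),
                  stats::setNames(rep("transcription_factor", n_tfs), tfs),
                  stats::setNames(rep("gene", n_genes), genes))
  list(prior = prior_graph(edges, categories = categories),
       tf_targets = tf_targets,
       receptor = receptor)
}
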