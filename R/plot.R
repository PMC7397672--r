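#' Plot node weights across replicate networks
#'
#' Boxplots of per-node weights over replicates, split by group when the
#' table carries one -- the standard view of which signaling proteins and
#' transcription factors the trained networks rely on.
#'
#' @param table a `node_weight_table`.
#' @return A ggplot object.
#' @export
plot_node_weights <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  W <- table$weights
  df <- data.frame(node = rep(rownames(W), ncol(W)),
                   weight = as.vector(W),
                   replicate = rep(colnames(W), each = nrow(W)))
  if (!is.null(table$groups))
    df$group <- rep(as.character(table$groups), each = nrow(W))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$weight)) +
    ggplot2::labs(x = NULL, y = "node weight") +
    ggplot2::theme_minimal()
  if (is.null(df$group)) p + ggplot2::geom_boxplot()
  else p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data$group))
}

#' Plot a fragmentation curve
#'
#' @param curves a data.frame from [fragmentation_curve()], or a named
#'   list of such data.frames to overlay several networks.
#' @return A ggplot object.
#' @export
plot_fragmentation <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (is.data.frame(curves)) curves <- list(network = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm)
    cbind(curves[[nm]], network = nm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$removed, y = .data$components,
                                   color = .data$network)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "edges removed", y = "connected components") +
    ggplot2::theme_minimal()
}
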