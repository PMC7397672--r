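#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained model into its edge weights
#'
#' @param x a `kpnn_model`.
#' @param ... unused.
#' @return data.frame: `parent`, `child`, `weight` per edge (data-flow
#'   orientation) plus the child's bias.
#' @export
tidy.kpnn_model <- function(x, ...) {
  st <- x$structure
  do.call(rbind, lapply(st$noninput, function(j)
    data.frame(parent = st$parents[[j]], child = j,
               weight = x$theta[st$idx_w[[j]]],
               bias = x$theta[st$idx_b[j]],
               row.names = NULL, stringsAsFactors = FALSE)))
}

#' One-row summary of a trained model
#'
#' @param x a `kpnn_model`.
#' @param ... unused.
#' @return data.frame with node/edge counts, epochs run, checkpoint epoch,
#'   test error and mean test AUC.
#' @export
glance.kpnn_model <- function(x, ...) {
  data.frame(n_inputs = length(x$structure$inputs),
             n_hidden = length(x$structure$hidden),
             n_outputs = length(x$structure$outputs),
             n_edges = nrow(x$graph$edges),
             epochs = nrow(x$history),
             checkpoint_epoch = if (x$failed) NA_integer_
             else x$checkpoint$epoch,
             failed = x$failed,
             test_error = x$test_metrics$error,
             test_auc = mean(x$test_metrics$auc))
}

#' @export
tidy.kpnn_diff <- function(x, ...) as.data.frame(x)

#' @export
glance.kpnn_diff <- function(x, ...) {
  data.frame(n_nodes = nrow(x),
             n_significant = sum(x$significant),
             alpha = attr(x, "alpha"))
}
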