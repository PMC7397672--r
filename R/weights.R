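#' Perturbation-based node weights
#'
#' Quantifies the global importance of each hidden node for the network's
#' predictions: the node's activation is perturbed by `+epsilon` and
#' `-epsilon` across the selected cells, and the node weight is the
#' absolute value of the mean (over cells and outputs) difference of class
#' probabilities, divided by `2 * epsilon` -- a central-difference
#' estimate of the sensitivity of the mean prediction to the node. The
#' absolute value is taken after averaging, because the sign of a hidden
#' node's contribution is arbitrary across replicate trainings. A hidden
#' node with no path to any output has weight exactly 0.
#'
#' @param model a `kpnn_model` from [train_kpnn()].
#' @param data an [expression_dataset()]; defaults to the model's stored
#'   (full) dataset, i.e., perturbations are averaged over all cells.
#' @param epsilon perturbation magnitude (> 0); defaults to the
#'   configuration value (0.001).
#' @param state which parameters to analyze: `"final"` (the last training
#'   state, default -- under dropout the final state has experienced the
#'   full stabilizing schedule) or `"checkpoint"` (the restored
#'   best-validation model used for test evaluation).
#' @return Named non-negative numeric vector, one weight per hidden node.
#' @export
node_weights <- function(model, data = NULL, epsilon = NULL,
                         state = c("final", "checkpoint")) {
  model <- model_at_state(model, match.arg(state))
  st <- model$structure
  if (is.null(epsilon)) epsilon <- model$config$epsilon
  stopifnot(epsilon > 0)
  X <- if (is.null(data)) model$data$values else data$values
  w <- vapply(st$hidden, function(h) {
    pp <- forward(model, X, overrides = stats::setNames(list(epsilon), h))
    pm <- forward(model, X, overrides = stats::setNames(list(-epsilon), h))
    abs(mean(pp - pm)) / (2 * epsilon)
  }, 1)
  names(w) <- st$hidden
  w
}

#' Analytic sensitivity of the mean prediction to each hidden node
#'
#' Backpropagates the derivative of the mean output probability (over
#' cells and outputs) with respect to each hidden node's activation. This
#' is the closed-form quantity that the central-difference perturbation in
#' [node_weights()] estimates; it is computed by a single reverse sweep
#' and serves as an independent check of the perturbation procedure.
#'
#' @inheritParams node_weights
#' @return Named numeric vector of signed derivatives per hidden node.
#' @export
node_gradients <- function(model, data = NULL,
                           state = c("final", "checkpoint")) {
  model <- model_at_state(model, match.arg(state))
  st <- model$structure
  X <- if (is.null(data)) model$data$values else data$values
  X <- X[, st$inputs, drop = FALSE]
  fp <- forward_pass(st, model$theta, X)
  n <- nrow(X); K <- length(st$outputs)
  dA <- matrix(0, n, length(st$order), dimnames = list(NULL, st$order))
  dZ <- matrix(0, n, length(st$noninput),
               dimnames = list(NULL, st$noninput))
  zo <- fp$Z[, st$outputs, drop = FALSE]
  dZ[, st$outputs] <- stats::plogis(zo) * (1 - stats::plogis(zo)) / (n * K)
  for (j in rev(st$noninput)) {
    if (!j %in% st$outputs) {
      sig <- stats::plogis(fp$Z[, j])
      dZ[, j] <- dA[, j] * sig * (1 - sig)
    }
    pj <- st$parents[[j]]
    dA[, pj] <- dA[, pj, drop = FALSE] +
      outer(dZ[, j], model$theta[st$idx_w[[j]]])
  }
  vapply(st$hidden, function(h) sum(dA[, h]), 1)
}

# swap in the requested parameter state ("final" = last epoch,
# "checkpoint" = restored best-validation parameters)
model_at_state <- function(model, state) {
  if (state == "final" && !is.null(model$theta_last))
    model$theta <- model$theta_last
  model
}

#' Train replicate networks and collect node weights
#'
#' Repeats training of the same network on the same dataset with derived
#' seeds (`base_seed + replicate index`), computes perturbation node
#' weights for each replicate, and assembles a node-weight table (hidden
#' nodes x replicates) plus per-replicate performance metrics. A
#' replicate that never checkpoints is recorded as failed and its weights
#' are excluded with a warning.
#'
#' @param graph a [neural_graph()].
#' @param data an [expression_dataset()] of raw counts.
#' @param config a [train_config()]; each replicate uses
#'   `base_seed + index` as its seed.
#' @param n_replicates number of replicate trainings.
#' @param base_seed integer base seed.
#' @param condition label stored with the table (e.g., `"actual"` or
#'   `"control_inputs"`).
#' @param weight_state parameter state analyzed by [node_weights()].
#' @return An object of class `node_weight_table`: list with `weights`
#'   (matrix hidden nodes x replicates), `metrics` (data.frame with test
#'   error and AUC per replicate), and metadata columns (`condition`,
#'   `dropout`, `normalized`).
#' @export
run_replicates <- function(graph, data, config = train_config(),
                           n_replicates = 10, base_seed = 1L,
                           condition = "actual",
                           weight_state = c("final", "checkpoint")) {
  weight_state <- match.arg(weight_state)
  weights <- list(); metrics <- list()
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    model <- suppressWarnings(train_kpnn(graph, data, cfg))
    if (model$failed) {
      warning("replicate ", i, " never checkpointed; excluded")
      next
    }
    weights[[length(weights) + 1L]] <- node_weights(model,
                                                    state = weight_state)
    metrics[[length(metrics) + 1L]] <-
      data.frame(replicate = i, seed = cfg$seed,
                 test_error = model$test_metrics$error,
                 test_auc = mean(model$test_metrics$auc),
                 epochs = nrow(model$history),
                 stringsAsFactors = FALSE)
  }
  if (!length(weights)) stop("all replicates failed to checkpoint")
  W <- do.call(cbind, weights)
  colnames(W) <- paste0("rep", vapply(metrics, function(m) m$replicate, 1))
  structure(list(weights = W,
                 metrics = do.call(rbind, metrics),
                 condition = condition,
                 dropout = c(hidden = config$hidden_dropout,
                             input = config$input_dropout),
                 normalized = FALSE),
            class = "node_weight_table")
}

#' @export
print.node_weight_table <- function(x, ...) {
  cat(sprintf("<node_weight_table> %d nodes x %d replicates (%s%s)\n",
              nrow(x$weights), ncol(x$weights), x$condition,
              if (x$normalized) ", quantile-normalized" else ""))
  invisible(x)
}

#' Aggregate replicate node-weight tables across groups
#'
#' Removes replicates whose test error exceeds the performance filter
#' (only highly predictive networks are interpreted; 0.2 is the documented
#' default for real data, 0.1 for simulations), optionally downsamples
#' every group to the size of the smallest group (seeded), and quantile
#' normalizes node weights across all retained replicates so that every
#' replicate column shares the same distribution.
#'
#' @param tables list of `node_weight_table` objects, one group each; the
#'   group label defaults to each table's `condition`.
#' @param performance_filter maximum test error for a replicate to be
#'   retained (`Inf` disables the filter).
#' @param group_downsample downsample groups to the smallest group size.
#' @param quantile_normalize apply [limma::normalizeQuantiles()] across
#'   replicate columns.
#' @param seed integer seed for the downsampling draw.
#' @return A combined `node_weight_table` with a `groups` factor aligned
#'   to the columns of `weights`.
#' @export
aggregate_replicates <- function(tables, performance_filter = 0.2,
                                 group_downsample = TRUE,
                                 quantile_normalize = TRUE, seed = 1L) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "node_weight_table")))
  labels <- vapply(tables, function(t) t$condition, "")
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  kept <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    keep <- t$metrics$test_error <= performance_filter
    if (!any(keep))
      stop("performance filter ", performance_filter,
           " removes every replicate of group '", labels[i], "'")
    list(weights = t$weights[, keep, drop = FALSE],
         metrics = t$metrics[keep, , drop = FALSE])
  })
  if (group_downsample && length(kept) > 1) {
    n_min <- min(vapply(kept, function(k) ncol(k$weights), 1L))
    kept <- with_seed(seed, lapply(kept, function(k) {
      sel <- sort(sample.int(ncol(k$weights), n_min))
      list(weights = k$weights[, sel, drop = FALSE],
           metrics = k$metrics[sel, , drop = FALSE])
    }))
  }
  W <- do.call(cbind, lapply(kept, function(k) k$weights))
  groups <- factor(rep(labels, vapply(kept, function(k) ncol(k$weights), 1L)))
  colnames(W) <- make.unique(colnames(W))
  if (quantile_normalize)
    W <- as.matrix(limma::normalizeQuantiles(as.data.frame(W)))
  structure(list(weights = W,
                 metrics = do.call(rbind, lapply(kept, function(k) k$metrics)),
                 groups = groups,
                 condition = paste(labels, collapse = " vs "),
                 normalized = quantile_normalize),
            class = "node_weight_table")
}

#' Differential node-weight statistics between replicate groups
#'
#' Tests, for every hidden node, whether its (normalized) weights differ
#' between two groups of replicate networks -- e.g., networks trained on
#' actual data vs on control inputs, which normalizes node importance for
#' the network's uneven connectivity. The default test is a two-sided
#' Welch t-test; when covariates are supplied, a per-node linear model is
#' fitted with coefficients for the group and each covariate and the group
#' coefficient is tested. P values are Benjamini-Hochberg adjusted and
#' nodes with adjusted p below `alpha` are flagged significant. A node
#' with zero variance in both groups is assigned p = 1 and flagged
#' `degenerate`.
#'
#' @param table a `node_weight_table` with a `groups` factor (from
#'   [aggregate_replicates()]), or a plain weights matrix.
#' @param groups optional group labels overriding the table's.
#' @param covariates optional data.frame of per-replicate covariates.
#' @param alpha significance threshold on the adjusted p value.
#' @return A data.frame of class `kpnn_diff` with one row per hidden node:
#'   `node`, group means, `mean_diff` (group 1 minus group 2), `statistic`,
#'   `p_value`, `p_adj`, `significant`, `degenerate`.
#' @export
differential_node_weights <- function(table, groups = NULL,
                                      covariates = NULL, alpha = 0.05) {
  W <- if (inherits(table, "node_weight_table")) table$weights else table
  if (is.null(groups) && inherits(table, "node_weight_table"))
    groups <- table$groups
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("both groups need >= 2 replicates")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  res <- lapply(rownames(W), function(node) {
    x1 <- W[node, groups == g1]; x2 <- W[node, groups == g2]
    degenerate <- stats::var(x1) == 0 && stats::var(x2) == 0
    if (degenerate) {
      stat <- 0; p <- 1
    } else if (is.null(covariates)) {
      tt <- stats::t.test(x1, x2)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      df <- data.frame(w = W[node, ], group = groups, covariates)
      fit <- stats::lm(w ~ ., data = df)
      co <- summary(fit)$coefficients
      row <- grep("^group", rownames(co))[1]
      stat <- co[row, "t value"]; p <- co[row, "Pr(>|t|)"]
    }
    data.frame(node = node, mean_1 = mean(x1), mean_2 = mean(x2),
               mean_diff = mean(x1) - mean(x2), statistic = stat,
               p_value = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  names(res)[names(res) == "mean_1"] <- paste0("mean_", g1)
  names(res)[names(res) == "mean_2"] <- paste0("mean_", g2)
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adj < alpha
  attr(res, "groups") <- c(g1, g2)
  attr(res, "alpha") <- alpha
  class(res) <- c("kpnn_diff", "data.frame")
  res
}

#' Write a node-weight table or differential result as TSV
#'
#' @param x a `node_weight_table` or `kpnn_diff`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_node_weights <- function(x, path) {
  if (inherits(x, "node_weight_table"))
    x <- data.frame(node = rownames(x$weights), x$weights,
                    check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
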