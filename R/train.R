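#' Training configuration
#'
#' Collects every tunable parameter of the training procedure. The
#' defaults follow the documented simulation protocol: learning rate 0.05
#' and L2 coefficient 0.2, early stopping after 20 failed epochs, models
#' checkpointed when the validation error drops by at least 20% relative
#' to the last checkpoint, and per-node caps on hidden dropout so that
#' nodes with a single parent are never dropped, nodes with two parents
#' are dropped at most 10% of the time, and nodes with three parents at
#' most 30%.
#'
#' @param alpha Adam learning rate (> 0).
#' @param lambda L2 regularization coefficient on edge weights (>= 0); the
#'   penalty added to the loss is `lambda * sum(w^2)`.
#' @param hidden_dropout,input_dropout dropout rates in `[0, 1)` applied
#'   per sample and training step to hidden and input nodes (inverted
#'   scaling on retained nodes).
#' @param parent_dropout_caps named numeric vector mapping a parent count
#'   to the maximum hidden-dropout rate for nodes with that many parents;
#'   counts not listed are uncapped.
#' @param patience number of failed epochs tolerated since the last
#'   checkpoint before training stops.
#' @param save_improvement relative validation-error decrease (vs the last
#'   checkpoint) required to save a new checkpoint.
#' @param plateau_tolerance relative training-loss decrease below which an
#'   epoch counts as plateaued (hence failed).
#' @param minibatch_size cells per minibatch; `NULL` trains full-batch.
#' @param max_epochs hard cap on training epochs.
#' @param epsilon perturbation magnitude used for node weights.
#' @param seed integer seed governing initialization, the data split, and
#'   dropout masks.
#' @return An object of class `train_config`.
#' @export
train_config <- function(alpha = 0.05, lambda = 0.2,
                         hidden_dropout = 0, input_dropout = 0,
                         parent_dropout_caps = c("1" = 0, "2" = 0.1,
                                                 "3" = 0.3),
                         patience = 20, save_improvement = 0.2,
                         plateau_tolerance = 1e-3, minibatch_size = NULL,
                         max_epochs = 2000, epsilon = 0.001, seed = 1L) {
  stopifnot(alpha > 0, lambda >= 0, epsilon > 0, patience >= 1,
            hidden_dropout >= 0, hidden_dropout < 1,
            input_dropout >= 0, input_dropout < 1)
  structure(list(alpha = alpha, lambda = lambda,
                 hidden_dropout = hidden_dropout,
                 input_dropout = input_dropout,
                 parent_dropout_caps = parent_dropout_caps,
                 patience = patience, save_improvement = save_improvement,
                 plateau_tolerance = plateau_tolerance,
                 minibatch_size = minibatch_size, max_epochs = max_epochs,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "train_config")
}

# ---- model compilation ----------------------------------------------------

# Freeze graph structure into index form: topological node order, parent
# lists, a flat parameter vector (edge weights then biases), and effective
# per-node hidden dropout rates.
compile_model <- function(graph, config) {
  ord <- topological_order(graph)
  inputs <- intersect(ord, input_nodes(graph))
  noninput <- setdiff(ord, inputs)
  parents <- lapply(noninput, function(j) graph$edges$from[graph$edges$to == j])
  names(parents) <- noninput
  n_par <- vapply(parents, length, 1L)
  # flat parameter layout: per-node weight blocks, then one bias per node
  idx_w <- vector("list", length(noninput)); names(idx_w) <- noninput
  pos <- 0L
  for (j in noninput) {
    idx_w[[j]] <- pos + seq_len(n_par[[j]])
    pos <- pos + n_par[[j]]
  }
  idx_b <- pos + seq_along(noninput)
  names(idx_b) <- noninput
  n_param <- pos + length(noninput)
  caps <- config$parent_dropout_caps
  p_eff <- vapply(noninput, function(j) {
    cap <- caps[as.character(n_par[[j]])]
    if (is.na(cap)) config$hidden_dropout
    else min(config$hidden_dropout, cap)
  }, 1)
  p_eff[noninput %in% output_nodes(graph)] <- 0   # outputs never dropped
  list(graph = graph, order = ord, inputs = inputs, noninput = noninput,
       outputs = intersect(ord, output_nodes(graph)),
       hidden = setdiff(noninput, output_nodes(graph)),
       parents = parents, idx_w = idx_w, idx_b = idx_b,
       n_param = n_param, p_eff = p_eff, n_weights = pos)
}

# Glorot-uniform initialization on +-sqrt(6/(fan_in + fan_out)) per edge
init_params <- function(st) {
  fan_out <- table(factor(st$graph$edges$from,
                          levels = unique(c(st$graph$edges$from,
                                            st$graph$edges$to))))
  theta <- numeric(st$n_param)
  for (j in st$noninput) {
    pj <- st$parents[[j]]
    fin <- length(pj)
    lim <- sqrt(6 / (fin + as.numeric(fan_out[pj])))
    theta[st$idx_w[[j]]] <- stats::runif(fin, -lim, lim)
  }
  theta   # biases start at 0
}

# forward pass over a cells x inputs matrix X (columns in st$inputs order);
# returns activations (post-dropout where masked) and pre-activation logits
forward_pass <- function(st, theta, X, overrides = NULL, hmask = NULL,
                         imask = NULL, input_dropout = 0) {
  n <- nrow(X)
  A <- matrix(0, n, length(st$order), dimnames = list(NULL, st$order))
  Xi <- X
  if (!is.null(imask)) Xi <- Xi * imask / (1 - input_dropout)
  A[, st$inputs] <- Xi
  if (!is.null(overrides)) {
    for (nm in intersect(names(overrides), st$inputs))
      A[, nm] <- A[, nm] + overrides[[nm]]
  }
  Z <- matrix(0, n, length(st$noninput), dimnames = list(NULL, st$noninput))
  for (j in st$noninput) {
    pj <- st$parents[[j]]
    z <- A[, pj, drop = FALSE] %*% theta[st$idx_w[[j]]] + theta[st$idx_b[j]]
    a <- stats::plogis(z)
    if (!is.null(overrides) && j %in% names(overrides))
      a <- a + overrides[[j]]
    if (!is.null(hmask) && st$p_eff[j] > 0)
      a <- a * hmask[, j] / (1 - st$p_eff[j])
    A[, j] <- a
    Z[, j] <- z
  }
  list(A = A, Z = Z)
}

# numerically stable per-element sigmoid cross-entropy from logits
ce_from_logits <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

# weighted cross-entropy + L2 given a forward pass; the cross-entropy is
# summed over samples and outputs (class weights already sum to N), so the
# documented L2 coefficients keep their intended relative strength
loss_value <- function(st, theta, fp, y, sample_w, lambda) {
  zo <- fp$Z[, st$outputs, drop = FALSE]
  ce <- rowSums(ce_from_logits(zo, y))
  sum(sample_w * ce) + lambda * sum(theta[seq_len(st$n_weights)]^2)
}

# backward pass: gradient of loss_value wrt theta, matching the masks and
# scaling used in the forward pass
backward_pass <- function(st, theta, fp, y, sample_w, lambda,
                          hmask = NULL) {
  n <- nrow(fp$A)
  grad <- numeric(st$n_param)
  dA <- matrix(0, n, length(st$order), dimnames = list(NULL, st$order))
  dZ <- matrix(0, n, length(st$noninput), dimnames = list(NULL, st$noninput))
  zo <- fp$Z[, st$outputs, drop = FALSE]
  dZ[, st$outputs] <- sample_w * (stats::plogis(zo) - y)
  for (j in rev(st$noninput)) {
    if (!j %in% st$outputs) {
      daj <- dA[, j]
      if (!is.null(hmask) && st$p_eff[j] > 0)
        daj <- daj * hmask[, j] / (1 - st$p_eff[j])
      sig <- stats::plogis(fp$Z[, j])
      dZ[, j] <- daj * sig * (1 - sig)
    }
    pj <- st$parents[[j]]
    dzj <- dZ[, j]
    grad[st$idx_w[[j]]] <- crossprod(fp$A[, pj, drop = FALSE], dzj)
    grad[st$idx_b[j]] <- sum(dzj)
    dA[, pj] <- dA[, pj, drop = FALSE] +
      outer(dzj, theta[st$idx_w[[j]]])
  }
  grad[seq_len(st$n_weights)] <- grad[seq_len(st$n_weights)] +
    2 * lambda * theta[seq_len(st$n_weights)]
  grad
}

# ---- training -------------------------------------------------------------

#' Train a neural graph on an expression dataset
#'
#' Fits edge weights and biases by Adam on the class-weighted sigmoid
#' cross-entropy with L2 regularization. Each epoch draws fresh dropout
#' masks per sample (hidden nodes at their capped rates, input nodes at
#' the input rate) and takes one optimization step per (mini)batch. An
#' epoch is "failed" if the training loss plateaus or the validation
#' error increases; the model is checkpointed whenever the validation
#' error improves by at least `save_improvement` relative to the last
#' checkpoint, which also resets the failed-epoch counter. After
#' `patience` failed epochs the last checkpoint is restored and test-set
#' metrics are computed.
#'
#' Genes present in the graph but absent from the data are pruned (with
#' removal of hidden nodes left without any input path) before training,
#' with a warning. If the dataset is not yet partitioned or normalized,
#' [split_dataset()] and [normalize_expression()] are applied using the
#' configuration seed.
#'
#' @param graph a [neural_graph()]; its number of output nodes must match
#'   the number of label classes (1 output for binary labels).
#' @param data an [expression_dataset()].
#' @param config a [train_config()].
#' @return An object of class `kpnn_model` with the fitted parameters,
#'   per-epoch history, checkpoint record, and test metrics.
#' @export
train_kpnn <- function(graph, data, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  graph <- prune_to_genes(graph, data$genes)
  data <- subset_genes(data, input_nodes(graph))
  if (is.null(data$partition))
    data <- split_dataset(data, seed = config$seed)
  data <- normalize_expression(data)
  st <- compile_model(graph, config)
  y_all <- label_matrix(data$labels)
  if (ncol(y_all) != length(st$outputs))
    stop("graph has ", length(st$outputs), " output node(s) but labels ",
         "imply ", ncol(y_all))
  cw <- class_weights(data$labels)
  sw_all <- as.numeric(cw[as.character(data$labels)])
  X_all <- data$values[, st$inputs, drop = FALSE]
  tr <- data$partition == "train"
  va <- data$partition == "validation"
  Xt <- X_all[tr, , drop = FALSE]; yt <- y_all[tr, , drop = FALSE]
  swt <- sw_all[tr]
  Xv <- X_all[va, , drop = FALSE]; yv <- y_all[va, , drop = FALSE]

  p_i <- config$input_dropout
  use_hmask <- any(st$p_eff > 0)
  drop_cols <- st$noninput[st$p_eff > 0]

  history <- list()
  with_seed(config$seed, {
    theta <- init_params(st)
    theta0 <- theta
    m <- numeric(st$n_param); v <- numeric(st$n_param); tstep <- 0
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8

    eval_err <- function(th, X, y) {
      p <- stats::plogis(forward_pass(st, th, X)$Z[, st$outputs,
                                                   drop = FALSE])
      mean(abs(y - p))
    }
    train_loss <- function(th) {
      loss_value(st, th, forward_pass(st, th, Xt), yt, swt, config$lambda)
    }

    prev_loss <- train_loss(theta)
    prev_val <- eval_err(theta, Xv, yv)
    ckpt_err <- prev_val
    ckpt <- NULL
    fails <- 0L
    n_tr <- nrow(Xt)
    for (epoch in seq_len(config$max_epochs)) {
      batches <- if (is.null(config$minibatch_size)) list(seq_len(n_tr))
      else split(sample.int(n_tr), ceiling(seq_len(n_tr) /
                                             config$minibatch_size))
      for (bi in batches) {
        Xb <- Xt[bi, , drop = FALSE]
        hmask <- NULL
        if (use_hmask) {
          hmask <- matrix(1, length(bi), length(st$noninput),
                          dimnames = list(NULL, st$noninput))
          for (j in drop_cols)
            hmask[, j] <- stats::rbinom(length(bi), 1, 1 - st$p_eff[j])
        }
        imask <- NULL
        if (p_i > 0)
          imask <- matrix(stats::rbinom(length(bi) * ncol(Xb), 1, 1 - p_i),
                          nrow = length(bi))
        fp <- forward_pass(st, theta, Xb, hmask = hmask, imask = imask,
                           input_dropout = p_i)
        g <- backward_pass(st, theta, fp, yt[bi, , drop = FALSE], swt[bi],
                           config$lambda, hmask = hmask)
        tstep <- tstep + 1
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        theta <- theta - config$alpha * (m / (1 - b1^tstep)) /
          (sqrt(v / (1 - b2^tstep)) + adam_eps)
      }
      cur_loss <- train_loss(theta)
      cur_val <- eval_err(theta, Xv, yv)
      # failed epoch: training loss plateaued (arrival at a minimum) or
      # validation error above the checkpointed best (overfitting)
      failed <- ((prev_loss - cur_loss) / abs(prev_loss) <
                   config$plateau_tolerance) || (cur_val > ckpt_err)
      saved <- FALSE
      if (cur_val <= (1 - config$save_improvement) * ckpt_err) {
        ckpt <- list(theta = theta, epoch = epoch, val_error = cur_val)
        ckpt_err <- cur_val
        fails <- 0L
        saved <- TRUE
      } else if (failed) fails <- fails + 1L
      history[[epoch]] <- c(epoch = epoch, train_loss = cur_loss,
                            val_error = cur_val, failed = as.numeric(failed),
                            saved = as.numeric(saved))
      prev_loss <- cur_loss; prev_val <- cur_val
      if (fails >= config$patience) break
    }
  })
  failed_run <- is.null(ckpt)
  if (failed_run) {
    warning("no checkpoint was ever saved; returning the initial model")
    theta_final <- theta0
  } else theta_final <- ckpt$theta

  model <- structure(
    list(structure = st, graph = graph, theta = theta_final,
         theta_last = theta, config = config, data = data,
         normalization = data$normalization,
         history = do.call(rbind, history),
         checkpoint = if (failed_run) NULL else ckpt[c("epoch", "val_error")],
         failed = failed_run),
    class = "kpnn_model")
  model$test_metrics <- evaluate_model(model, "test")
  model
}

# drop graph input nodes missing from the data, then hidden nodes left
# without any parent (orphan cleanup), repeating until stable
prune_to_genes <- function(graph, genes) {
  missing <- setdiff(input_nodes(graph), genes)
  if (!length(missing)) return(graph)
  warning(length(missing), " graph input gene(s) absent from data; pruned")
  edges <- graph$edges
  drop <- missing
  while (length(drop)) {
    edges <- edges[!(edges$from %in% drop), , drop = FALSE]
    if (!nrow(edges)) stop("pruning removed every edge of the graph")
    sources <- setdiff(unique(edges$from), unique(edges$to))
    drop <- setdiff(sources, c(genes, output_nodes(graph)))
  }
  neural_graph(edges, output_nodes = output_nodes(graph))
}

#' @export
print.kpnn_model <- function(x, ...) {
  cat(sprintf(
    "<kpnn_model> %d parameters; %s; test error %.4f\n",
    x$structure$n_param,
    if (x$failed) "no checkpoint saved (failed run)"
    else sprintf("checkpoint at epoch %d", x$checkpoint$epoch),
    x$test_metrics$error))
  invisible(x)
}

#' Forward evaluation of a trained model
#'
#' Evaluates the network in topological order on normalized input vectors:
#' each hidden/output activation is the sigmoid of its weighted inputs
#' plus bias. Optional additive overrides are applied to designated node
#' activations before propagation (the mechanism behind perturbation node
#' weights), and optional dropout masks reproduce training-time forward
#' passes.
#'
#' @param model a `kpnn_model` from [train_kpnn()].
#' @param inputs cells x genes matrix of normalized values with columns
#'   covering the model's input nodes; defaults to the model's stored
#'   dataset.
#' @param overrides named list/vector of additive activation deltas.
#' @param hidden_mask,input_mask optional 0/1 dropout masks (cells x
#'   nodes); retained nodes are scaled by the inverted dropout factor.
#' @return Matrix of per-output class probabilities (cells x outputs).
#' @export
forward <- function(model, inputs = NULL, overrides = NULL,
                    hidden_mask = NULL, input_mask = NULL) {
  st <- model$structure
  if (is.null(inputs)) inputs <- model$data$values
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), st$order)
    if (length(bad)) stop("override on nonexistent node(s): ",
                          paste(bad, collapse = ", "))
  }
  miss <- setdiff(st$inputs, colnames(inputs))
  if (length(miss)) stop("input matrix missing gene(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  X <- inputs[, st$inputs, drop = FALSE]
  fp <- forward_pass(st, model$theta, X, overrides = overrides,
                     hmask = hidden_mask, imask = input_mask,
                     input_dropout = model$config$input_dropout)
  p <- fp$A[, st$outputs, drop = FALSE]
  rownames(p) <- rownames(inputs)
  p
}

#' Loss of a model on a batch
#'
#' Class-weighted sigmoid cross-entropy on the output logits, summed over
#' samples and outputs (per-class weights sum to the number of samples),
#' plus `lambda` times the sum of squared edge weights.
#'
#' @param model a `kpnn_model`.
#' @param inputs cells x genes normalized matrix.
#' @param y cells x outputs 0/1 target matrix.
#' @param sample_weights per-sample weights (e.g., from [class_weights()]).
#' @param lambda L2 coefficient; defaults to the model's configuration.
#' @return Scalar loss.
#' @export
model_loss <- function(model, inputs, y, sample_weights = 1,
                       lambda = model$config$lambda) {
  st <- model$structure
  X <- inputs[, st$inputs, drop = FALSE]
  y <- as.matrix(y)
  if (nrow(y) == 0) stop("batch is empty")
  sw <- rep_len(sample_weights, nrow(y))
  loss_value(st, model$theta, forward_pass(st, model$theta, X), y, sw, lambda)
}

#' Evaluate prediction performance on a partition
#'
#' The error is the mean absolute difference between labels and predicted
#' class probabilities; ROC AUC is computed per output by the rank
#' statistic (Mann-Whitney). A partition containing a single class yields
#' `NA` AUC.
#'
#' @param model a `kpnn_model`.
#' @param partition `"train"`, `"validation"`, or `"test"`.
#' @return List with elements `error` and `auc` (one value per output).
#' @export
evaluate_model <- function(model, partition = "test") {
  data <- model$data
  sel <- data$partition == partition
  if (!any(sel)) stop("partition is empty: ", partition)
  p <- forward(model, data$values[sel, , drop = FALSE])
  y <- label_matrix(data$labels)[sel, , drop = FALSE]
  auc <- vapply(seq_len(ncol(y)), function(k) rank_auc(p[, k], y[, k]), 1)
  names(auc) <- model$structure$outputs
  list(error = mean(abs(y - p)), auc = auc)
}

# ROC AUC via the rank-sum statistic; NA when one class is absent
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
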