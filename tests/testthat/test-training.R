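test_that("dataset splits have the documented sizes and are seeded", {
  base <- default_baseline_profile(20, seed = 1)
  mk <- function(n) simulate_cells(simulation_spec(base, names(base)[1],
                                                   n_cells = n,
                                                   reads_per_cell = 100))
  d10 <- split_dataset(mk(10), seed = 5)
  expect_equal(as.integer(table(factor(d10$partition,
                                       c("train", "validation", "test")))),
               c(6L, 2L, 2L))
  d5 <- split_dataset(mk(5), seed = 5)
  expect_equal(sum(d5$partition == "train"), 3L)
  expect_equal(sum(d5$partition == "validation"), 1L)
  expect_identical(split_dataset(mk(10), seed = 7)$partition,
                   split_dataset(mk(10), seed = 7)$partition)
  expect_error(split_dataset(mk(4)), "at least 5")
})

test_that("normalization is min-max on log TPM with training-split factors", {
  # gc is a deep constant background so per-cell totals vary smoothly;
  # gb is entirely unexpressed (constant after TPM)
  m <- cbind(ga = c(0, 10, 4, 20), gb = c(0, 0, 0, 0),
             gc = c(100, 100, 100, 100))
  rownames(m) <- paste0("c", 1:4)
  d <- expression_dataset(m, labels = c(0, 1, 0, 1))
  d$partition <- c("train", "train", "test", "test")
  expect_warning(dn <- normalize_expression(d), "constant")
  # training endpoints map to 0 and 1
  expect_equal(unname(dn$values[1:2, "ga"]), c(0, 1))
  # test cell above the training max is not clipped
  expect_gt(dn$values[4, "ga"], 1)
  # unexpressed gene flagged and mapped to zero
  expect_true("gb" %in% dn$normalization$flagged_constant)
  expect_equal(unname(dn$values[, "gb"]), rep(0, 4))
  # already-normalized data pass through unchanged
  expect_identical(normalize_expression(dn)$values, dn$values)
})

test_that("class weights follow the inverse-frequency formula", {
  expect_equal(unname(class_weights(c(0, 0, 1, 1))), c(1, 1))
  w <- class_weights(c("A", "A", "A", "B"))
  expect_equal(unname(w), c(2 / 3, 2))
  # conservation: weighted sample count equals N
  set.seed(1)
  for (i in 1:50) {
    lab <- sample(c("x", "y", "z"), 30, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
    if (length(unique(lab)) < 2) next
    w <- class_weights(lab)
    expect_equal(sum(w[lab]), 30)
  }
  expect_error(class_weights(c("A", "A")), "two classes")
})

test_that("forward evaluation matches hand-computed sigmoid chains", {
  chain <- neural_graph(data.frame(from = c("g", "h"), to = c("h", "out")))
  # all weights/biases zero: every activation 0.5
  m0 <- manual_model(chain)
  X <- matrix(1, 1, 1, dimnames = list("c1", "g"))
  expect_equal(unname(forward(m0, X)[1, 1]),
               plogis(0 * 0.5))   # = 0.5
  # weights 1, biases 0: out = sigmoid(sigmoid(1))
  st <- m0$structure
  theta <- numeric(st$n_param)
  theta[st$idx_w[["h"]]] <- 1; theta[st$idx_w[["out"]]] <- 1
  m1 <- manual_model(chain, theta)
  expect_equal(unname(forward(m1, X)[1, 1]), plogis(plogis(1)))
  # additive override shifts the hidden activation before propagation
  p <- forward(m1, X, overrides = list(h = 0.1))
  expect_equal(unname(p[1, 1]), plogis(plogis(1) + 0.1))
  expect_error(forward(m1, X, overrides = list(zz = 1)), "nonexistent")
})

test_that("output probabilities stay inside (0, 1)", {
  chain <- neural_graph(data.frame(from = c("g", "h"), to = c("h", "out")))
  set.seed(2)
  for (i in 1:20) {
    m <- manual_model(chain, rnorm(4, sd = 3))
    p <- forward(m, matrix(rnorm(1), 1, 1, dimnames = list(NULL, "g")))
    expect_true(p > 0 && p < 1)
  }
})

test_that("the loss has its closed forms", {
  chain <- neural_graph(data.frame(from = c("g", "h"), to = c("h", "out")))
  st <- kpnn:::compile_model(chain, train_config())
  X <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "g"))
  y <- matrix(c(1, 0), 2, 1)
  # all-zero weights, lambda > 0: pure cross-entropy at p = 0.5,
  # i.e., sum over samples of w * log(2)
  m0 <- manual_model(chain)
  expect_equal(model_loss(m0, X, y, sample_weights = c(1, 1), lambda = 0.5),
               2 * log(2))
  # doubling lambda adds exactly lambda * sum(w^2)
  theta <- rnorm(st$n_param); m1 <- manual_model(chain, theta)
  sw2 <- sum(theta[seq_len(st$n_weights)]^2)
  l1 <- model_loss(m1, X, y, lambda = 0.3)
  l2 <- model_loss(m1, X, y, lambda = 0.6)
  expect_equal(l2 - l1, 0.3 * sw2)
  # near-perfect confident predictions, lambda = 0: loss near 0
  theta2 <- numeric(st$n_param)
  theta2[st$idx_w[["h"]]] <- 50; theta2[st$idx_b["h"]] <- -25
  theta2[st$idx_w[["out"]]] <- 80; theta2[st$idx_b["out"]] <- -40
  m2 <- manual_model(chain, theta2)
  expect_lt(model_loss(m2, X, y, lambda = 0), 1e-6)
  expect_error(model_loss(m2, X[0, , drop = FALSE], y[0, , drop = FALSE]),
               "empty")
})

test_that("backpropagated gradients match central finite differences", {
  ex <- small_scenario("single_node", seed = 6)
  cfg <- train_config(max_epochs = 1, patience = 1, seed = 3)
  m <- suppressWarnings(train_kpnn(ex$graph, ex$data, cfg))
  st <- m$structure
  X <- m$data$values[1:15, st$inputs, drop = FALSE]
  y <- kpnn:::label_matrix(m$data$labels)[1:15, , drop = FALSE]
  sw <- rep(1.3, 15)
  set.seed(4)
  theta <- rnorm(st$n_param, 0, 0.4)
  f <- function(th) kpnn:::loss_value(st, th, kpnn:::forward_pass(st, th, X),
                                      y, sw, 0.2)
  g <- kpnn:::backward_pass(st, theta,
                            kpnn:::forward_pass(st, theta, X), y, sw, 0.2)
  gn <- vapply(seq_len(st$n_param), function(i) {
    e <- numeric(st$n_param); e[i] <- 1e-5
    (f(theta + e) - f(theta - e)) / 2e-5
  }, 1)
  expect_lt(max(abs(g - gn) / pmax(abs(gn), 1e-6)), 1e-5)
})

test_that("hidden dropout is capped by parent count", {
  g <- neural_graph(data.frame(
    from = c("g1", "g2", "g3", "g1", "g2", "g1", "h1", "h2", "h3"),
    to   = c("h1", "h1", "h1", "h2", "h2", "h3", "out", "out", "out")))
  st <- kpnn:::compile_model(g, train_config(hidden_dropout = 0.3))
  expect_equal(unname(st$p_eff[c("h3", "h2", "h1")]), c(0, 0.1, 0.3))
  expect_equal(unname(st$p_eff["out"]), 0)    # outputs never dropped
})

test_that("training is deterministic and honors the stopping contract", {
  ex <- small_scenario("single_node", seed = 8)
  cfg <- train_config(alpha = 0.05, lambda = 0.2, max_epochs = 120,
                      seed = 17)
  m1 <- train_kpnn(ex$graph, ex$data, cfg)
  m2 <- train_kpnn(ex$graph, ex$data, cfg)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$history, m2$history)
  # an impossible save threshold stops training quickly with a failure flag
  cfg2 <- train_config(patience = 1, save_improvement = Inf,
                       max_epochs = 50, seed = 17)
  expect_warning(mf <- train_kpnn(ex$graph, ex$data, cfg2), "checkpoint")
  expect_true(mf$failed)
  expect_lt(nrow(mf$history), 50)
})

test_that("graph genes absent from the data are pruned with a warning", {
  ex <- small_scenario("single_node", seed = 9)
  extra <- neural_graph(rbind(ex$graph$edges,
                              data.frame(from = "ghost_gene", to = "A")),
                        output_nodes = "out")
  w <- testthat::capture_warnings(
    train_kpnn(extra, ex$data,
               train_config(max_epochs = 5, patience = 1,
                            save_improvement = Inf)))
  expect_true(any(grepl("pruned", w)))
})

test_that("evaluation reports mean absolute error and rank AUC", {
  expect_equal(kpnn:::rank_auc(c(.9, .6, .7, .2), c(1, 1, 0, 0)), 0.75)
  expect_equal(kpnn:::rank_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  expect_true(is.na(kpnn:::rank_auc(c(.5, .6), c(1, 1))))
  ex <- small_scenario("single_node", seed = 10)
  m <- suppressWarnings(train_kpnn(ex$graph, ex$data,
                                   train_config(max_epochs = 150, seed = 2)))
  ev <- evaluate_model(m, "test")
  expect_true(ev$error >= 0 && ev$error <= 1)
  expect_true(is.na(ev$auc) || (ev$auc >= 0 && ev$auc <= 1))
})

test_that("tidy and glance summarize a trained model", {
  ex <- small_scenario("single_node", seed = 11)
  m <- suppressWarnings(train_kpnn(ex$graph, ex$data,
                                   train_config(max_epochs = 80, seed = 2)))
  td <- tidy(m)
  expect_setequal(names(td), c("parent", "child", "weight", "bias"))
  expect_equal(nrow(td), nrow(m$graph$edges))
  gl <- glance(m)
  expect_equal(gl$n_edges, nrow(m$graph$edges))
  expect_equal(gl$n_outputs, 1L)
})
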