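test_that("average profiles are renormalized per-class means", {
  d <- expression_dataset(matrix(c(2, 0, 0, 2), nrow = 2, byrow = TRUE,
                                 dimnames = list(c("c1", "c2"), c("g1", "g2"))),
                          labels = c(0, 0))
  expect_equal(unname(average_profile(d, 0)), c(0.5, 0.5))
  d1 <- expression_dataset(matrix(c(3, 1), nrow = 1,
                                  dimnames = list("c1", c("g1", "g2"))),
                           labels = 1)
  expect_equal(unname(average_profile(d1, 1)), c(0.75, 0.25))
  # 10-cell fixture against an explicit loop
  set.seed(42)
  m <- matrix(rpois(40, 5), nrow = 10)
  colnames(m) <- paste0("g", 1:4)
  d10 <- expression_dataset(m, labels = rep(c("a", "b"), 5))
  manual <- sapply(1:4, function(j) sum(m[d10$labels == "a", j]) / 5)
  expect_equal(unname(average_profile(d10, "a")), manual / sum(manual))
  expect_error(average_profile(d10, "c"), "no cells")
})

test_that("simulation spec validates its invariants", {
  p <- c(g1 = 0.5, g2 = 0.5)
  expect_error(simulation_spec(c(g1 = 0.5, g2 = 0.4), "g1"), "sum to 1")
  expect_error(simulation_spec(p, "gX"), "absent")
  expect_error(simulation_spec(p, "g1", fold_change = -1), "positive")
  expect_error(simulation_spec(p, "g1", n_cells = 10,
                               reads_per_cell = c(1, 2)), "length")
})

test_that("simulated class sizes are exact and draws are reproducible", {
  base <- default_baseline_profile(100, seed = 1)
  spec <- simulation_spec(base, names(base)[1:5], n_cells = 250,
                          class_balance = 0.5, reads_per_cell = 2000,
                          seed = 9)
  d <- simulate_cells(spec)
  expect_equal(as.integer(table(d$labels)), c(125L, 125L))
  d2 <- simulate_cells(spec)
  expect_identical(d$values, d2$values)
  # unbalanced classes follow the requested fraction exactly
  d3 <- simulate_cells(simulation_spec(base, names(base)[1], n_cells = 10,
                                       class_balance = 0.3,
                                       reads_per_cell = 500))
  expect_equal(sum(d3$labels == "1"), 3L)
})

test_that("fold change of 1 produces a null dataset", {
  base <- default_baseline_profile(200, seed = 2)
  spec <- simulation_spec(base, names(base)[1:20], fold_change = 1,
                          n_cells = 400, reads_per_cell = 4000, seed = 11)
  d <- simulate_cells(spec)
  expressed <- which(colSums(d$values) > 20)
  p <- vapply(expressed, function(j)
    stats::t.test(d$values[d$labels == "0", j],
                  d$values[d$labels == "1", j])$p.value, 1)
  expect_gte(mean(p > 0.01), 0.98)
})

test_that("predictive genes converge to the requested fold change", {
  base <- default_baseline_profile(100, seed = 3)
  pred <- names(sort(base, decreasing = TRUE))[3:7]  # well expressed
  spec <- simulation_spec(base, pred, fold_change = 2, n_cells = 200,
                          reads_per_cell = 10000, seed = 13)
  d <- simulate_cells(spec)
  signs <- attr(d, "predictive_signs")
  # renormalization rescales all genes; compare against the exact profiles
  diffp <- kpnn:::differential_profile(base, pred, 2, signs)
  m0 <- colMeans(d$values[d$labels == "0", pred])
  m1 <- colMeans(d$values[d$labels == "1", pred])
  expect_equal(unname(m1 / m0), unname(diffp[pred] / base[pred]),
               tolerance = 0.05)
})

test_that("per-cell totals match the read target in expectation", {
  base <- default_baseline_profile(300, seed = 4)
  d <- simulate_cells(simulation_spec(base, names(base)[1], n_cells = 1000,
                                      reads_per_cell = 2000, seed = 5))
  expect_equal(mean(rowSums(d$values)) / 2000, 1, tolerance = 0.01)
})

test_that("fold-changed profiles renormalize to unit sum", {
  base <- default_baseline_profile(50, seed = 6)
  p <- kpnn:::differential_profile(base, names(base)[1:10], 2,
                                   rep(c(1, -1), 5))
  expect_equal(sum(p), 1)
})

test_that("control inputs preserve cells, labels, and depths", {
  base <- default_baseline_profile(150, seed = 7)
  d <- simulate_cells(simulation_spec(base, names(base)[1:10],
                                      n_cells = 120, reads_per_cell = 3000,
                                      seed = 8))
  ctrl <- make_control_inputs(d, class_of_reference = "0", seed = 21)
  expect_identical(ctrl$cells, d$cells)
  expect_identical(ctrl$labels, d$labels)
  expect_equal(mean(rowSums(ctrl$values)) / 3000, 1, tolerance = 0.02)
  # fold_change = 1: both classes drawn from the same profile
  ctrl1 <- make_control_inputs(d, "0", fold_change = 1, seed = 22)
  expressed <- which(colSums(ctrl1$values) > 30)
  p <- vapply(expressed, function(j)
    stats::t.test(ctrl1$values[ctrl1$labels == "0", j],
                  ctrl1$values[ctrl1$labels == "1", j])$p.value, 1)
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("control inputs make every gene carry the fold change", {
  base <- rep(1 / 40, 40); names(base) <- paste0("g", 1:40)
  d <- simulate_cells(simulation_spec(base, "g1", n_cells = 100,
                                      reads_per_cell = 25000, seed = 9))
  ctrl <- make_control_inputs(d, "0", fold_change = 2, seed = 23)
  m0 <- colMeans(ctrl$values[ctrl$labels == "0", ])
  m1 <- colMeans(ctrl$values[ctrl$labels == "1", ])
  lr <- abs(log2(m1 / m0))
  # every gene's |log2 ratio| near log2(2) = 1 (renormalization shifts all
  # genes by a common constant, here ~0 since signs are balanced)
  expect_equal(mean(lr), 1, tolerance = 0.15)
  expect_gt(min(lr), 0.5)
})

test_that("toy scenarios carry the documented ground truth", {
  ws <- toy_scenario("weak_strong", seed = 2, n_genes = 200, n_cells = 100,
                     reads_per_cell = 1000)
  expect_equal(sum(ws$ground_truth$role == "strong"), 3)
  expect_equal(sum(ws$ground_truth$role == "weak"), 3)
  expect_silent(validate_neural_graph(ws$graph))

  uc <- toy_scenario("uneven_connectivity", seed = 2, n_genes = 200,
                     n_cells = 100, reads_per_cell = 1000)
  nch <- uc$ground_truth$n_children[match(c("A", "B"), uc$ground_truth$node)]
  expect_equal(nch, c(2L, 8L))
  ig <- as_igraph(uc$graph)
  expect_equal(unname(igraph::degree(ig, c("A", "B"), mode = "in")),
               c(2, 8))
  expect_silent(validate_neural_graph(uc$graph))

  expect_error(toy_scenario("nope"), "arg")
})

test_that("scenarios are byte-identical under the same seed", {
  a <- toy_scenario("redundant_pair", seed = 3, n_genes = 150, n_cells = 80,
                    reads_per_cell = 800)
  b <- toy_scenario("redundant_pair", seed = 3, n_genes = 150, n_cells = 80,
                    reads_per_cell = 800)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$graph$edges, b$graph$edges)
})

test_that("expression matrices round-trip through TSV and MTX", {
  base <- default_baseline_profile(30, seed = 8)
  d <- simulate_cells(simulation_spec(base, names(base)[1:3], n_cells = 12,
                                      reads_per_cell = 500, seed = 4))
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "m.tsv"); lab <- file.path(dir, "lab.tsv")
  write_expression(d, tsv, lab, format = "tsv")
  r <- read_expression(tsv, lab, format = "tsv")
  expect_equal(unname(r$values), unname(d$values))
  expect_equal(as.character(r$labels), as.character(d$labels))
  mtx <- file.path(dir, "m.mtx")
  write_expression(d, mtx, lab, format = "mtx")
  r2 <- read_expression(mtx, lab, format = "mtx")
  expect_equal(unname(r2$values), unname(d$values))
})
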