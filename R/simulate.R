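#' Specification of a ground-truth single-cell simulation
#'
#' Cells are simulated by binomial subsampling of reads from an average
#' expression profile: class-0 cells from a baseline profile of per-gene
#' read fractions, class-1 cells from a differential profile in which the
#' fractions of the predictive genes are multiplied by `fold_change` or
#' `1/fold_change` (sign chosen per gene by a seeded fair coin) and the
#' profile renormalized.
#'
#' @param baseline_profile named non-negative numeric vector of per-gene
#'   expected read fractions summing to 1.
#' @param predictive_genes character vector, a subset of the profile genes.
#' @param fold_change positive expression ratio introduced in predictive
#'   genes (default 2, i.e., a two-fold change).
#' @param n_cells number of cells to simulate (default 2000).
#' @param class_balance fraction of cells in class 1 (default 0.5).
#' @param reads_per_cell per-cell total-read target; a scalar is recycled
#'   to all cells (default 10000, a typical droplet-sequencing depth).
#' @param seed integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(baseline_profile, predictive_genes,
                            fold_change = 2, n_cells = 2000,
                            class_balance = 0.5, reads_per_cell = 10000,
                            seed = 1L) {
  stopifnot(is.numeric(baseline_profile), !is.null(names(baseline_profile)))
  if (any(baseline_profile < 0) ||
      abs(sum(baseline_profile) - 1) > 1e-9)
    stop("baseline fractions must be non-negative and sum to 1")
  bad <- setdiff(predictive_genes, names(baseline_profile))
  if (length(bad)) stop("predictive genes absent from the profile: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (fold_change <= 0) stop("fold_change must be positive")
  if (length(reads_per_cell) == 1)
    reads_per_cell <- rep(reads_per_cell, n_cells)
  if (length(reads_per_cell) != n_cells)
    stop("reads_per_cell must have length 1 or n_cells")
  structure(list(baseline_profile = baseline_profile,
                 predictive_genes = predictive_genes,
                 fold_change = fold_change,
                 n_cells = as.integer(n_cells),
                 class_balance = class_balance,
                 reads_per_cell = reads_per_cell,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Average expression profile of one class
#'
#' Per-gene mean raw count over the cells of one class, renormalized to
#' fractions -- the baseline profile from which simulated cells are drawn.
#'
#' @param data an [expression_dataset()] of raw counts.
#' @param class_label the class whose cells are averaged.
#' @return Named numeric vector of per-gene fractions summing to 1.
#' @export
average_profile <- function(data, class_label) {
  sel <- data$labels == class_label
  if (!any(sel)) stop("no cells carry class label ", class_label)
  m <- colMeans(data$values[sel, , drop = FALSE])
  m / sum(m)
}

#' Default synthetic baseline profile
#'
#' A seeded, heavy-tailed decreasing profile standing in for an average
#' transcriptome when no real data are supplied: per-gene magnitudes are
#' gamma draws scaled by a power-law rank decay, then normalized to
#' fractions. The resulting profile spans several orders of magnitude, as
#' average single-cell expression profiles do.
#'
#' @param n_genes number of genes (default 1000).
#' @param seed integer seed.
#' @return Named numeric vector of fractions summing to 1 (names
#'   `g0001`...).
#' @export
default_baseline_profile <- function(n_genes = 1000, seed = 1L) {
  with_seed(seed, {
    mag <- stats::rgamma(n_genes, shape = 1.5, rate = 1) *
      seq_len(n_genes)^-0.9
  })
  p <- mag / sum(mag)
  names(p) <- sprintf("g%04d", seq_len(n_genes))
  p
}

# apply a signed fold change to selected genes and renormalize
differential_profile <- function(baseline, genes, fold_change, signs) {
  p <- baseline
  p[genes] <- p[genes] * fold_change^signs
  p / sum(p)
}

# draw cells x genes counts: independent binomials per gene with the
# cell's read target as size and the profile fraction as probability
draw_cells <- function(profile, reads) {
  n_genes <- length(profile)
  m <- matrix(0L, nrow = length(reads), ncol = n_genes,
              dimnames = list(NULL, names(profile)))
  for (i in seq_along(reads))
    m[i, ] <- stats::rbinom(n_genes, size = reads[i], prob = profile)
  m
}

#' Simulate single-cell expression counts with known ground truth
#'
#' Draws `n_cells` single-cell profiles by binomial read subsampling:
#' class-0 cells from the baseline profile, class-1 cells from the
#' differential profile carrying the fold changes in the predictive genes.
#' Class sizes follow `class_balance` exactly.
#'
#' @param spec a [simulation_spec()].
#' @return An [expression_dataset()] of raw counts with labels `0`/`1`;
#'   the chosen per-gene fold-change signs are attached as attribute
#'   `predictive_signs`.
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n1 <- round(spec$n_cells * spec$class_balance)
  n0 <- spec$n_cells - n1
  with_seed(spec$seed, {
    signs <- sample(c(1, -1), length(spec$predictive_genes), replace = TRUE)
    diffp <- differential_profile(spec$baseline_profile,
                                  spec$predictive_genes,
                                  spec$fold_change, signs)
    m0 <- draw_cells(spec$baseline_profile,
                     spec$reads_per_cell[seq_len(n0)])
    m1 <- draw_cells(diffp, spec$reads_per_cell[n0 + seq_len(n1)])
  })
  data <- expression_dataset(rbind(m0, m1),
                             labels = c(rep(0, n0), rep(1, n1)),
                             cells = sprintf("cell%05d", seq_len(spec$n_cells)))
  attr(data, "predictive_signs") <-
    structure(signs, names = spec$predictive_genes)
  data
}

#' Generate connectivity-normalizing control inputs
#'
#' Control inputs are simulated data in which every input gene is equally
#' predictive of the class, so that node weights learned from them reflect
#' only the network's connectivity. Raw counts of the reference class are
#' summed into an average profile; a fold change with random sign is then
#' applied to all genes to form the second profile, and per-cell reads are
#' drawn with the same per-cell depths, the same number of cells, and the
#' same class labels as the original data.
#'
#' @param data an [expression_dataset()] of raw counts.
#' @param class_of_reference the class whose summed counts define the
#'   baseline profile; cells of this class are redrawn from the baseline,
#'   all other cells from the differential profile.
#' @param fold_change positive ratio applied to every gene (default 2).
#' @param seed integer seed.
#' @return An [expression_dataset()] of control counts.
#' @export
make_control_inputs <- function(data, class_of_reference, fold_change = 2,
                                seed = 1L) {
  stopifnot(inherits(data, "expression_dataset"))
  ref <- data$labels == class_of_reference
  if (!any(ref)) stop("no cells carry class label ", class_of_reference)
  prof <- colSums(data$values[ref, , drop = FALSE])
  prof <- prof / sum(prof)
  reads <- round(data$cell_totals)
  with_seed(seed, {
    signs <- sample(c(1, -1), length(prof), replace = TRUE)
    diffp <- differential_profile(prof, names(prof), fold_change, signs)
    m <- matrix(0L, nrow = length(reads), ncol = length(prof),
                dimnames = list(data$cells, names(prof)))
    for (i in seq_along(reads)) {
      p <- if (ref[i]) prof else diffp
      m[i, ] <- stats::rbinom(length(p), size = reads[i], prob = p)
    }
  })
  expression_dataset(m, labels = data$labels, cells = data$cells)
}
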