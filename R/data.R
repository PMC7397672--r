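#' Single-cell expression dataset
#'
#' Holds a cells-by-genes value matrix with per-cell class labels, an
#' optional train/validation/test partition, and the per-cell total counts
#' recorded at construction time (so that per-cell scaling stays correct if
#' genes are later subset to a network's input nodes).
#'
#' @param values numeric matrix, cells in rows, genes in columns,
#'   non-negative.
#' @param labels per-cell class labels (coerced to factor).
#' @param genes,cells optional names; default to the matrix dimnames.
#' @param partition optional character vector in
#'   `{"train","validation","test"}` per cell.
#' @param cell_totals per-cell total raw counts; defaults to the row sums
#'   of `values`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, labels, genes = colnames(values),
                               cells = rownames(values), partition = NULL,
                               cell_totals = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(values)))
  if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(values)))
  if (anyDuplicated(genes)) stop("duplicate gene names")
  if (anyDuplicated(cells)) stop("duplicate cell identifiers")
  if (length(genes) != ncol(values) || length(cells) != nrow(values))
    stop("gene/cell name lengths do not match the matrix")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (length(labels) != nrow(values))
    stop("labels must cover every cell")
  dimnames(values) <- list(cells, genes)
  if (is.null(cell_totals)) cell_totals <- rowSums(values)
  if (!is.null(partition)) {
    stopifnot(length(partition) == nrow(values),
              all(partition %in% c("train", "validation", "test")))
  }
  structure(list(values = values,
                 genes = genes,
                 cells = cells,
                 labels = factor(labels),
                 partition = partition,
                 cell_totals = as.numeric(cell_totals),
                 normalization = NULL),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d cells x %d genes; classes: %s%s\n",
              length(x$cells), length(x$genes),
              paste(levels(x$labels), collapse = "/"),
              if (is.null(x$partition)) "" else " (partitioned)"))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# subset genes, keeping cell totals from the full matrix
subset_genes <- function(data, genes) {
  keep <- intersect(genes, data$genes)
  data$values <- data$values[, keep, drop = FALSE]
  data$genes <- keep
  data
}

#' Split a dataset into train, validation, and test partitions
#'
#' Cells are assigned at random (seeded) to the three partitions, with
#' sizes rounded to integers summing to the number of cells. The default
#' fractions are 60% training, 20% validation, 20% test.
#'
#' @param data an [expression_dataset()].
#' @param fractions numeric length-3 vector summing to 1, in the order
#'   train, validation, test.
#' @param seed integer seed.
#' @return The dataset with its `partition` field populated.
#' @export
split_dataset <- function(data, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  n <- length(data$cells)
  if (n < 5) stop("need at least 5 cells to split")
  sizes <- partition_sizes(n, fractions)
  tags <- rep(c("train", "validation", "test"), times = sizes)
  data$partition <- with_seed(seed, sample(tags))
  data
}

# largest-remainder rounding of n * fractions to integers summing to n
partition_sizes <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Normalize expression to the unit interval per gene
#'
#' Values are scaled per cell to transcripts-per-million (using the
#' dataset's recorded per-cell totals), transformed as `log(TPM + 1)`, and
#' then min-max normalized per gene. Normalization factors (per-gene min
#' and max) are computed from the training partition only and applied to
#' all cells, so validation and test values can fall outside `[0, 1]`.
#' Genes with zero range in the training split are mapped to constant 0
#' and flagged.
#'
#' @param data a partitioned [expression_dataset()] with raw non-negative
#'   values.
#' @return The dataset with normalized `values` and a `normalization`
#'   element holding `gene_min`, `gene_max`, and `flagged_constant`.
#' @export
normalize_expression <- function(data) {
  if (is.null(data$partition))
    stop("dataset must be split before normalization (factors come from ",
         "the training partition)")
  if (!is.null(data$normalization)) return(data)
  tot <- data$cell_totals
  tot[tot == 0] <- 1
  logtpm <- log1p(data$values / tot * 1e6)
  train <- data$partition == "train"
  gmin <- apply(logtpm[train, , drop = FALSE], 2, min)
  gmax <- apply(logtpm[train, , drop = FALSE], 2, max)
  rng <- gmax - gmin
  flagged <- data$genes[rng == 0]
  if (length(flagged))
    warning(length(flagged),
            " gene(s) constant in the training split mapped to 0")
  rng[rng == 0] <- 1
  data$values <- sweep(sweep(logtpm, 2, gmin), 2, rng, "/")
  data$values[, data$genes %in% flagged] <- 0
  data$normalization <- list(gene_min = gmin, gene_max = gmax,
                             flagged_constant = flagged)
  data
}

#' Per-class loss weights for imbalanced data
#'
#' The weight of class x is `(1/N_classes) / (N_x / N_samples)`, so that a
#' balanced dataset yields weight 1 for every class and the weighted sample
#' count always sums to the number of samples.
#'
#' @param labels factor (or coercible) of class labels; at least two
#'   classes must be present.
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  labels <- factor(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least two classes")
  if (any(counts == 0)) stop("class with zero samples: ",
                             paste(names(counts)[counts == 0], collapse = ", "))
  n <- length(labels)
  w <- (1 / length(counts)) / (as.numeric(counts) / n)
  names(w) <- names(counts)
  w
}

# cells x outputs 0/1 target matrix; binary labels give a single column
# for the second factor level, K > 2 classes give one-hot columns
label_matrix <- function(labels) {
  labels <- factor(labels)
  lv <- levels(labels)
  if (length(lv) == 2) {
    y <- matrix(as.numeric(labels == lv[2]), ncol = 1)
    colnames(y) <- lv[2]
  } else {
    y <- vapply(lv, function(l) as.numeric(labels == l),
                numeric(length(labels)))
  }
  y
}

#' Read an expression matrix with labels
#'
#' Supports a dense genes-by-cells TSV (gene names in the first column,
#' cell identifiers in the header) and MatrixMarket sparse-triplet format
#' accompanied by row-name (genes) and column-name (cells) files, one name
#' per line. Labels are a two-column `cell<TAB>class` TSV without header.
#'
#' @param path matrix file path (`.tsv` or `.mtx`).
#' @param labels_path path to the labels TSV.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_path,cells_path name files for MTX input; default to
#'   `<path>.genes.txt` / `<path>.cells.txt`.
#' @return An [expression_dataset()] (cells in rows).
#' @export
read_expression <- function(path, labels_path, format = c("tsv", "mtx"),
                            genes_path = paste0(path, ".genes.txt"),
                            cells_path = paste0(path, ".cells.txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    if (anyDuplicated(genes))
      stop("duplicate gene names in ", path, " (first at line ",
           which(duplicated(genes))[1] + 1, ")")
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(m) <- genes
  } else {
    sm <- Matrix::readMM(path)      # genes x cells triplets
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(sm) != length(genes) || ncol(sm) != length(cells))
      stop("MTX shape ", nrow(sm), "x", ncol(sm),
           " does not match name files (", length(genes), " genes, ",
           length(cells), " cells)")
    if (anyDuplicated(genes)) stop("duplicate gene names in ", genes_path)
    m <- t(as.matrix(sm))
    dimnames(m) <- list(cells, genes)
  }
  if (any(m < 0)) stop("negative expression values in ", path)
  lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("cell", "class"),
                           colClasses = "character")
  missing <- setdiff(rownames(m), lab$cell)
  if (length(missing))
    stop("labels missing for cell(s): ", paste(utils::head(missing, 5),
                                               collapse = ", "))
  labels <- lab$class[match(rownames(m), lab$cell)]
  expression_dataset(m, labels)
}

#' @rdname read_expression
#' @param data an [expression_dataset()] to write.
#' @export
write_expression <- function(data, path, labels_path,
                             format = c("tsv", "mtx"),
                             genes_path = paste0(path, ".genes.txt"),
                             cells_path = paste0(path, ".cells.txt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene = data$genes, t(data$values),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene", data$cells)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(t(data$values), sparse = TRUE), path)
    writeLines(data$genes, genes_path)
    writeLines(data$cells, cells_path)
  }
  utils::write.table(data.frame(cell = data$cells,
                                class = as.character(data$labels)),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
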