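#' Construct a time-stamped expression dataset
#'
#' The central container of the package: a genes-by-cells expression matrix
#' split into independent cohorts, one per observation time (destructive
#' sampling -- each cell is measured once).
#'
#' @param matrices list of m x n(t) numeric matrices, one per time point,
#'   all with the same gene (row) order.
#' @param times numeric vector of strictly increasing time stamps, one per
#'   matrix.
#' @param gene_names character vector of m gene identifiers; defaults to the
#'   row names of the first matrix.
#' @param cell_ids optional list of per-time-point cell identifier vectors.
#' @param branch_labels optional list of per-time-point character vectors of
#'   branch/lineage labels.
#' @param cell_weights optional list of per-time-point nonnegative weights;
#'   normalized to sum to one within each time point.
#' @param pseudotime optional list of per-time-point numeric pseudotimes.
#' @param transformed logical; whether values are already log-transformed.
#'
#' @return an object of class `expression_dataset` with fields
#'   `gene_names`, `times`, `matrices`, `cell_ids`, `branch_labels`,
#'   `cell_weights`, `pseudotime`, `transformed`.
#' @export
expression_dataset <- function(matrices, times, gene_names = NULL,
                               cell_ids = NULL, branch_labels = NULL,
                               cell_weights = NULL, pseudotime = NULL,
                               transformed = FALSE) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop("need at least 2 time points, got ", length(matrices))
  matrices <- lapply(matrices, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  if (length(times) != length(matrices))
    stop("length(times) must equal the number of expression matrices")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  m <- nrow(matrices[[1L]])
  if (is.null(gene_names)) gene_names <- rownames(matrices[[1L]])
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(m))
  for (i in seq_along(matrices)) {
    if (nrow(matrices[[i]]) != m)
      stop("gene dimension differs at time index ", i)
    if (ncol(matrices[[i]]) < 2L)
      stop("need at least 2 cells per time point (time index ", i, ")")
    if (any(!is.finite(matrices[[i]])))
      stop("non-finite expression values at time index ", i)
    if (!transformed && any(matrices[[i]] < 0))
      stop("negative expression values at time index ", i)
    rownames(matrices[[i]]) <- gene_names
  }
  if (is.null(cell_ids))
    cell_ids <- lapply(seq_along(matrices), function(i)
      paste0("t", i, "_c", seq_len(ncol(matrices[[i]]))))
  for (i in seq_along(matrices)) {
    if (length(cell_ids[[i]]) != ncol(matrices[[i]]))
      stop("cell_ids length mismatch at time index ", i)
    colnames(matrices[[i]]) <- cell_ids[[i]]
  }
  if (!is.null(cell_weights)) {
    cell_weights <- lapply(cell_weights, function(w) {
      if (any(w < 0)) stop("cell weights must be nonnegative")
      if (sum(w) <= 0) stop("cell weights sum to zero at a time point")
      w / sum(w)
    })
  }
  structure(list(gene_names = gene_names, times = as.numeric(times),
                 matrices = matrices, cell_ids = cell_ids,
                 branch_labels = branch_labels, cell_weights = cell_weights,
                 pseudotime = pseudotime, transformed = transformed),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  n <- vapply(x$matrices, ncol, integer(1))
  cat("expression_dataset:", length(x$gene_names), "genes,",
      length(x$times), "time points, cells per time:",
      paste(n, collapse = ", "), "\n")
  cat("  times:", paste(signif(x$times, 4), collapse = ", "), "\n")
  if (!is.null(x$branch_labels))
    cat("  branches:",
        paste(sort(unique(unlist(x$branch_labels))), collapse = ", "), "\n")
  cat("  log-transformed:", x$transformed, "\n")
  invisible(x)
}

#' Number of cells per time point
#' @param dataset an `expression_dataset`.
#' @return integer vector n(t).
#' @export
n_cells <- function(dataset) vapply(dataset$matrices, ncol, integer(1))

## Sniff the field separator of a delimited text file from its first line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a time-stamped expression dataset from disk
#'
#' The expression matrix is genes x cells, either dense delimited text
#' (CSV/TSV, auto-detected; first column = gene names, header = cell ids) or
#' MatrixMarket with gene/cell name sidecar files.  The metadata table has
#' one row per cell with columns `cell_id`, `time` (or `pseudotime`), and
#' optional `branch` and `weight` columns.  Cells are grouped by time label
#' into per-time cohorts sorted by ascending time.
#'
#' A transposed matrix (cells x genes) is detected by comparing dimensions
#' against the metadata and reported as an error rather than silently fixed.
#'
#' @param matrix_path path to the expression matrix.
#' @param metadata_path path to the cell metadata table (CSV/TSV).
#' @param genes_path,cells_path sidecar name files, only used for
#'   MatrixMarket input; default to `genes.txt` / `cells.txt` next to the
#'   matrix file.
#' @param n_bins if the metadata carries `pseudotime` instead of `time`,
#'   number of quantile bins used to create discrete time labels
#'   (see [bin_pseudotime()]).
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path,
                            genes_path = NULL, cells_path = NULL,
                            n_bins = NULL) {
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    mat <- as.matrix(Matrix::readMM(matrix_path))
    dir <- dirname(matrix_path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.txt")
    if (is.null(cells_path)) cells_path <- file.path(dir, "cells.txt")
    rownames(mat) <- readLines(genes_path)
    colnames(mat) <- readLines(cells_path)
  } else {
    sep <- detect_sep(matrix_path)
    tab <- data.table::fread(matrix_path, sep = sep, header = TRUE,
                             data.table = FALSE)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- as.character(tab[[1L]])
  }
  storage.mode(mat) <- "double"

  meta <- data.table::fread(metadata_path, header = TRUE, data.table = FALSE)
  if (!"cell_id" %in% names(meta)) stop("metadata must have a cell_id column")
  meta$cell_id <- as.character(meta$cell_id)

  if (nrow(meta) != ncol(mat) && nrow(meta) == nrow(mat))
    stop("matrix appears transposed (cells x genes): ", nrow(mat),
         " rows match the metadata cell count; expected genes as rows")
  missing <- setdiff(colnames(mat), meta$cell_id)
  if (length(missing) > 0)
    stop("cell(s) absent from metadata, first offender: ", missing[1L])
  extra <- setdiff(meta$cell_id, colnames(mat))
  if (length(extra) > 0)
    warning("metadata rows without matrix columns ignored (e.g. ",
            extra[1L], ")")
  meta <- meta[match(colnames(mat), meta$cell_id), , drop = FALSE]

  if ("time" %in% names(meta)) {
    tlab <- as.numeric(meta$time)
    tstamps <- NULL
  } else if ("pseudotime" %in% names(meta)) {
    if (is.null(n_bins))
      stop("metadata has pseudotime but no time column; supply n_bins")
    pt <- as.numeric(meta$pseudotime)
    tlab <- bin_pseudotime(pt, n_bins)
    ## bin midpoints of the pseudotime ranges serve as time stamps
    tstamps <- vapply(sort(unique(tlab)), function(b)
      mean(range(pt[tlab == b])), numeric(1))
  } else stop("metadata must have a time or pseudotime column")

  if (any(!is.finite(mat))) stop("non-finite expression values in matrix")
  if (any(mat < 0)) stop("negative expression values in matrix")

  ulab <- sort(unique(tlab))
  if (length(ulab) < 2L) stop("fewer than 2 time points in metadata")
  idx <- lapply(ulab, function(u) which(tlab == u))
  matrices <- lapply(idx, function(j) mat[, j, drop = FALSE])
  cell_ids <- lapply(idx, function(j) colnames(mat)[j])
  branch_labels <- if ("branch" %in% names(meta))
    lapply(idx, function(j) as.character(meta$branch[j])) else NULL
  cell_weights <- if ("weight" %in% names(meta))
    lapply(idx, function(j) as.numeric(meta$weight[j])) else NULL
  pseudotime <- if ("pseudotime" %in% names(meta))
    lapply(idx, function(j) as.numeric(meta$pseudotime[j])) else NULL
  times <- if (is.null(tstamps)) ulab else tstamps

  expression_dataset(matrices, times, gene_names = rownames(mat),
                     cell_ids = cell_ids, branch_labels = branch_labels,
                     cell_weights = cell_weights, pseudotime = pseudotime)
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [read_expression()]: writes a genes x cells CSV and a cell
#' metadata CSV (`cell_id`, `time`, optional `branch`, `weight`).
#'
#' @param dataset an `expression_dataset`.
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(dataset, matrix_path, metadata_path) {
  mat <- do.call(cbind, dataset$matrices)
  df <- data.frame(gene = dataset$gene_names, mat, check.names = FALSE)
  data.table::fwrite(df, matrix_path, sep = ",")
  nt <- n_cells(dataset)
  meta <- data.frame(cell_id = unlist(dataset$cell_ids),
                     time = rep(dataset$times, nt))
  if (!is.null(dataset$branch_labels))
    meta$branch <- unlist(dataset$branch_labels)
  if (!is.null(dataset$cell_weights))
    meta$weight <- unlist(dataset$cell_weights)
  data.table::fwrite(meta, metadata_path, sep = ",")
  invisible(c(matrix_path, metadata_path))
}

#' Assign discrete time labels from pseudotime by quantile binning
#'
#' Cells are sorted by pseudotime and sliced into `n_bins` contiguous blocks
#' of near-equal size (sizes differ by at most one when pseudotimes are
#' distinct).  Cells sharing a pseudotime value always share a bin; at block
#' boundaries the tie goes to the lower bin.
#'
#' @param pseudotime numeric vector, one value per cell.
#' @param n_bins integer >= 2, at most the number of cells.
#' @return integer vector of bin labels in `0..n_bins-1`, same order as the
#'   input.
#' @export
bin_pseudotime <- function(pseudotime, n_bins) {
  n <- length(pseudotime)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (n_bins > n) stop("n_bins exceeds the number of cells")
  if (any(!is.finite(pseudotime))) stop("non-finite pseudotime")
  if (length(unique(pseudotime)) == 1L)
    stop("all pseudotimes identical: no temporal signal to bin")
  ord <- order(pseudotime)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  prov <- integer(n)
  prov[ord] <- rep(seq_len(n_bins) - 1L, times = sizes)
  ## ties share a bin; lower bin wins at block boundaries
  bins <- stats::ave(prov, pseudotime, FUN = min)
  counts <- tabulate(bins + 1L, nbins = n_bins)
  if (any(counts == 0L))
    stop("tied pseudotimes empty bin(s) ",
         paste(which(counts == 0L) - 1L, collapse = ", "),
         "; reduce n_bins")
  as.integer(bins)
}

#' Export the top edges of a weight matrix as a ranked edge list
#'
#' Off-diagonal entries are ranked by absolute weight (descending, ties by
#' regulator then target index) and the top fraction is written as a
#' tab-delimited table with columns `regulator`, `target`, `weight`, `sign`,
#' `interval`.  Self-loops are never written.
#'
#' @param weights m x m numeric matrix, rows = regulators, columns =
#'   targets; gene names taken from dimnames.
#' @param top_fraction fraction in (0, 1] of off-diagonal entries to keep
#'   (rounded up).
#' @param out_path output path.
#' @param interval label for the `interval` column (default "global").
#' @param exclude_targets gene names never to report as targets (e.g. an
#'   artificial stimulus gene).
#' @return invisibly, the edge table (data.frame) that was written.
#' @export
write_edge_list <- function(weights, top_fraction, out_path,
                            interval = "global",
                            exclude_targets = character(0)) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  genes <- rownames(weights)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(weights)))
  m <- nrow(weights)
  reg <- rep(seq_len(m), times = m)
  tgt <- rep(seq_len(m), each = m)
  keep <- reg != tgt & !(genes[tgt] %in% exclude_targets)
  reg <- reg[keep]; tgt <- tgt[keep]
  w <- weights[cbind(reg, tgt)]
  nz <- w != 0
  ord <- order(-abs(w), reg, tgt)
  k <- min(ceiling(top_fraction * length(w)), sum(nz))
  sel <- ord[seq_len(k)]
  edges <- data.frame(regulator = genes[reg[sel]], target = genes[tgt[sel]],
                      weight = w[sel],
                      sign = ifelse(w[sel] >= 0, "+", "-"),
                      interval = rep(interval, length(sel)),
                      stringsAsFactors = FALSE)
  data.table::fwrite(edges, out_path, sep = "\t")
  invisible(edges)
}

#' Read a signed ground-truth network from an edge list
#'
#' Expects a delimited table with columns `regulator`, `target` and an
#' optional `sign` column (+1 assumed when absent).
#'
#' @param path edge-list file.
#' @param gene_names optional full gene universe (edge lists usually name
#'   only connected genes).
#' @return a [ground_truth_network()].
#' @export
read_ground_truth <- function(path, gene_names = NULL) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("regulator", "target") %in% names(tab)))
    stop("edge list needs regulator and target columns")
  sgn <- if ("sign" %in% names(tab)) {
    s <- tab$sign
    if (is.character(s)) ifelse(s %in% c("-", "-1"), -1L, 1L)
    else as.integer(sign(as.numeric(s)))
  } else rep(1L, nrow(tab))
  if (is.null(gene_names))
    gene_names <- sort(unique(c(tab$regulator, tab$target)))
  adj <- matrix(0L, length(gene_names), length(gene_names),
                dimnames = list(gene_names, gene_names))
  adj[cbind(match(tab$regulator, gene_names),
            match(tab$target, gene_names))] <- sgn
  ground_truth_network(adj, gene_names)
}

#' Write a ground-truth network as an edge list
#' @param truth a `ground_truth_network`.
#' @param path output path (TSV with regulator, target, sign).
#' @return invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  idx <- which(truth$adjacency != 0 &
                 row(truth$adjacency) != col(truth$adjacency), arr.ind = TRUE)
  edges <- data.frame(regulator = truth$gene_names[idx[, 1]],
                      target = truth$gene_names[idx[, 2]],
                      sign = truth$adjacency[idx])
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  data.table::fwrite(edges, path, sep = "\t")
  invisible(path)
}

#' Construct a signed ground-truth network
#'
#' @param adjacency m x m integer matrix with entries in `{-1, 0, +1}`;
#'   entry `(g1, g2)` means g1 regulates g2 with that sign.  The diagonal is
#'   ignored in all scoring.
#' @param gene_names gene identifiers (defaults to adjacency dimnames).
#' @param stimulus optional name of a stimulus-marked node.
#' @return object of class `ground_truth_network`.
#' @export
ground_truth_network <- function(adjacency, gene_names = NULL,
                                 stimulus = NULL) {
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == ncol(adjacency))
  if (!all(adjacency %in% c(-1, 0, 1)))
    stop("adjacency entries must be in {-1, 0, +1}")
  if (is.null(gene_names)) gene_names <- rownames(adjacency)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(gene_names, gene_names)
  storage.mode(adjacency) <- "integer"
  structure(list(gene_names = gene_names, adjacency = adjacency,
                 stimulus = stimulus),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  off <- x$adjacency[row(x$adjacency) != col(x$adjacency)]
  cat("ground_truth_network:", length(x$gene_names), "genes,",
      sum(off != 0), "signed edges (", sum(off > 0), "activating,",
      sum(off < 0), "inhibiting)\n")
  if (!is.null(x$stimulus)) cat("  stimulus node:", x$stimulus, "\n")
  invisible(x)
}

#' Run configuration with package defaults
#'
#' Bundles the tunable parameters of the pipeline.  Defaults follow the
#' values that proved stable across datasets: `alpha = 0.5` (trade-off
#' between the feature-space and structure-preservation transport costs),
#' `epsilon = 0.01` (entropic regularization), `lam = 1` and
#' `ratio_r = 0.5` (elastic-net magnitude and l1 fraction), `lag = 1`.
#'
#' @param alpha trade-off in `[0, 1]` between Wasserstein (0) and
#'   Gromov-Wasserstein (1) cost terms.
#' @param epsilon entropic regularization coefficient, > 0.
#' @param lam elastic-net penalty magnitude, >= 0.
#' @param ratio_r l1 fraction of the elastic-net penalty, in `[0, 1]`.
#' @param lag time lag for the correlation method (positive integer).
#' @param n_bins optional pseudotime bin count.
#' @param marginal_mode `"uniform"` or `"branch_reweighed"`.
#' @param branch_mode `"combined"` (one transport sequence on all cells) or
#'   `"split"` (one per branch, then combined).
#' @param combine_rule `"sum"` or `"maxabs"` for combining branch networks.
#' @param metric `"euclidean"` or `"cosine"` cell-cell distance.
#' @param stimulus_time optional 1-based time index at which a stimulus was
#'   applied; adds an artificial unit-velocity predictor gene.
#' @param seed integer seed.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(alpha = 0.5, epsilon = 0.01, lam = 1, ratio_r = 0.5,
                       lag = 1L, n_bins = NULL,
                       marginal_mode = c("uniform", "branch_reweighed"),
                       branch_mode = c("combined", "split"),
                       combine_rule = c("sum", "maxabs"),
                       metric = c("euclidean", "cosine"),
                       stimulus_time = NULL, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, epsilon > 0, lam >= 0,
            ratio_r >= 0, ratio_r <= 1, lag >= 1)
  structure(list(alpha = alpha, epsilon = epsilon, lam = lam,
                 ratio_r = ratio_r, lag = as.integer(lag), n_bins = n_bins,
                 marginal_mode = match.arg(marginal_mode),
                 branch_mode = match.arg(branch_mode),
                 combine_rule = match.arg(combine_rule),
                 metric = match.arg(metric),
                 stimulus_time = stimulus_time, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unspecified keys keep their
#' defaults, and entries of `overrides` (e.g. from command-line flags) win
#' over the file.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list of overriding values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
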