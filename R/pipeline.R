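## End-to-end orchestration: expression data in, inferred network out.

## Subset an expression_dataset to the cells of one branch.  Time points
## left with fewer than 2 cells of the branch are dropped.
subset_branch <- function(dataset, branch) {
  if (is.null(dataset$branch_labels)) stop("dataset has no branch labels")
  keep_t <- which(vapply(dataset$branch_labels,
                         function(l) sum(l == branch) >= 2L, logical(1)))
  if (length(keep_t) < 2L)
    stop("branch '", branch, "' present at fewer than 2 time points")
  sel <- lapply(keep_t, function(i) dataset$branch_labels[[i]] == branch)
  expression_dataset(
    matrices = Map(function(i, s) dataset$matrices[[i]][, s, drop = FALSE],
                   keep_t, sel),
    times = dataset$times[keep_t],
    gene_names = dataset$gene_names,
    cell_ids = Map(function(i, s) dataset$cell_ids[[i]][s], keep_t, sel),
    branch_labels = Map(function(i, s) dataset$branch_labels[[i]][s],
                        keep_t, sel),
    transformed = dataset$transformed)
}

## One full single-branch pass: couplings -> velocities -> network.
infer_single <- function(dataset, method, config) {
  couplings <- solve_coupling_sequence(dataset, config)
  field <- compute_velocities(dataset, couplings)
  field <- normalize_velocities(field)
  field <- add_stimulus_gene(field, config$stimulus_time)
  if (method == "corr") {
    grn <- lagged_correlation(field, couplings, lag = config$lag,
                              include_stimulus = !is.null(
                                config$stimulus_time))
    weights <- grn$C
    per_interval <- grn$per_interval
  } else {
    grn <- granger_network(field, couplings, lam = config$lam,
                           ratio_r = config$ratio_r)
    weights <- grn$weights
    per_interval <- lapply(grn$A_intervals, t)
  }
  list(weights = weights, per_interval = per_interval, grn = grn,
       couplings = couplings, field = field)
}

#' Infer a gene regulatory network from a time-stamped dataset
#'
#' Runs the full pipeline: optional log transform, entropic fused
#' Gromov-Wasserstein couplings between consecutive cohorts, velocity
#' estimation and per-gene normalization, optional stimulus gene, and the
#' chosen network method (transport-weighted time-lagged correlation or
#' elastic-net Granger regression).  With `branch_mode = "split"` the whole
#' pipeline runs once per branch and the branch networks are combined by
#' the configured rule.
#'
#' @param dataset an [expression_dataset()] of raw (or, if flagged,
#'   pre-transformed) values.
#' @param method `"corr"` or `"granger"`.
#' @param config a [run_config()].
#' @return object of class `grn_result`: list with `weights` (m x m,
#'   rows = regulators, columns = targets; the stimulus gene, if any, is an
#'   extra source-only row), `per_interval` (same orientation),
#'   `interval_labels` (time pairs), `method`, `config`, `branches`
#'   (per-branch weight matrices in split mode), and -- in combined mode --
#'   the intermediate `couplings` and `field`.
#' @export
infer_grn <- function(dataset, method = c("corr", "granger"),
                      config = run_config()) {
  method <- match.arg(method)
  if (!dataset$transformed) dataset <- log_transform(dataset)
  res <- if (config$branch_mode == "split") {
    branches <- sort(unique(unlist(dataset$branch_labels)))
    if (length(branches) == 0L)
      stop("branch_mode = 'split' requires branch labels")
    runs <- lapply(branches, function(br)
      infer_single(subset_branch(dataset, br), method, config))
    names(runs) <- branches
    weights <- combine_branches(lapply(runs, `[[`, "weights"),
                                rule = config$combine_rule)
    list(weights = weights, per_interval = NULL,
         branches = lapply(runs, `[[`, "weights"),
         couplings = NULL, field = NULL,
         interval_labels = NULL)
  } else {
    one <- infer_single(dataset, method, config)
    N <- length(dataset$times)
    lag <- if (method == "corr") config$lag else 1L
    one$interval_labels <- paste0(dataset$times[seq_len(N - lag)], "-",
                                  dataset$times[seq_len(N - lag) + lag])
    one$branches <- NULL
    one
  }
  structure(c(res, list(method = method, config = config)),
            class = "grn_result")
}

#' @export
print.grn_result <- function(x, ...) {
  cat("grn_result (", x$method, "): ", nrow(x$weights), " genes",
      sep = "")
  if (!is.null(x$branches))
    cat(", ", length(x$branches), " branches combined by ",
        x$config$combine_rule, sep = "")
  cat("\n  nonzero weights:", sum(x$weights != 0), "/",
      sum(row(x$weights) != col(x$weights)), "off-diagonal entries\n")
  invisible(x)
}

#' Strip an artificial stimulus gene from a weight matrix
#'
#' Convenience for scoring against a ground truth that does not contain
#' the artificial stimulus node.
#'
#' @param result a `grn_result` (or plain weight matrix).
#' @param name stimulus gene name.
#' @return the weight matrix without the stimulus row/column.
#' @export
drop_stimulus <- function(result, name = "stimulus") {
  W <- if (inherits(result, "grn_result")) result$weights else result
  keep <- setdiff(rownames(W), name)
  W[keep, keep, drop = FALSE]
}

#' Project per-cell velocities onto a 2-D embedding
#'
#' Utility for velocity-field figures: given user-supplied 2-D coordinates
#' of all cells (in dataset cell order) it returns per-cell displacement
#' arrows, computed by projecting each cell's predicted descendant state
#' onto the embedding via the same barycentric weights.
#'
#' @param dataset the (transformed) `expression_dataset`.
#' @param couplings matching `coupling_sequence`.
#' @param embedding (sum n(t)) x 2 matrix of cell coordinates, cells in
#'   dataset order (time point by time point).
#' @return data.frame with columns `x`, `y`, `dx`, `dy`, `time`.
#' @export
embed_velocity <- function(dataset, couplings, embedding) {
  plans <- if (inherits(couplings, "coupling_sequence"))
    couplings$couplings else couplings
  nt <- n_cells(dataset)
  stopifnot(nrow(embedding) == sum(nt), ncol(embedding) == 2L)
  offs <- cumsum(c(0L, nt))
  out <- vector("list", length(nt) - 1L)
  for (k in seq_len(length(nt) - 1L)) {
    E_t <- embedding[offs[k] + seq_len(nt[k]), , drop = FALSE]
    E_t2 <- embedding[offs[k + 1L] + seq_len(nt[k + 1L]), , drop = FALSE]
    pred <- barycentric_project(plans[[k]], t(E_t2))   # 2 x n(t)
    out[[k]] <- data.frame(x = E_t[, 1L], y = E_t[, 2L],
                           dx = pred[1L, ] - E_t[, 1L],
                           dy = pred[2L, ] - E_t[, 2L],
                           time = dataset$times[k])
  }
  do.call(rbind, out)
}
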