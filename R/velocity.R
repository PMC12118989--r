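#' Per-cell, per-gene velocities by finite differences of transported states
#'
#' For each cell the descendant (and ancestor) state is predicted by
#' barycentric projection through the interval coupling, and the velocity
#' (rate of change of expression) is the finite difference: forward
#' difference at the first time point, backward at the last, and the
#' spacing-weighted centered combination
#' `(t_k - t_{k-1})/(t_{k+1} - t_{k-1}) * v_forward +
#'  (t_{k+1} - t_k)/(t_{k+1} - t_{k-1}) * v_backward`
#' at interior points (which reduces to the plain average for equally
#' spaced times).  The backward (ancestor) map uses the transposed coupling
#' of the preceding interval, so one transport solve per interval suffices.
#'
#' @param dataset the (log-transformed) `expression_dataset` the couplings
#'   were computed on.
#' @param couplings a `coupling_sequence` (or plain list of N - 1 plans).
#' @return object of class `velocity_field`: list with `velocities` (per
#'   time point, m x n(t)), `gene_names`, `times`, `normalized`,
#'   `gene_sds`, `stimulus_gene`.
#' @export
compute_velocities <- function(dataset, couplings) {
  plans <- if (inherits(couplings, "coupling_sequence"))
    couplings$couplings else couplings
  N <- length(dataset$times)
  if (length(plans) != N - 1L)
    stop("need one coupling per consecutive interval (", N - 1L, ")")
  tms <- dataset$times
  X <- dataset$matrices
  forward <- function(k) {
    pred <- barycentric_project(plans[[k]], X[[k + 1L]])
    (pred - X[[k]]) / (tms[k + 1L] - tms[k])
  }
  backward <- function(k) {
    pred <- barycentric_project(t(plans[[k - 1L]]), X[[k - 1L]])
    (X[[k]] - pred) / (tms[k] - tms[k - 1L])
  }
  vel <- vector("list", N)
  vel[[1L]] <- forward(1L)
  if (N > 2L) for (k in 2L:(N - 1L)) {
    wf <- (tms[k] - tms[k - 1L]) / (tms[k + 1L] - tms[k - 1L])
    vel[[k]] <- wf * forward(k) + (1 - wf) * backward(k)
  }
  vel[[N]] <- backward(N)
  structure(list(velocities = vel, gene_names = dataset$gene_names,
                 times = tms, normalized = FALSE, gene_sds = NULL,
                 stimulus_gene = NULL),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("velocity_field:", length(x$gene_names), "genes,",
      length(x$velocities), "time points,",
      if (isTRUE(x$normalized)) "normalized" else "raw", "\n")
  if (!is.null(x$stimulus_gene))
    cat("  stimulus gene:", x$stimulus_gene, "\n")
  invisible(x)
}

#' Project a velocity matrix onto another cohort's cells
#'
#' Transfers velocities defined on the source cohort to the cells of the
#' target cohort: the projected velocity of a target cell is the
#' column-normalized, coupling-weighted average of source-cell velocities.
#'
#' @param coupling n_source x n_target plan (zero columns are an error;
#'   repair upstream via [compose_couplings()]).
#' @param v m x n_source velocity matrix.
#' @return m x n_target matrix of projected velocities.
#' @export
project_velocity <- function(coupling, v) {
  if (nrow(coupling) != ncol(v))
    stop("coupling and velocity dimensions disagree")
  cs <- colSums(coupling)
  if (any(cs == 0)) stop("zero column in coupling")
  v %*% sweep(coupling, 2L, cs, "/")
}

#' Normalize velocities to unit per-gene standard deviation
#'
#' Each gene's velocities, pooled over all cells at all time points, are
#' divided by their population standard deviation so genes with different
#' expression magnitudes contribute comparably.  The mean is deliberately
#' not subtracted: the sign of a velocity distinguishes activation from
#' repression.  Genes with zero pooled SD are left untouched and recorded.
#' An appended stimulus gene keeps its unit velocity by construction.
#'
#' @param field a raw `velocity_field`.
#' @return the normalized field, with `gene_sds` (the divisors used) and
#'   `zero_sd_genes` recorded.
#' @export
normalize_velocities <- function(field) {
  if (isTRUE(field$normalized)) stop("velocity field already normalized")
  pooled <- do.call(cbind, field$velocities)
  n <- ncol(pooled)
  sds <- sqrt(rowSums((pooled - rowMeans(pooled))^2) / n)
  names(sds) <- field$gene_names
  if (!is.null(field$stimulus_gene))
    sds[field$stimulus_gene] <- 1
  zero <- sds == 0
  div <- ifelse(zero, 1, sds)
  field$velocities <- lapply(field$velocities, function(v) v / div)
  field$normalized <- TRUE
  field$gene_sds <- sds
  field$zero_sd_genes <- field$gene_names[zero]
  field
}

#' Append an artificial stimulus gene to a velocity field
#'
#' Encodes an external stimulus as an extra gene whose velocity is one for
#' every cell at the stimulus time point and zero elsewhere.  The gene is
#' predictor-only: it is exempt from SD normalization and is never reported
#' as a regression or correlation target.
#'
#' @param field a `velocity_field`.
#' @param stimulus_time_index 1-based index of the stimulus time point, or
#'   `NULL` for no change.
#' @param name name of the appended gene.
#' @return the augmented field (m + 1 genes).
#' @export
add_stimulus_gene <- function(field, stimulus_time_index,
                              name = "stimulus") {
  if (is.null(stimulus_time_index)) return(field)
  N <- length(field$velocities)
  if (stimulus_time_index < 1L || stimulus_time_index > N)
    stop("stimulus_time_index out of range")
  if (name %in% field$gene_names)
    stop("gene name '", name, "' already present")
  field$velocities <- lapply(seq_len(N), function(k) {
    v <- field$velocities[[k]]
    rbind(v, `row` = as.numeric(k == stimulus_time_index))
  })
  field$gene_names <- c(field$gene_names, name)
  field$velocities <- lapply(field$velocities, function(v) {
    rownames(v) <- field$gene_names
    v
  })
  if (!is.null(field$gene_sds)) field$gene_sds <- c(field$gene_sds,
                                                    stats::setNames(1, name))
  field$stimulus_gene <- name
  field
}
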