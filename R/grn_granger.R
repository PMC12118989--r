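#' Elastic-net Granger regression for one time interval
#'
#' Regresses each gene's velocity at time `t_{k+1}` on the velocities of
#' all genes projected forward from `t_k` onto the same cells
#' (see [project_velocity()]), one penalized regression per target gene:
#' `min (1/(2n)) sum_cells (v_g2 - sum_g1 A[g2, g1] vhat_g1)^2 +
#'  lam * (ratio_r * |A[g2, .]|_1 + (1 - ratio_r)/2 * |A[g2, .]|_2^2)`,
#' with no intercept and no further standardization (velocities are already
#' unit-SD per gene, and their means carry sign information).  A nonzero
#' `A[g2, g1]` means the past velocity of g1 carries unique information
#' about the present velocity of g2 -- the Granger notion of causality.
#'
#' @param outcome m x n matrix of velocities at the later time point.
#' @param predictor m x n matrix of projected past velocities on the same
#'   cells.
#' @param lam penalty magnitude, >= 0.
#' @param ratio_r l1 fraction of the penalty, in `[0, 1]`.
#' @param stimulus_gene optional gene name used as predictor only (its
#'   outcome row is skipped and left at zero).
#' @return m x m matrix `A` with rows = targets, columns = regulators; the
#'   weight of edge g1 -> g2 is `A[g2, g1]`.
#' @export
fit_interval_regression <- function(outcome, predictor, lam = 1,
                                    ratio_r = 0.5, stimulus_gene = NULL) {
  stopifnot(is.matrix(outcome), is.matrix(predictor),
            all(dim(outcome) == dim(predictor)))
  if (lam < 0) stop("lam must be >= 0")
  n <- ncol(outcome)
  if (n < 2L) stop("need at least 2 cells for the interval regression")
  m <- nrow(outcome)
  genes <- rownames(outcome)
  if (is.null(genes)) genes <- paste0("g", seq_len(m))
  X <- t(predictor)
  A <- matrix(0, m, m, dimnames = list(genes, genes))
  targets <- seq_len(m)
  if (!is.null(stimulus_gene))
    targets <- targets[genes != stimulus_gene]
  for (g in targets) {
    y <- outcome[g, ]
    ## glmnet internally rescales a no-intercept gaussian response by its
    ## root mean square, which would distort the l1/l2 balance of the
    ## stated objective; reparameterize so the objective solved is exactly
    ## (1/(2n)) RSS + lam * (r l1 + (1-r)/2 l2^2)
    sy <- sqrt(mean(y^2))
    if (sy == 0) next          # zero response: coefficients stay zero
    l1_part <- lam * ratio_r / sy
    l2_part <- lam * (1 - ratio_r)
    lam_eff <- l1_part + l2_part
    r_eff <- if (lam_eff > 0) l1_part / lam_eff else ratio_r
    fit <- glmnet::glmnet(X, y / sy, alpha = r_eff, lambda = lam_eff,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14, maxit = 1e7)
    A[g, ] <- as.numeric(fit$beta) * sy
  }
  A
}

#' Aggregate per-interval Granger matrices into a global network
#'
#' Elementwise sum over intervals; opposite-signed interval weights may
#' cancel, which is intended -- a regulation active with one sign early and
#' the opposite sign late carries no consistent global signal.
#'
#' @param A_intervals non-empty list of equally shaped matrices.
#' @return their elementwise sum.
#' @export
aggregate_global <- function(A_intervals) {
  if (length(A_intervals) == 0L) stop("empty interval list")
  dims <- vapply(A_intervals, dim, integer(2))
  if (any(dims != dims[, 1])) stop("interval matrices differ in shape")
  Reduce(`+`, A_intervals)
}

#' Granger network across all intervals of a dataset
#'
#' Runs [fit_interval_regression()] for every consecutive time pair (the
#' predictor being the earlier cohort's velocities projected onto the later
#' cohort's cells) and aggregates via [aggregate_global()].
#'
#' @param field a normalized `velocity_field` (possibly with a stimulus
#'   gene appended).
#' @param couplings matching `coupling_sequence` or list of plans.
#' @param lam,ratio_r elastic-net parameters, see
#'   [fit_interval_regression()].
#' @return object of class `granger_grn`: list with `A_intervals` (N - 1
#'   matrices, rows = targets), `A_global` (their sum), `weights`
#'   (transposed global matrix: rows = regulators, columns = targets, the
#'   orientation used for edge lists and evaluation), `lam`, `ratio_r`,
#'   `fit_report`.
#' @export
granger_network <- function(field, couplings, lam = 1, ratio_r = 0.5) {
  plans <- if (inherits(couplings, "coupling_sequence"))
    couplings$couplings else couplings
  N <- length(field$velocities)
  if (length(plans) != N - 1L)
    stop("need one coupling per consecutive interval")
  if (!isTRUE(field$normalized))
    warning("velocity field is not normalized")
  A_intervals <- vector("list", N - 1L)
  fit_report <- vector("list", N - 1L)
  for (k in seq_len(N - 1L)) {
    vhat <- project_velocity(plans[[k]], field$velocities[[k]])
    A <- fit_interval_regression(field$velocities[[k + 1L]], vhat,
                                 lam = lam, ratio_r = ratio_r,
                                 stimulus_gene = field$stimulus_gene)
    A_intervals[[k]] <- A
    fit_report[[k]] <- list(n_cells = ncol(vhat),
                            nonzero = sum(A != 0))
  }
  A_global <- aggregate_global(A_intervals)
  structure(list(A_intervals = A_intervals, A_global = A_global,
                 weights = t(A_global), lam = lam, ratio_r = ratio_r,
                 gene_names = rownames(A_global), times = field$times,
                 stimulus_gene = field$stimulus_gene,
                 fit_report = fit_report),
            class = "granger_grn")
}

#' @export
print.granger_grn <- function(x, ...) {
  cat("granger_grn:", length(x$gene_names), "genes,",
      length(x$A_intervals), "interval matrices, lambda =", x$lam,
      ", r =", x$ratio_r, "\n")
  cat("  nonzero global entries:", sum(x$A_global != 0), "/",
      length(x$A_global), "\n")
  invisible(x)
}

#' Combine per-branch network matrices
#'
#' `"sum"` adds the branch-specific weight matrices elementwise; `"maxabs"`
#' keeps, per entry, the single branch value of largest absolute weight
#' (sign retained, ties to the lowest branch index).
#'
#' @param matrices non-empty list of equally shaped weight matrices, one
#'   per branch.
#' @param rule `"sum"` or `"maxabs"`.
#' @return the combined matrix.
#' @export
combine_branches <- function(matrices, rule = c("sum", "maxabs")) {
  rule <- match.arg(rule)
  if (length(matrices) == 0L) stop("no branch matrices supplied")
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims != dims[, 1])) stop("branch matrices differ in shape")
  if (rule == "sum") return(Reduce(`+`, matrices))
  out <- matrices[[1L]]
  if (length(matrices) > 1L) for (b in 2L:length(matrices)) {
    take <- abs(matrices[[b]]) > abs(out)   # strict: ties keep lower index
    out[take] <- matrices[[b]][take]
  }
  out
}
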