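#' Transport-weighted time-lagged correlation network
#'
#' Scores the evidence that gene g1 precedes (regulates) gene g2 by the
#' lagged product of their velocities, weighted by the ancestor-descendant
#' coupling: for each interval k,
#' `C_k[g1, g2] = sum_{c, c~} v_g1(t_k, c) * v_g2(t_{k+lag}, c~) *
#'  T[c, c~]`, and `C` is the average of the `C_k` over the `N - lag`
#' intervals.  For `lag > 1` the coupling is the composition of consecutive
#' plans (see [compose_couplings()]).  With one cell per time point and
#' forced unit couplings this reduces to the classical single-trajectory
#' time-lagged correlation.  Positive entries suggest activation of g2 by
#' g1, negative entries inhibition.
#'
#' @param field a normalized `velocity_field`.
#' @param couplings a `coupling_sequence` (or list of consecutive plans)
#'   matching the field's time points.
#' @param lag positive integer < N.
#' @param include_stimulus if the field carries a stimulus gene, whether to
#'   keep it as a source-only row (its target column is always zeroed);
#'   default drops it entirely.
#' @return object of class `correlation_grn`: list with `C` (m x m,
#'   rows = earlier/regulator gene, columns = later/target gene),
#'   `per_interval`, `lag`, `gene_names`, `times`.
#' @export
lagged_correlation <- function(field, couplings, lag = 1L,
                               include_stimulus = FALSE) {
  if (!isTRUE(field$normalized))
    warning("velocity field is not normalized; the correlation matrix ",
            "will not be unit-free")
  plans <- if (inherits(couplings, "coupling_sequence"))
    couplings$couplings else couplings
  N <- length(field$velocities)
  lag <- as.integer(lag)
  if (lag < 1L || lag >= N) stop("lag must be in 1..N-1")
  if (length(plans) != N - 1L)
    stop("need one coupling per consecutive interval")
  V <- field$velocities
  per_interval <- vector("list", N - lag)
  for (k in seq_len(N - lag)) {
    Tk <- compose_couplings(plans[k:(k + lag - 1L)])
    per_interval[[k]] <- V[[k]] %*% Tk %*% t(V[[k + lag]])
    dimnames(per_interval[[k]]) <- list(field$gene_names, field$gene_names)
  }
  C <- Reduce(`+`, per_interval) / (N - lag)
  stim <- field$stimulus_gene
  if (!is.null(stim)) {
    if (include_stimulus) {
      C[, stim] <- 0           # source-only: never a target
      per_interval <- lapply(per_interval, function(M) {
        M[, stim] <- 0
        M
      })
    } else {
      keep <- setdiff(field$gene_names, stim)
      C <- C[keep, keep, drop = FALSE]
      per_interval <- lapply(per_interval,
                             function(M) M[keep, keep, drop = FALSE])
    }
  }
  structure(list(C = C, per_interval = per_interval, lag = lag,
                 gene_names = rownames(C), times = field$times),
            class = "correlation_grn")
}

#' @export
print.correlation_grn <- function(x, ...) {
  cat("correlation_grn:", length(x$gene_names), "genes, lag", x$lag, ",",
      length(x$per_interval), "interval matrices\n")
  invisible(x)
}

#' Correlation network restricted to a window of intervals
#'
#' Averages the per-interval correlation matrices over intervals
#' `from..to` (1-based, inclusive), giving a time-resolved network for that
#' window.  The full window reproduces `C` exactly.
#'
#' @param grn a `correlation_grn`.
#' @param from,to interval indices, `1 <= from <= to <= N - lag`.
#' @return m x m matrix.
#' @export
interval_correlation <- function(grn, from, to = from) {
  K <- length(grn$per_interval)
  if (from < 1L || to > K || from > to)
    stop("interval window must satisfy 1 <= from <= to <= ", K)
  Reduce(`+`, grn$per_interval[from:to]) / (to - from + 1L)
}

#' In-out degree ratio of each gene
#'
#' Ratio of total absolute incoming to total absolute outgoing correlation
#' weight (self-loops excluded).  Values below one suggest a regulator
#' (transcription-factor-like) gene, values above one a target.  A zero
#' denominator with a nonzero numerator yields `Inf`; 0/0 yields `NaN`
#' (undefined).  Optionally, only the top fraction of entries by absolute
#' value is kept before forming the ratio.
#'
#' @param C square weight matrix (rows = regulators, columns = targets).
#' @param top_fraction optional fraction in (0, 1] of off-diagonal entries
#'   to retain (by absolute value) before computing the ratio.
#' @return named numeric vector of degree ratios.
#' @export
in_out_degree <- function(C, top_fraction = NULL) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  m <- nrow(C)
  W <- C
  diag(W) <- 0
  if (!is.null(top_fraction)) {
    stopifnot(top_fraction > 0, top_fraction <= 1)
    off <- abs(W[row(W) != col(W)])
    k <- ceiling(top_fraction * length(off))
    thr <- sort(off, decreasing = TRUE)[k]
    W[abs(W) < thr] <- 0
  }
  incoming <- colSums(abs(W))
  outgoing <- rowSums(abs(W))
  deg <- incoming / outgoing
  deg[incoming == 0 & outgoing == 0] <- NaN
  names(deg) <- rownames(C)
  deg
}
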