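## Scoring of predicted weight matrices against signed ground truth.
## Self-loops are excluded from every count, ranking and metric.

## Flatten the off-diagonal of a weight matrix in (regulator, target) index
## order, aligned with the truth adjacency.
off_diagonal_pairs <- function(m) {
  reg <- rep(seq_len(m), times = m)
  tgt <- rep(seq_len(m), each = m)
  keep <- reg != tgt
  list(reg = reg[keep], tgt = tgt[keep])
}

## Average-precision AUPRC over a fixed ranking: sum of precision at each
## recall increment.  `scores` are ranked descending with ties broken by
## (regulator, target) index for a deterministic, stable order.
average_precision <- function(scores, labels, reg, tgt) {
  ord <- order(-scores, reg, tgt)
  lab <- labels[ord]
  n_pos <- sum(lab)
  cum_tp <- cumsum(lab)
  prec <- cum_tp / seq_along(lab)
  sum(prec[lab == 1L]) / n_pos
}

## Trapezoidal AUROC with tied scores averaged (Mann-Whitney form).
auroc_rank <- function(scores, labels) {
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  r <- rank(scores)          # average ranks on ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Random-classifier baseline (edge density)
#'
#' Number of true edges divided by the number of possible directed edges,
#' self-loops excluded from both counts.  The AUPRC of a random classifier
#' equals this density in expectation.
#'
#' @param truth a `ground_truth_network` with at least one edge.
#' @return edge density in (0, 1].
#' @export
random_baseline <- function(truth) {
  adj <- truth$adjacency
  m <- nrow(adj)
  n_true <- sum(adj[row(adj) != col(adj)] != 0)
  if (n_true == 0L) stop("ground truth has no edges: baseline undefined")
  n_true / (m * (m - 1L))
}

#' Score a predicted weight matrix against a signed ground truth
#'
#' Unsigned scoring ranks the off-diagonal entries by absolute weight
#' (descending, ties in stable regulator-then-target index order) against
#' the truth support, reporting average-precision AUPRC, trapezoidal AUROC
#' (tied scores averaged), the AUPRC ratio over the random baseline, and
#' early precision among the top `k = min(#true edges, #nonzero
#' predictions)` edges.  Signed scoring first zeroes every prediction on a
#' true edge whose sign contradicts the truth (predictions on non-edges
#' have no true sign and are left untouched), then scores as unsigned.
#'
#' @param weights m x m matrix, rows = regulators, columns = targets, with
#'   gene names as dimnames.
#' @param truth a `ground_truth_network` over the same gene set.
#' @param undirected if `TRUE`, both prediction and truth are symmetrized
#'   by the maximum absolute weight over the two directions before scoring.
#' @return object of class `eval_report` (a list with `auprc`, `auroc`,
#'   `signed_auprc`, `signed_auroc`, `auprc_ratio`, `signed_auprc_ratio`,
#'   `early_precision`, `ep_ratio`, `random_baseline`, `n_true_edges`,
#'   `n_possible_edges`).
#' @export
evaluate_network <- function(weights, truth, undirected = FALSE) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  genes <- rownames(weights)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(weights)))
  sym <- c(setdiff(genes, truth$gene_names),
           setdiff(truth$gene_names, genes))
  if (length(sym) > 0)
    stop("gene sets differ between prediction and truth: ",
         paste(sym, collapse = ", "))
  adj <- truth$adjacency[genes, genes]
  if (undirected) {
    ## max-|weight| symmetrization of both prediction and truth
    take <- abs(t(weights)) > abs(weights)
    weights[take] <- t(weights)[take]
    ta <- t(adj)
    take <- abs(ta) > abs(adj)
    adj[take] <- ta[take]
  }
  m <- nrow(weights)
  od <- off_diagonal_pairs(m)
  w <- weights[cbind(od$reg, od$tgt)]
  a <- adj[cbind(od$reg, od$tgt)]
  labels <- as.integer(a != 0)
  n_true <- sum(labels)
  if (n_true == 0L) stop("ground truth has no edges")
  base <- n_true / length(labels)

  score_one <- function(wv) {
    s <- abs(wv)
    auprc <- average_precision(s, labels, od$reg, od$tgt)
    auroc <- auroc_rank(s, labels)
    ## early precision: zero entries count as "not predicted"
    k <- min(n_true, sum(s > 0))
    ep <- if (k == 0L) 0 else {
      topk <- order(-s, od$reg, od$tgt)[seq_len(k)]
      sum(labels[topk]) / k
    }
    list(auprc = auprc, auroc = auroc, ep = ep)
  }
  uns <- score_one(w)
  w_signed <- w
  mismatch <- labels == 1L & w != 0 & sign(w) != sign(a)
  w_signed[mismatch] <- 0
  sgn <- score_one(w_signed)

  structure(list(auprc = uns$auprc, auroc = uns$auroc,
                 signed_auprc = sgn$auprc, signed_auroc = sgn$auroc,
                 auprc_ratio = uns$auprc / base,
                 signed_auprc_ratio = sgn$auprc / base,
                 early_precision = uns$ep, ep_ratio = uns$ep / base,
                 random_baseline = base, n_true_edges = n_true,
                 n_possible_edges = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d true / %d possible edges (baseline %.4f)\n",
              x$n_true_edges, x$n_possible_edges, x$random_baseline))
  cat(sprintf("  AUPRC %.4f (ratio %.2f)   signed AUPRC %.4f (ratio %.2f)\n",
              x$auprc, x$auprc_ratio, x$signed_auprc,
              x$signed_auprc_ratio))
  cat(sprintf("  AUROC %.4f   signed AUROC %.4f\n", x$auroc,
              x$signed_auroc))
  cat(sprintf("  early precision %.4f (ratio %.2f)\n", x$early_precision,
              x$ep_ratio))
  invisible(x)
}

#' @rdname evaluate_network
#' @param x an `eval_report`.
#' @export
as.list.eval_report <- function(x, ...) unclass(x)
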