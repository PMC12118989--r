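#' Log-transform expression values
#'
#' Applies the conventional `log(x + 1)` transform elementwise and flags the
#' dataset as transformed.  Applying it twice is an error.
#'
#' @param dataset an `expression_dataset` of nonnegative values.
#' @return the transformed dataset.
#' @export
log_transform <- function(dataset) {
  if (isTRUE(dataset$transformed))
    stop("dataset is already log-transformed")
  dataset$matrices <- lapply(dataset$matrices, log1p)
  dataset$transformed <- TRUE
  dataset
}

#' Neighbor count for the intra-cohort structure graph
#'
#' `k = max(1, floor(min(50, 0.2 n(t), 0.2 n(t~))))`, a rule that caps the
#' graph density for large cohorts while keeping small cohorts connected.
#' Both cohort sizes of the time pair enter the rule.
#'
#' @param n_t,n_t2 cohort sizes of the two time points.
#' @return integer k >= 1.
#' @export
knn_count <- function(n_t, n_t2) {
  max(1L, floor(min(50, 0.2 * n_t, 0.2 * n_t2)))
}

## Pairwise Euclidean distances between columns of X (m x n1) and Y (m x n2).
pairwise_euclidean <- function(X, Y) {
  d2 <- outer(colSums(X^2), colSums(Y^2), "+") - 2 * crossprod(X, Y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Cosine distance 1 - <x,y>/(|x||y|); zero-norm columns are an error.
pairwise_cosine <- function(X, Y) {
  nx <- sqrt(colSums(X^2)); ny <- sqrt(colSums(Y^2))
  bad <- c(which(nx == 0), which(ny == 0))
  if (length(bad) > 0)
    stop("zero-norm cell under cosine metric (first: column ", bad[1L], ")")
  1 - crossprod(X, Y) / outer(nx, ny)
}

#' Inter-cohort cost matrix
#'
#' Pairwise distances between cells of two cohorts, divided by the maximum
#' entry so the largest cost is exactly one (left as zeros if all distances
#' vanish).
#'
#' @param X_t,X_t2 m x n matrices (same gene dimension).
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return an n(t) x n(t~) normalized cost matrix.
#' @export
inter_cost_matrix <- function(X_t, X_t2, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (nrow(X_t) != nrow(X_t2)) stop("gene dimensions differ")
  D <- switch(metric,
              euclidean = pairwise_euclidean(X_t, X_t2),
              cosine = pairwise_cosine(X_t, X_t2))
  mx <- max(D)
  if (mx > 0) D <- D / mx
  unname(D)
}

#' Intra-cohort structure matrix via kNN geodesics
#'
#' Builds the union-symmetrized k-nearest-neighbor graph on the cells of one
#' cohort (Euclidean edge weights), computes all-pairs shortest-path
#' (geodesic) distances, replaces unreachable pairs by the largest finite
#' geodesic, and normalizes to maximum one.  This captures the local
#' manifold geometry of the cohort, so the transport plan can preserve it
#' across time points.
#'
#' @param X_t m x n(t) expression matrix.
#' @param k number of neighbors (see [knn_count()]).
#' @return symmetric n x n matrix with zero diagonal and max entry one.
#' @export
intra_structure_matrix <- function(X_t, k) {
  n <- ncol(X_t)
  if (n < 2L) stop("need at least 2 cells for a structure matrix")
  k <- min(as.integer(k), n - 1L)
  if (k < 1L) stop("k must be >= 1")
  D <- pairwise_euclidean(X_t, X_t)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k + 1L)]
    nb <- setdiff(nb, i)[seq_len(k)]
    adj[i, nb] <- D[i, nb]
  }
  ## union symmetrization: keep an edge if either endpoint selected it
  adj <- pmax(adj, t(adj))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  S <- igraph::distances(g, algorithm = "dijkstra")
  finite <- S[is.finite(S)]
  if (any(!is.finite(S))) S[!is.finite(S)] <- max(finite)
  mx <- max(S)
  if (mx > 0) S <- S / mx
  dimnames(S) <- NULL
  S
}

#' Marginal weights for a pair of cohorts
#'
#' Uniform mode gives every cell of a cohort equal mass.  Branch-reweighed
#' mode compensates for branch proportions that drift over time: each branch
#' receives total mass equal to its average proportion across the two time
#' points, split uniformly among that branch's cells within each cohort, so
#' the mass transported along a branch does not depend on how many of its
#' cells happened to be sampled.
#'
#' @param dataset an `expression_dataset`.
#' @param t_idx,t2_idx 1-based time indices of the pair.
#' @param mode `"uniform"` or `"branch_reweighed"`.
#' @return list with probability vectors `p` (time `t_idx`) and `q`.
#' @export
compute_marginals <- function(dataset, t_idx, t2_idx,
                              mode = c("uniform", "branch_reweighed")) {
  mode <- match.arg(mode)
  n1 <- ncol(dataset$matrices[[t_idx]])
  n2 <- ncol(dataset$matrices[[t2_idx]])
  if (mode == "uniform")
    return(list(p = rep(1 / n1, n1), q = rep(1 / n2, n2)))
  if (is.null(dataset$branch_labels))
    stop("branch_reweighed marginals require branch labels")
  b1 <- dataset$branch_labels[[t_idx]]
  b2 <- dataset$branch_labels[[t2_idx]]
  branches <- sort(unique(c(b1, b2)))
  prop1 <- table(factor(b1, levels = branches)) / n1
  prop2 <- table(factor(b2, levels = branches)) / n2
  mass <- (as.numeric(prop1) + as.numeric(prop2)) / 2
  names(mass) <- branches
  only_one <- branches[as.numeric(prop1) == 0 | as.numeric(prop2) == 0]
  if (length(only_one) > 0)
    warning("branch(es) absent at one time point: ",
            paste(only_one, collapse = ", "),
            "; their mass is assigned only where present")
  p <- numeric(n1); q <- numeric(n2)
  for (br in branches) {
    i1 <- b1 == br; i2 <- b2 == br
    if (any(i1)) p[i1] <- mass[br] / sum(i1)
    if (any(i2)) q[i2] <- mass[br] / sum(i2)
  }
  list(p = p / sum(p), q = q / sum(q))
}

#' Assemble all transport-cost inputs for one time pair
#'
#' Convenience wrapper producing the inter-cohort cost matrix, the two
#' intra-cohort structure matrices (with the neighbor count from
#' [knn_count()]) and the marginals.
#'
#' @param dataset an `expression_dataset` (typically log-transformed).
#' @param t_idx,t2_idx 1-based indices of the time pair.
#' @param metric cell-cell distance for the inter-cohort cost.
#' @param marginal_mode see [compute_marginals()].
#' @return list with `D`, `S_t`, `S_t2`, `p`, `q`, `k_neighbors`.
#' @export
build_cost_inputs <- function(dataset, t_idx, t2_idx,
                              metric = "euclidean",
                              marginal_mode = "uniform") {
  X1 <- dataset$matrices[[t_idx]]
  X2 <- dataset$matrices[[t2_idx]]
  k <- knn_count(ncol(X1), ncol(X2))
  marg <- compute_marginals(dataset, t_idx, t2_idx, marginal_mode)
  list(D = inter_cost_matrix(X1, X2, metric),
       S_t = intra_structure_matrix(X1, k),
       S_t2 = intra_structure_matrix(X2, k),
       p = marg$p, q = marg$q, k_neighbors = k)
}
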