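## Independent brute-force oracles used across the suite.  These stay
## deliberately naive (loops, enumeration) so they cannot share a bug with
## the vectorized implementations they check.

## All permutations of 1..n as a list.
all_permutations <- function(n) {
  rec <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(rec(v[-i]), function(r) c(v[i], r)))
    out
  }
  rec(seq_len(n))
}

## Exact optimal transport cost for uniform marginals on a square cost
## matrix: minimum over permutation plans (Birkhoff vertices).
lp_transport_cost <- function(D) {
  n <- nrow(D)
  best <- Inf
  for (pp in all_permutations(n))
    best <- min(best, mean(D[cbind(seq_len(n), pp)]))
  best
}

## Quadruple-loop Gromov-Wasserstein objective, squared loss.
gw_objective_loops <- function(S1, S2, Tm) {
  tot <- 0
  for (c in seq_len(nrow(Tm))) for (d in seq_len(nrow(Tm)))
    for (ct in seq_len(ncol(Tm))) for (dt in seq_len(ncol(Tm)))
      tot <- tot + (S1[c, d] - S2[ct, dt])^2 * Tm[c, ct] * Tm[d, dt]
  tot
}

## Best permutation-plan GW objective (uniform marginals, square).
best_permutation_gw <- function(S1, S2) {
  n <- nrow(S1)
  best <- Inf
  for (pp in all_permutations(n)) {
    Tp <- matrix(0, n, n)
    Tp[cbind(seq_len(n), pp)] <- 1 / n
    best <- min(best, gw_objective_loops(S1, S2, Tp))
  }
  best
}

## Textbook Dijkstra all-pairs shortest paths on a weighted adjacency
## matrix (0 = no edge).
dijkstra_all_pairs <- function(adj) {
  n <- nrow(adj)
  out <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0L) break
      u <- cand[which.min(dist[cand])]
      done[u] <- TRUE
      for (v in which(adj[u, ] > 0))
        if (dist[u] + adj[u, v] < dist[v]) dist[v] <- dist[u] + adj[u, v]
    }
    out[s, ] <- dist
  }
  out
}

## AUPRC by explicit threshold enumeration: precision/recall at every cut
## of the ranked list, area accumulated stepwise.
auprc_threshold_oracle <- function(scores, labels, reg, tgt) {
  ord <- order(-scores, reg, tgt)
  lab <- labels[ord]
  n_pos <- sum(lab)
  area <- 0
  recall_prev <- 0
  for (k in seq_along(lab)) {
    tp <- sum(lab[seq_len(k)])
    precision <- tp / k
    recall <- tp / n_pos
    area <- area + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  area
}

## Classical time-lagged correlation of a single trajectory (one cell per
## time point): sum of lagged velocity products averaged over intervals.
trajectory_lagged_corr <- function(V, lag = 1L) {
  ## V: m x N matrix of per-time velocities of one cell
  m <- nrow(V); N <- ncol(V)
  C <- matrix(0, m, m)
  for (g1 in seq_len(m)) for (g2 in seq_len(m))
    for (k in seq_len(N - lag))
      C[g1, g2] <- C[g1, g2] + V[g1, k] * V[g2, k + lag]
  C / (N - lag)
}

## Small random expression dataset for generic pipeline tests.
random_dataset <- function(m = 3L, n = c(5L, 6L, 4L), times = NULL,
                           seed = 1L) {
  set.seed(seed)
  if (is.null(times)) times <- seq_along(n) - 1
  mats <- lapply(n, function(nc) matrix(stats::rexp(m * nc), m, nc))
  expression_dataset(mats, times, gene_names = paste0("g", seq_len(m)))
}

## Random normalized cost inputs for solver tests.
random_cost_inputs <- function(n1, n2, m = 3L, seed = 1L) {
  set.seed(seed)
  X <- matrix(stats::rnorm(m * n1), m, n1)
  Y <- matrix(stats::rnorm(m * n2), m, n2)
  S1 <- as.matrix(stats::dist(t(X))); S1 <- S1 / max(S1)
  S2 <- as.matrix(stats::dist(t(Y))); S2 <- S2 / max(S2)
  D <- inter_cost_matrix(X, Y)
  list(D = D, S_t = unname(S1), S_t2 = unname(S2),
       p = rep(1 / n1, n1), q = rep(1 / n2, n2))
}

## Hand-built velocity field (bypasses the pipeline) for method tests.
manual_field <- function(V_list, gene_names = NULL, times = NULL,
                         normalized = TRUE) {
  m <- nrow(V_list[[1L]])
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(m))
  if (is.null(times)) times <- seq_along(V_list) - 1
  V_list <- lapply(V_list, function(v) {
    rownames(v) <- gene_names
    v
  })
  structure(list(velocities = V_list, gene_names = gene_names,
                 times = times, normalized = normalized, gene_sds = NULL,
                 stimulus_gene = NULL),
            class = "velocity_field")
}
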