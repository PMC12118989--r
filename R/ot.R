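## Entropic optimal transport and fused Gromov-Wasserstein solvers.
##
## Sign convention: we minimize  <T, C> + eps * sum(T log T)  over the
## transport polytope, so larger eps yields a more diffuse plan.  The
## scaling (Sinkhorn) form is used when eps is moderate; for small eps the
## kernel exp(-C/eps) underflows and the iteration runs in the log domain.

logsumexp_rows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(rowSums(exp(M - mx)))
}

logsumexp_cols <- function(M) {
  tM <- t(M)
  mx <- tM[cbind(seq_len(nrow(tM)), max.col(tM, ties.method = "first"))]
  mx + log(rowSums(exp(tM - mx)))
}

## Entropic OT by Sinkhorn scaling.  Returns the plan plus convergence info.
## The final half-iteration rescales rows so row sums match p exactly;
## convergence is declared on the column-sum violation.
sinkhorn_plan <- function(C, p, q, eps, max_iter = 1000L, tol = 1e-9,
                          log_domain = eps < 5e-3) {
  n1 <- length(p); n2 <- length(q)
  if (!log_domain) {
    K <- exp(-(C - min(C)) / eps)
    u <- rep(1, n1); v <- rep(1, n2)
    it <- 0L; viol <- Inf
    while (it < max_iter) {
      it <- it + 1L
      u <- p / as.vector(K %*% v)
      v <- q / as.vector(crossprod(K, u))
      if (!all(is.finite(u)) || !all(is.finite(v))) {
        return(sinkhorn_plan(C, p, q, eps, max_iter, tol, log_domain = TRUE))
      }
      if (it %% 10L == 0L || it == max_iter) {
        Tm <- u * K * rep(v, each = n1)
        viol <- max(abs(rowSums(Tm) - p))
        if (viol < tol) break
      }
    }
    Tm <- u * K * rep(v, each = n1)
  } else {
    f <- rep(0, n1); g <- rep(0, n2)
    it <- 0L; viol <- Inf
    while (it < max_iter) {
      it <- it + 1L
      f <- eps * log(p) - eps * logsumexp_rows(sweep(-C, 2L, g, "+") / eps)
      g <- eps * log(q) - eps * logsumexp_cols((-C + f) / eps)
      if (it %% 10L == 0L || it == max_iter) {
        Tm <- exp((outer(f, g, "+") - C) / eps)
        viol <- max(abs(rowSums(Tm) - p))
        if (viol < tol) break
      }
    }
    Tm <- exp((outer(f, g, "+") - C) / eps)
  }
  Tm <- round_to_polytope(Tm, p, q)
  list(plan = Tm, iterations = it,
       marginal_violation = max(abs(rowSums(Tm) - p),
                                abs(colSums(Tm) - q)),
       converged = viol < tol)
}

## Round a nonnegative matrix onto the transport polytope: scale rows and
## columns down to their targets, then distribute the missing mass as a
## rank-one correction.  Marginals become exact up to floating point.
round_to_polytope <- function(Tm, p, q) {
  rs <- rowSums(Tm)
  Tm <- Tm * pmin(p / pmax(rs, .Machine$double.xmin), 1)
  cs <- colSums(Tm)
  Tm <- Tm %*% diag(pmin(q / pmax(cs, .Machine$double.xmin), 1),
                    nrow = length(q))
  err_p <- p - rowSums(Tm)
  err_q <- q - colSums(Tm)
  s <- sum(err_p)
  if (s > 0) Tm <- Tm + outer(err_p, err_q) / s
  Tm
}

## Gromov-Wasserstein objective sum_{c,d,c~,d~} L(S1[c,d], S2[c~,d~]) T T.
gw_objective <- function(S1, S2, Tm, loss = c("sq", "abs")) {
  loss <- match.arg(loss)
  p <- rowSums(Tm); q <- colSums(Tm)
  if (loss == "sq") {
    drop(p %*% (S1 * S1) %*% p) + drop(q %*% (S2 * S2) %*% q) -
      2 * sum(Tm * (S1 %*% Tm %*% S2))
  } else {
    tot <- 0
    n1 <- nrow(Tm); n2 <- ncol(Tm)
    for (d in seq_len(n1)) for (dt in seq_len(n2)) {
      if (Tm[d, dt] == 0) next
      tot <- tot + Tm[d, dt] * sum(abs(outer(S1[, d], S2[, dt], "-")) * Tm)
    }
    tot
  }
}

## Linearization of the GW term at the current plan: the gradient (up to an
## additive constant that does not affect the entropic OT subproblem).
gw_gradient <- function(S1, S2, Tm, p, q, loss = c("sq", "abs")) {
  loss <- match.arg(loss)
  if (loss == "sq") {
    outer(as.vector((S1 * S1) %*% p), rep(1, length(q))) +
      outer(rep(1, length(p)), as.vector((S2 * S2) %*% q)) -
      2 * (S1 %*% Tm %*% S2)
  } else {
    n1 <- length(p); n2 <- length(q)
    G <- matrix(0, n1, n2)
    for (c in seq_len(n1)) for (ct in seq_len(n2))
      G[c, ct] <- sum(abs(outer(S1[c, ], S2[ct, ], "-")) * Tm)
    2 * G
  }
}

## Deterministic structural initialization: cells of the two cohorts are
## ranked by structure-matrix eccentricity (row sums) and mass is placed on
## the monotone rank matching (ascending-ascending or, with `flip`,
## ascending-descending), blended with a whiff of the independent coupling
## so Sinkhorn potentials stay finite.
rank_matching_init <- function(S1, S2, p, q, flip = FALSE) {
  o1 <- order(rowSums(S1))
  o2 <- order(rowSums(S2), decreasing = flip)
  n1 <- length(p); n2 <- length(q)
  T0 <- matrix(0, n1, n2)
  if (n1 == n2) {
    T0[cbind(o1, o2)] <- pmin(p[o1], q[o2])
  } else {
    ## north-west-corner filling along the rank orders
    i <- 1L; j <- 1L
    pr <- p[o1]; qr <- q[o2]
    while (i <= n1 && j <= n2) {
      mass <- min(pr[i], qr[j])
      T0[o1[i], o2[j]] <- mass
      pr[i] <- pr[i] - mass; qr[j] <- qr[j] - mass
      if (pr[i] <= 1e-15) i <- i + 1L
      if (j <= n2 && qr[j] <= 1e-15) j <- j + 1L
    }
  }
  T0 <- 0.99 * T0 / sum(T0) + 0.01 * outer(p, q)
  T0
}

#' Solve the entropic fused Gromov-Wasserstein problem for one time pair
#'
#' Minimizes `(1 - alpha) <T, D> + alpha * GW(T) + eps * sum(T log T)` over
#' couplings with marginals `p`, `q`, where `GW(T)` compares intra-cohort
#' pairwise structure under a squared-difference loss (an absolute-value
#' loss is available for small problems).  The quadratic GW term is handled
#' by a conditional-gradient loop: at each outer step the objective is
#' linearized at the current plan, the entropic OT subproblem is solved by
#' Sinkhorn iterations, and the step length along the feasible direction is
#' chosen by exact line search on the quadratic objective, so the recorded
#' objective trajectory is non-increasing.  Because the problem is
#' non-convex in the structure term, the solver deterministically tries the
#' independent coupling `p q^T` and, on small problems, two structural
#' rank-matching initializations, and returns the best local solution.
#'
#' @param cost list as returned by [build_cost_inputs()] (fields `D`,
#'   `S_t`, `S_t2`, `p`, `q`).
#' @param alpha trade-off in `[0, 1]`; `alpha = 0` is pure entropic OT on
#'   `D`, `alpha = 1` pure Gromov-Wasserstein.
#' @param epsilon entropic coefficient, > 0.
#' @param max_iter maximum outer conditional-gradient iterations.
#' @param tol relative objective-change tolerance for the outer loop.
#' @param sink_max_iter,sink_tol Sinkhorn iteration cap and marginal
#'   tolerance for the inner subproblems.
#' @param gw_loss `"sq"` (squared difference, default) or `"abs"`.
#' @param multi_init_max largest `n(t) * n(t~)` for which the extra
#'   structural initializations are tried (they triple the cost).
#' @return list with the coupling `plan` (rows sum to `p`, columns to `q`
#'   within `sink_tol`), `objective` (the fused transport objective of the
#'   plan, entropy term excluded), `objective_trace` (per accepted outer
#'   step, non-increasing), `iterations`, `marginal_violation`,
#'   `converged`.
#' @export
solve_entropic_fgw <- function(cost, alpha = 0.5, epsilon = 0.01,
                               max_iter = 50L, tol = 1e-7,
                               sink_max_iter = 1000L, sink_tol = 1e-9,
                               gw_loss = c("sq", "abs"),
                               multi_init_max = 2500L) {
  gw_loss <- match.arg(gw_loss)
  stopifnot(alpha >= 0, alpha <= 1, epsilon > 0)
  D <- cost$D; S1 <- cost$S_t; S2 <- cost$S_t2
  p <- cost$p; q <- cost$q
  fgw_obj <- function(Tm) {
    val <- (1 - alpha) * sum(Tm * D)
    if (alpha > 0) val <- val + alpha * gw_objective(S1, S2, Tm, gw_loss)
    val
  }

  if (alpha == 0) {
    sk <- sinkhorn_plan(D, p, q, epsilon, sink_max_iter, sink_tol)
    return(list(plan = sk$plan, objective = fgw_obj(sk$plan),
                objective_trace = c(fgw_obj(outer(p, q)),
                                    fgw_obj(sk$plan)),
                iterations = sk$iterations,
                marginal_violation = sk$marginal_violation,
                converged = sk$converged))
  }

  run_from <- function(T0) {
    Tm <- T0
    viol <- 0; iters <- 0L
    lin_cost <- function(Tm)
      (1 - alpha) * D + alpha * gw_gradient(S1, S2, Tm, p, q, gw_loss)
    ## phase 1: annealed mirror descent -- iterate the entropic subproblem
    ## at a decreasing temperature schedule ending at the target epsilon,
    ## which tracks a good basin before the plan sharpens
    e_hi <- max(0.05, epsilon)
    schedule <- unique(c(rev(epsilon * 2^(seq_len(
      max(0, ceiling(log2(e_hi / epsilon)))) - 1) * 2), epsilon))
    warm_iter <- min(sink_max_iter, 300L)
    for (e in schedule) {
      for (it in seq_len(min(max_iter, 25L))) {
        sk <- sinkhorn_plan(lin_cost(Tm), p, q, e, warm_iter, sink_tol)
        moved <- max(abs(sk$plan - Tm))
        Tm <- sk$plan
        if (moved < 1e-8) break
      }
    }
    ## phase 2: conditional gradient with exact line search at the target
    ## epsilon; steps are accepted only if the fused objective improves,
    ## so the trace is non-increasing
    obj <- fgw_obj(Tm)
    trace <- obj
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      sk <- sinkhorn_plan(lin_cost(Tm), p, q, epsilon, sink_max_iter,
                          sink_tol)
      viol <- max(viol, sk$marginal_violation)
      iters <- it
      Dlt <- sk$plan - Tm
      if (gw_loss == "sq") {
        ## f(tau) = f(Tm) + b tau + a tau^2 along Tm + tau * Dlt
        a <- -2 * alpha * sum(Dlt * (S1 %*% Dlt %*% S2))
        b <- (1 - alpha) * sum(D * Dlt) -
          4 * alpha * sum(Dlt * (S1 %*% Tm %*% S2))
        tau <- if (a > 0) min(1, max(0, -b / (2 * a)))
               else if (a + b < 0) 1 else 0
      } else tau <- 1
      cand <- Tm + tau * Dlt
      cobj <- fgw_obj(cand)
      if (cobj > obj - tol * max(1, abs(obj))) {
        if (cobj < obj) { Tm <- cand; obj <- cobj; trace <- c(trace, cobj) }
        converged <- TRUE
        break
      }
      Tm <- cand; obj <- cobj; trace <- c(trace, cobj)
    }
    list(plan = Tm, objective = obj, objective_trace = trace,
         iterations = iters, marginal_violation = viol,
         converged = converged)
  }

  inits <- list(outer(p, q))
  small <- length(p) * length(q) <= multi_init_max
  if (small)
    inits <- c(inits, list(rank_matching_init(S1, S2, p, q, FALSE),
                           rank_matching_init(S1, S2, p, q, TRUE)))
  runs <- lapply(inits, run_from)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  best$marginal_violation <- max(vapply(runs, `[[`, numeric(1),
                                        "marginal_violation"))
  n1 <- length(p)
  if (small && n1 == length(q) && n1 <= 12L &&
      max(abs(p - 1 / n1)) < 1e-12 && max(abs(q - 1 / n1)) < 1e-12) {
    ## tiny uniform square problems: polish by local search over
    ## permutation plans (transpositions and 3-cycles), multi-started from
    ## the rounded entropic solution, the identity and the two structural
    ## rank matchings -- the entropic and combinatorial candidates fail on
    ## different instances, so the best of both is kept
    mkperm <- function(pp) {
      Tp <- matrix(0, n1, n1)
      Tp[cbind(seq_len(n1), pp)] <- 1 / n1
      Tp
    }
    r1 <- rank(rowSums(S1), ties.method = "first")
    o2 <- order(rowSums(S2))
    starts <- list(best$plan, mkperm(seq_len(n1)),
                   mkperm(o2[r1]), mkperm(rev(o2)[r1]))
    for (T0 in starts) {
      pol <- polish_permutation(T0, fgw_obj)
      if (!is.null(pol) && pol$objective < best$objective) {
        best$plan <- pol$plan
        best$objective <- pol$objective
        best$objective_trace <- c(best$objective_trace, pol$objective)
      }
    }
  }
  if (!best$converged)
    warning("fused GW solver did not converge in ", max_iter,
            " outer iterations; returning best iterate")
  best
}

## Greedy local search over permutation plans for small uniform problems:
## round the plan to a permutation (row-wise argmax with conflict repair),
## then hill-climb over pairwise transpositions and 3-cycles.
polish_permutation <- function(Tm, objective_fn) {
  n <- nrow(Tm)
  if (n != ncol(Tm) || n > 12L) return(NULL)
  ## greedy rounding: repeatedly take the largest remaining entry
  perm <- integer(n)
  W <- Tm
  for (s in seq_len(n)) {
    ij <- arrayInd(which.max(W), dim(W))
    perm[ij[1L]] <- ij[2L]
    W[ij[1L], ] <- -Inf; W[, ij[2L]] <- -Inf
  }
  mk <- function(pp) {
    Tp <- matrix(0, n, n)
    Tp[cbind(seq_len(n), pp)] <- 1 / n
    Tp
  }
  obj <- objective_fn(mk(perm))
  repeat {
    improved <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      pp <- perm; pp[c(i, j)] <- pp[c(j, i)]
      o2 <- objective_fn(mk(pp))
      if (o2 < obj - 1e-15) { perm <- pp; obj <- o2; improved <- TRUE }
    }
    if (n >= 3L) {
      trip <- utils::combn(n, 3L)
      for (cidx in seq_len(ncol(trip))) {
        i <- trip[1L, cidx]; j <- trip[2L, cidx]; k <- trip[3L, cidx]
        for (rot in list(c(j, k, i), c(k, i, j))) {
          pp <- perm; pp[c(i, j, k)] <- perm[rot]
          o2 <- objective_fn(mk(pp))
          if (o2 < obj - 1e-15) { perm <- pp; obj <- o2; improved <- TRUE }
        }
      }
    }
    if (!improved) break
  }
  list(plan = mk(perm), objective = obj)
}

#' Solve the coupling sequence of a dataset
#'
#' Runs [build_cost_inputs()] and [solve_entropic_fgw()] for every pair of
#' consecutive time points.
#'
#' @param dataset a (log-transformed) `expression_dataset`.
#' @param config a [run_config()] supplying `alpha`, `epsilon`, `metric`
#'   and `marginal_mode`.
#' @param ... further arguments passed to [solve_entropic_fgw()].
#' @return object of class `coupling_sequence`: list with `couplings`
#'   (N - 1 plans), `marginals` (per-pair `p`, `q`), `times`,
#'   `solver_report`.
#' @export
solve_coupling_sequence <- function(dataset, config = run_config(), ...) {
  N <- length(dataset$times)
  couplings <- vector("list", N - 1L)
  marginals <- vector("list", N - 1L)
  report <- vector("list", N - 1L)
  for (k in seq_len(N - 1L)) {
    cost <- build_cost_inputs(dataset, k, k + 1L, metric = config$metric,
                              marginal_mode = config$marginal_mode)
    sol <- solve_entropic_fgw(cost, alpha = config$alpha,
                              epsilon = config$epsilon, ...)
    couplings[[k]] <- sol$plan
    marginals[[k]] <- list(p = cost$p, q = cost$q)
    report[[k]] <- sol[c("objective", "iterations", "marginal_violation",
                         "converged")]
  }
  structure(list(couplings = couplings, marginals = marginals,
                 times = dataset$times, solver_report = report),
            class = "coupling_sequence")
}

#' @export
print.coupling_sequence <- function(x, ...) {
  dims <- vapply(x$couplings, function(t) paste(dim(t), collapse = "x"),
                 character(1))
  viol <- max(vapply(x$solver_report, `[[`, numeric(1),
                     "marginal_violation"))
  cat("coupling_sequence:", length(x$couplings), "interval plans (",
      paste(dims, collapse = ", "), ")\n")
  cat("  max marginal violation:", format(viol, digits = 3), "\n")
  invisible(x)
}

#' Compose consecutive couplings into a longer-lag plan
#'
#' Converts each coupling to a Markov kernel (rows normalized to sum one),
#' chains the kernels, and restores the source marginal, yielding the joint
#' ancestor-descendant plan across `lag` intervals.  A cell with no
#' descendants (zero row) is repaired by teleporting to the target marginal,
#' with a warning.
#'
#' @param couplings list of chain-compatible coupling matrices (consecutive
#'   intervals).
#' @return a single coupling matrix from the first source cohort to the
#'   last target cohort; total mass one.
#' @export
compose_couplings <- function(couplings) {
  stopifnot(length(couplings) >= 1L)
  if (length(couplings) == 1L) return(couplings[[1L]])
  acc <- couplings[[1L]]
  for (j in 2L:length(couplings)) {
    Tj <- couplings[[j]]
    if (ncol(acc) != nrow(Tj))
      stop("couplings are not chain-compatible at position ", j)
    rs <- rowSums(Tj)
    K <- Tj / rs
    if (any(rs == 0)) {
      warning("zero row(s) in coupling ", j,
              "; teleporting to the target marginal")
      qj <- colSums(Tj)
      qj <- qj / sum(qj)
      K[rs == 0, ] <- rep(qj, each = sum(rs == 0))
    }
    acc <- acc %*% K
  }
  acc
}

#' Barycentric projection of cell states through a coupling
#'
#' Predicts, for every source cell, its state in the target cohort as the
#' coupling-weighted average of target expression vectors (rows of the
#' coupling normalized to sum one).  Applying the transposed coupling gives
#' ancestor predictions.
#'
#' @param coupling n_source x n_target plan.
#' @param X_target m x n_target expression matrix.
#' @return m x n_source matrix of predicted states.
#' @export
barycentric_project <- function(coupling, X_target) {
  if (ncol(coupling) != ncol(X_target))
    stop("coupling and target cohort dimensions disagree")
  rs <- rowSums(coupling)
  if (any(rs == 0))
    stop("zero row in coupling: repair with compose_couplings first")
  tcrossprod(X_target, coupling / rs)
}
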