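## Stochastic simulator of destructively sampled single-cell time courses
## driven by a known signed regulatory network.
##
## Dynamics per cell (Euler-Maruyama, reflected at zero):
##   dx_g = (beta_g * sigmoid(sum_h W[h,g] x_h + b_g + u_g * s(t))
##           - gamma_g * x_g) dt + noise_sd dW
## with s(t) = 1 for t >= 0 when a stimulus is configured.  Each
## observation time gets a fresh, independent cohort of cells recorded at
## that time only (destructive sampling: no cell is measured twice).

sigmoid <- function(z) 1 / (1 + exp(-z))

## Deterministic substream seed for cohort i of run `seed`; cohorts are
## order-independent because each draws from its own stream.
cohort_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Simulation configuration
#'
#' @param network list with `gene_names`, real-valued signed weight matrix
#'   `W` (`W[h, g]` = effect of gene h on gene g), basal inputs `b`,
#'   production scales `beta`, degradation rates `gamma` (all length m,
#'   `gamma > 0`), and optional `u` (stimulus input per gene, active from
#'   `t = 0`).
#' @param times observation time stamps (strictly increasing, >= 0).
#' @param cells_per_time cohort size at each observation time.
#' @param noise_sd diffusion magnitude of the SDE.
#' @param dt Euler integration step; must satisfy `dt <= min spacing / 10`.
#' @param init_sd SD of the jitter around the basal fixed point at `t = 0`.
#' @param branch optional list with `time` (when branch-specific dynamics
#'   switch on), `W` (named list of per-branch weight matrices) and
#'   `proportions` (vector, or N x B matrix of per-time branch fractions,
#'   rows summing to one).
#' @param dropout_rate Bernoulli zeroing probability applied last.
#' @param count_model `"none"` (continuous values) or `"poisson"`
#'   (counts with mean `count_scale * x`).
#' @param count_scale Poisson scale.
#' @param seed integer master seed; all randomness derives from it through
#'   per-cohort substreams.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(network, times, cells_per_time = 100L,
                              noise_sd = 0.1, dt = NULL, init_sd = 0.05,
                              branch = NULL, dropout_rate = 0,
                              count_model = c("none", "poisson"),
                              count_scale = 10, seed = 1L) {
  stopifnot(all(diff(times) > 0), cells_per_time >= 2L,
            noise_sd >= 0, dropout_rate >= 0, dropout_rate < 1)
  if (any(network$gamma <= 0)) stop("degradation rates must be > 0")
  max_dt <- min(diff(times)) / 10
  if (is.null(dt)) dt <- max_dt
  if (dt > max_dt + 1e-12)
    stop("dt must be <= min time spacing / 10 (", signif(max_dt, 3), ")")
  structure(list(network = network, times = as.numeric(times),
                 cells_per_time = as.integer(cells_per_time),
                 noise_sd = noise_sd, dt = dt, init_sd = init_sd,
                 branch = branch, dropout_rate = dropout_rate,
                 count_model = match.arg(count_model),
                 count_scale = count_scale, seed = as.integer(seed)),
            class = "simulation_config")
}

## Basal fixed point of the deterministic system with the stimulus off.
basal_fixed_point <- function(network, iters = 200L) {
  m <- length(network$gene_names)
  x <- rep(0, m)
  for (i in seq_len(iters))
    x <- network$beta *
      sigmoid(as.vector(crossprod(network$W, x)) + network$b) /
      network$gamma
  x
}

## Advance a cohort matrix X (m x n) from t0 to t1 under weight matrix W.
advance_cohort <- function(X, t0, t1, network, W, noise_sd, dt) {
  if (t1 <= t0) return(X)
  n_steps <- round((t1 - t0) / dt)
  h <- (t1 - t0) / n_steps
  sq <- sqrt(h)
  u <- if (is.null(network$u)) 0 else network$u
  for (s in seq_len(n_steps)) {
    drift <- network$beta *
      sigmoid(crossprod(W, X) + network$b + u) -
      network$gamma * X
    X <- X + drift * h
    if (noise_sd > 0)
      X <- X + noise_sd * sq * matrix(stats::rnorm(length(X)), nrow(X))
    X <- pmax(X, 0)
    if (any(abs(X) > 1e6))
      stop("unstable integration (|x| > 1e6); use a smaller dt")
  }
  X
}

#' Simulate a time-stamped single-cell dataset from a known network
#'
#' Every cell is an independent stochastic path of the regulatory SDE; for
#' each observation time a fresh cohort is integrated from `t = 0` and
#' recorded at that time only, emulating the destructive sampling of
#' single-cell sequencing.  With branching, cells are assigned to branches
#' by the configured proportions and follow the branch-specific weight
#' matrix after the branch time.  Optional Poisson counting noise and
#' dropout are applied last.  Fully reproducible from the seed.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (the [ground_truth_network()] of signed edges implied by the base
#'   weight matrix).
#' @export
simulate_dataset <- function(config) {
  net <- config$network
  m <- length(net$gene_names)
  N <- length(config$times)
  n <- config$cells_per_time
  xstar <- basal_fixed_point(net)
  branch <- config$branch
  branch_names <- if (is.null(branch)) NULL else names(branch$W)

  branch_counts <- function(i) {
    prop <- branch$proportions
    if (is.matrix(prop)) prop <- prop[i, ]
    cnt <- floor(prop * n)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(prop * n - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    cnt
  }

  matrices <- vector("list", N)
  labels <- if (is.null(branch)) NULL else vector("list", N)
  for (i in seq_len(N)) {
    set.seed(cohort_seed(config$seed, i))
    X0 <- pmax(xstar + config$init_sd * matrix(stats::rnorm(m * n), m, n), 0)
    t_obs <- config$times[i]
    if (is.null(branch)) {
      X <- advance_cohort(X0, 0, t_obs, net, net$W,
                          config$noise_sd, config$dt)
    } else {
      cnt <- branch_counts(i)
      lab <- rep(branch_names, times = cnt)
      X <- advance_cohort(X0, 0, min(t_obs, branch$time), net, net$W,
                          config$noise_sd, config$dt)
      if (t_obs > branch$time) {
        pos <- 0L
        for (b in seq_along(branch_names)) {
          if (cnt[b] == 0L) next
          j <- pos + seq_len(cnt[b]); pos <- pos + cnt[b]
          X[, j] <- advance_cohort(X[, j, drop = FALSE], branch$time,
                                   t_obs, net, branch$W[[b]],
                                   config$noise_sd, config$dt)
        }
      }
      labels[[i]] <- lab
    }
    if (config$count_model == "poisson")
      X <- matrix(stats::rpois(length(X), config$count_scale * X),
                  m, n)
    if (config$dropout_rate > 0)
      X <- X * (matrix(stats::runif(length(X)), m, n) >=
                  config$dropout_rate)
    rownames(X) <- net$gene_names
    matrices[[i]] <- X
  }
  dataset <- expression_dataset(matrices, config$times,
                                gene_names = net$gene_names,
                                branch_labels = labels)
  adj <- sign(net$W)
  diag(adj) <- 0L
  truth <- ground_truth_network(adj, net$gene_names)
  list(dataset = dataset, truth = truth)
}

#' Inject dropout into an expression dataset
#'
#' Sets every entry independently to zero with the given probability,
#' reproducibly from the seed.
#'
#' @param dataset an `expression_dataset`.
#' @param rate dropout probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the perturbed dataset.
#' @export
inject_dropout <- function(dataset, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(dataset)
  set.seed(as.integer(seed))
  dataset$matrices <- lapply(dataset$matrices, function(X)
    X * (matrix(stats::runif(length(X)), nrow(X)) >= rate))
  dataset
}

#' Downsample branches on a per-time schedule
#'
#' Removes cells uniformly at random within each branch x time stratum to
#' reach the scheduled keep fractions (rounded down, at least one cell
#' kept), creating time-varying branch imbalance.
#'
#' @param dataset an `expression_dataset` with branch labels.
#' @param schedule named list: for each branch, a keep fraction in
#'   `(0, 1]`, either a scalar or one value per time point.
#' @param seed integer seed.
#' @return the downsampled dataset.
#' @export
downsample_branches <- function(dataset, schedule, seed = 1L) {
  if (is.null(dataset$branch_labels))
    stop("dataset has no branch labels")
  branches <- unique(unlist(dataset$branch_labels))
  unknown <- setdiff(names(schedule), branches)
  if (length(unknown) > 0)
    stop("schedule names unknown branch(es): ",
         paste(unknown, collapse = ", "))
  N <- length(dataset$times)
  set.seed(as.integer(seed))
  for (i in seq_len(N)) {
    lab <- dataset$branch_labels[[i]]
    keep <- rep(TRUE, length(lab))
    for (br in names(schedule)) {
      fr <- schedule[[br]]
      if (length(fr) > 1L) fr <- fr[i]
      stopifnot(fr > 0, fr <= 1)
      idx <- which(lab == br)
      n_keep <- max(1L, floor(fr * length(idx)))
      if (n_keep < length(idx))
        keep[sample(idx, length(idx) - n_keep)] <- FALSE
    }
    dataset$matrices[[i]] <- dataset$matrices[[i]][, keep, drop = FALSE]
    dataset$cell_ids[[i]] <- dataset$cell_ids[[i]][keep]
    dataset$branch_labels[[i]] <- lab[keep]
    if (!is.null(dataset$cell_weights)) {
      w <- dataset$cell_weights[[i]][keep]
      dataset$cell_weights[[i]] <- w / sum(w)
    }
    if (!is.null(dataset$pseudotime))
      dataset$pseudotime[[i]] <- dataset$pseudotime[[i]][keep]
  }
  dataset
}

## Shared kinetic scales of the built-in fixtures: logistic interaction
## networks with strong edges (|W| = 3), production scale 4, unit
## degradation, inactive basal input -4 (targets of inhibitory edges start
## active at +2 so repression is observable), stimulus input +6.
fixture_network <- function(gene_names, edges, inhib_active_basal = TRUE,
                            stimulus_target = NULL) {
  m <- length(gene_names)
  W <- matrix(0, m, m, dimnames = list(gene_names, gene_names))
  for (e in edges) W[e[[1L]], e[[2L]]] <- 3 * e[[3L]]
  b <- rep(-4, m)
  names(b) <- gene_names
  if (inhib_active_basal) {
    inhibited <- gene_names[colSums(W < 0) > 0]
    b[inhibited] <- 2
  }
  u <- rep(0, m)
  names(u) <- gene_names
  if (!is.null(stimulus_target)) u[stimulus_target] <- 6
  list(gene_names = gene_names, W = W, b = b, beta = rep(4, m),
       gamma = rep(1, m), u = u)
}

#' Built-in simulation fixtures
#'
#' Small deterministic-seed datasets for testing every pipeline stage:
#' * `tiny2` -- two genes, activator edge A -> B, stimulus on A, 3 time
#'   points, 30 cells each;
#' * `tiny2_inhib` -- the inhibitor variant A -| B (B starts active);
#' * `fn4like` -- four genes with a branching structure (two branches with
#'   different active arms) and an inhibition feedback loop, stimulus;
#' * `tree8` -- eight genes wired as a tree of 7 signed edges rooted at
#'   the stimulus-driven gene, 10 time points, 200 cells each.
#'
#' @param name fixture name.
#' @param seed integer seed (datasets are reproducible per seed).
#' @param cells_per_time optional override of the fixture's cohort size.
#' @return list with `dataset`, `truth`, `config`, `stimulus_time`
#'   (1-based index of the stimulus time point).
#' @export
make_fixture <- function(name = c("tiny2", "tiny2_inhib", "fn4like",
                                  "tree8"),
                         seed = 1L, cells_per_time = NULL) {
  name <- match.arg(name)
  spec <- switch(
    name,
    tiny2 = list(
      net = fixture_network(c("A", "B"), list(list("A", "B", +1)),
                            stimulus_target = "A"),
      times = 0:2, cells = 30L),
    tiny2_inhib = list(
      net = fixture_network(c("A", "B"), list(list("A", "B", -1)),
                            stimulus_target = "A"),
      times = 0:2, cells = 30L),
    fn4like = list(
      net = fixture_network(
        c("g1", "g2", "g3", "g4"),
        list(list("g1", "g2", +1), list("g1", "g3", +1),
             list("g3", "g4", +1), list("g4", "g1", -1)),
        stimulus_target = "g1"),
      times = 0:5, cells = 40L,
      branch = TRUE),
    tree8 = list(
      net = fixture_network(
        paste0("g", 1:8),
        list(list("g1", "g2", +1), list("g1", "g3", +1),
             list("g2", "g4", +1), list("g2", "g5", +1),
             list("g3", "g6", +1), list("g3", "g7", -1),
             list("g4", "g8", +1)),
        stimulus_target = "g1"),
      times = 0:9, cells = 200L))
  if (!is.null(cells_per_time)) spec$cells <- as.integer(cells_per_time)
  branch <- NULL
  if (isTRUE(spec$branch)) {
    ## two branches: each silences one arm of the g1 -> {g2, g3} split
    W_a <- spec$net$W; W_a["g1", "g3"] <- 0
    W_b <- spec$net$W; W_b["g1", "g2"] <- 0
    branch <- list(time = 2, W = list(brA = W_a, brB = W_b),
                   proportions = c(0.5, 0.5))
  }
  config <- simulation_config(spec$net, times = spec$times,
                              cells_per_time = spec$cells,
                              noise_sd = 0.1, branch = branch,
                              seed = seed)
  sim <- simulate_dataset(config)
  list(dataset = sim$dataset, truth = sim$truth, config = config,
       stimulus_time = 1L)
}
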