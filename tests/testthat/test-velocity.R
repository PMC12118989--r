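## near-identity couplings for hand-built tests
diag_plan <- function(n) diag(n) / n

test_that("stationary data gives near-zero velocities", {
  set.seed(3)
  X <- matrix(rexp(3 * 5), 3, 5)
  ds <- expression_dataset(list(X, X, X), times = 0:2, transformed = TRUE)
  plans <- list(diag_plan(5), diag_plan(5))
  f <- compute_velocities(ds, plans)
  for (k in 1:3) expect_equal(max(abs(f$velocities[[k]])), 0)
})

test_that("finite-difference assignment follows the time spacing", {
  set.seed(6)
  m <- 2L; n <- 4L
  mk <- function() matrix(rexp(m * n), m, n)
  X <- list(mk(), mk(), mk())
  plans <- list(diag_plan(n), diag_plan(n))

  ## equally spaced: centered velocity is the plain average
  ds <- expression_dataset(X, times = 0:2, transformed = TRUE)
  f <- compute_velocities(ds, plans)
  vf <- (X[[2L]] - X[[1L]])   # identity coupling, dt = 1
  vb <- (X[[3L]] - X[[2L]])
  expect_equal(f$velocities[[1L]], X[[2L]] - X[[1L]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(f$velocities[[2L]], (vf + vb) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(f$velocities[[3L]], X[[3L]] - X[[2L]], tolerance = 1e-12,
               ignore_attr = TRUE)

  ## times (0, 1, 3): centered weights are 1/3 forward, 2/3 backward
  ds <- expression_dataset(X, times = c(0, 1, 3), transformed = TRUE)
  f <- compute_velocities(ds, plans)
  vfwd <- (X[[3L]] - X[[2L]]) / 2
  vbwd <- (X[[2L]] - X[[1L]]) / 1
  expect_equal(f$velocities[[2L]], vfwd / 3 + 2 * vbwd / 3,
               tolerance = 1e-12, ignore_attr = TRUE)

  ## N = 2: forward at t1, backward at t2, no centered points
  ds <- expression_dataset(X[1:2], times = 0:1, transformed = TRUE)
  f <- compute_velocities(ds, plans[1L])
  expect_equal(f$velocities[[1L]], X[[2L]] - X[[1L]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(f$velocities[[2L]], X[[2L]] - X[[1L]], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("velocities are linear in the expression values", {
  set.seed(8)
  mk <- function() matrix(rexp(6), 2, 3)
  X <- list(mk(), mk(), mk())
  plans <- list(diag_plan(3), diag_plan(3))
  ds1 <- expression_dataset(X, times = 0:2, transformed = TRUE)
  ds2 <- expression_dataset(lapply(X, `*`, 2), times = 0:2,
                            transformed = TRUE)
  f1 <- compute_velocities(ds1, plans)
  f2 <- compute_velocities(ds2, plans)
  for (k in 1:3)
    expect_equal(f2$velocities[[k]], 2 * f1$velocities[[k]],
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a translated cloud yields velocity close to the offset", {
  set.seed(19)
  n <- 60L
  delta <- c(1, -2, 0)
  X1 <- matrix(rnorm(3 * n, sd = 0.2), 3, n)
  X2 <- X1[, sample(n)] + delta
  ds <- expression_dataset(list(X1, X2), times = c(0, 1),
                           transformed = TRUE)
  cpl <- solve_coupling_sequence(ds, run_config(epsilon = 1e-3))
  f <- compute_velocities(ds, cpl)
  err <- abs(rowMeans(f$velocities[[1L]]) - delta)
  expect_true(all(err <= 0.05 * max(abs(delta))))
})

test_that("velocity projection is the column-normalized average", {
  V <- matrix(c(1, 10, 2, 20, 3, 30), 2, 3)  # m = 2, 3 source cells
  ## one nonzero per column: copies the matched source cell
  Tm <- matrix(c(0, 0.5, 0, 0, 0, 0.5), 3, 2)
  vh <- project_velocity(Tm, V)
  expect_equal(vh[, 1L], V[, 2L])
  expect_equal(vh[, 2L], V[, 3L])
  ## uniform plan: every projection is the mean source velocity
  Tu <- matrix(1 / 6, 3, 2)
  expect_equal(project_velocity(Tu, V),
               cbind(rowMeans(V), rowMeans(V)))
  ## per-column loop oracle on a random 3 x 5 plan
  set.seed(23)
  Tm <- matrix(runif(15), 3, 5)
  V <- matrix(rnorm(6), 2, 3)
  vh <- project_velocity(Tm, V)
  for (ct in 1:5) {
    w <- Tm[, ct] / sum(Tm[, ct])
    for (g in 1:2)
      expect_equal(vh[g, ct], sum(w * V[g, ]), tolerance = 1e-12)
  }
  Tm[, 2L] <- 0
  expect_error(project_velocity(Tm, V), "zero column")
})

test_that("normalization gives pooled unit SD without centering", {
  ## two-point example under the population SD convention
  f <- manual_field(list(matrix(-2, 1, 1), matrix(2, 1, 1)),
                    normalized = FALSE)
  nf <- normalize_velocities(f)
  expect_equal(nf$gene_sds[["g1"]], 2)
  expect_equal(unname(nf$velocities[[1L]][1, 1]), -1)
  expect_equal(unname(nf$velocities[[2L]][1, 1]), 1)

  set.seed(29)
  f <- manual_field(list(matrix(rnorm(8, mean = 3), 2, 4),
                         matrix(rnorm(6, mean = 3), 2, 3)),
                    normalized = FALSE)
  f$velocities[[1L]][2, ] <- 0      # an all-zero gene
  f$velocities[[2L]][2, ] <- 0
  nf <- normalize_velocities(f)
  pooled <- do.call(cbind, nf$velocities)
  sd_pop <- sqrt(rowMeans((pooled - rowMeans(pooled))^2))
  expect_equal(sd_pop[[1L]], 1, tolerance = 1e-12)
  expect_equal(unname(nf$velocities[[1L]][2, ]), rep(0, 4))   # untouched
  expect_equal(nf$zero_sd_genes, "g2")
  ## means must not be removed
  expect_gt(abs(mean(pooled[1L, ])), 0.5)
  expect_error(normalize_velocities(nf), "already")
})

test_that("the stimulus gene is unit velocity at its time and exempt", {
  set.seed(33)
  f <- manual_field(list(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3),
                         matrix(rnorm(6), 2, 3)),
                    normalized = FALSE)
  nf <- normalize_velocities(f)
  sf <- add_stimulus_gene(nf, 1L)
  expect_equal(length(sf$gene_names), 3L)
  expect_equal(unname(sf$velocities[[1L]]["stimulus", ]), rep(1, 3))
  expect_equal(unname(sf$velocities[[2L]]["stimulus", ]), rep(0, 3))
  expect_equal(unname(sf$velocities[[3L]]["stimulus", ]), rep(0, 3))
  expect_equal(unname(sf$gene_sds[["stimulus"]]), 1)
  expect_identical(add_stimulus_gene(nf, NULL), nf)
  ## never a target downstream: correlation column is zeroed
  plans <- list(diag_plan(3), diag_plan(3))
  C <- lagged_correlation(sf, plans, include_stimulus = TRUE)
  expect_equal(unname(C$C[, "stimulus"]), rep(0, 3))
  edges <- write_edge_list(C$C, 1, withr::local_tempfile(),
                           exclude_targets = "stimulus")
  expect_false("stimulus" %in% edges$target)
})
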