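mk_truth <- function(m, edges, genes = paste0("g", seq_len(m))) {
  adj <- matrix(0L, m, m, dimnames = list(genes, genes))
  for (e in edges) adj[e[1L], e[2L]] <- if (length(e) > 2L) e[3L] else 1L
  ground_truth_network(adj, genes)
}

test_that("a perfect ranking scores 1 on every metric", {
  truth <- mk_truth(4, list(c(1, 2), c(2, 3, -1), c(3, 4)))
  W <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  W[1, 2] <- 5; W[2, 3] <- -4; W[3, 4] <- 3
  rep <- evaluate_network(W, truth)
  expect_equal(rep$auprc, 1)
  expect_equal(rep$auroc, 1)
  expect_equal(rep$signed_auprc, 1)
  expect_equal(rep$early_precision, 1)
  expect_equal(rep$auprc_ratio, 1 / rep$random_baseline)
})

test_that("the random baseline is the off-diagonal edge density", {
  truth <- mk_truth(10, lapply(1:5, function(i) c(i, i + 1)))
  expect_equal(random_baseline(truth), 5 / 90)
  truth <- mk_truth(5, list(c(1, 2), c(2, 5), c(4, 1)))
  expect_equal(random_baseline(truth), 3 / 20)
  full <- ground_truth_network(matrix(1L, 3, 3) - diag(1L, 3))
  expect_equal(random_baseline(full), 1)
  empty <- ground_truth_network(matrix(0L, 3, 3))
  expect_error(random_baseline(empty), "no edges")
  expect_error(evaluate_network(matrix(rnorm(9), 3, 3,
                                       dimnames = list(paste0("g", 1:3),
                                                       paste0("g", 1:3))),
                                empty), "no edges")
})

test_that("gene mismatches are reported as a symmetric difference", {
  truth <- mk_truth(3, list(c(1, 2)))
  W <- matrix(0, 3, 3, dimnames = list(c("g1", "g2", "gX"),
                                       c("g1", "g2", "gX")))
  expect_error(evaluate_network(W, truth), "gX")
  expect_error(evaluate_network(W, truth), "g3")
})

test_that("signed scoring only demotes sign-mismatched true edges", {
  truth <- mk_truth(4, list(c(1, 2, 1), c(2, 3, -1), c(3, 4, 1)))
  W <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  W[1, 2] <- 5; W[2, 3] <- -4; W[3, 4] <- 3; W[4, 1] <- -2.5
  rep <- evaluate_network(W, truth)
  ## all predicted signs correct: signed metrics equal unsigned exactly
  expect_equal(rep$signed_auprc, rep$auprc)
  expect_equal(rep$signed_auroc, rep$auroc)
  ## flip one true edge's sign: signed metrics drop, unsigned unchanged
  W2 <- W; W2[2, 3] <- 4
  rep2 <- evaluate_network(W2, truth)
  expect_equal(rep2$auprc, rep$auprc)
  expect_lt(rep2$signed_auprc, rep2$auprc)
  ## non-edge predictions keep their weight whatever their sign
  W3 <- W; W3[4, 1] <- 2.5
  rep3 <- evaluate_network(W3, truth)
  expect_equal(rep3$signed_auprc, rep$signed_auprc)
})

test_that("signed AUPRC never exceeds unsigned and scaling changes nothing", {
  set.seed(97)
  for (i in 1:10) {
    truth <- mk_truth(5, list(c(1, 2, 1), c(2, 3, -1), c(4, 5, 1),
                              c(5, 1, -1)))
    W <- matrix(rnorm(25), 5, 5,
                dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
    rep <- evaluate_network(W, truth)
    expect_lte(rep$signed_auprc, rep$auprc + 1e-12)
    rep_scaled <- evaluate_network(3.7 * W, truth)
    expect_equal(rep_scaled$auprc, rep$auprc, tolerance = 1e-12)
    expect_equal(rep_scaled$auroc, rep$auroc, tolerance = 1e-12)
    expect_equal(rep_scaled$ep_ratio, rep$ep_ratio, tolerance = 1e-12)
  }
})

test_that("average precision equals the threshold-enumeration oracle", {
  set.seed(101)
  for (i in 1:25) {
    m <- 5L
    n_edges <- sample(2:8, 1)
    idx <- which(diag(m) == 0)
    pick <- sample(idx, n_edges)
    adj <- matrix(0L, m, m); adj[pick] <- sample(c(-1L, 1L), n_edges,
                                                 replace = TRUE)
    genes <- paste0("g", 1:m)
    dimnames(adj) <- list(genes, genes)
    truth <- ground_truth_network(adj)
    W <- matrix(rnorm(m * m), m, m, dimnames = list(genes, genes))
    ## sprinkle ties and zeros to exercise the tie-break path
    W[sample(length(W), 5)] <- 0
    W[sample(length(W), 4)] <- 0.5
    rep <- evaluate_network(W, truth)
    od <- velogrn:::off_diagonal_pairs(m)
    scores <- abs(W[cbind(od$reg, od$tgt)])
    labels <- as.integer(adj[cbind(od$reg, od$tgt)] != 0)
    expect_equal(rep$auprc,
                 auprc_threshold_oracle(scores, labels, od$reg, od$tgt),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(103)
  truth <- mk_truth(6, list(c(1, 2), c(2, 3), c(3, 4), c(5, 6), c(6, 1)))
  W <- matrix(rnorm(36), 6, 6,
              dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  rep <- evaluate_network(W, truth)
  od <- velogrn:::off_diagonal_pairs(6)
  scores <- abs(W[cbind(od$reg, od$tgt)])
  labels <- as.integer(truth$adjacency[cbind(od$reg, od$tgt)] != 0)
  ref <- pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                             direction = "<"))
  expect_equal(rep$auroc, as.numeric(ref), tolerance = 1e-12)
})

test_that("early precision uses k = min(true edges, nonzero predictions)", {
  truth <- mk_truth(4, list(c(1, 2), c(2, 3), c(3, 4)))
  W <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  W[1, 2] <- 3; W[2, 4] <- 1   # only 2 nonzero predictions, 3 true edges
  rep <- evaluate_network(W, truth)
  expect_equal(rep$early_precision, 0.5)   # 1 hit of top k = 2
  expect_equal(rep$ep_ratio, 0.5 / (3 / 12))
})

test_that("undirected scoring symmetrizes by maximum absolute weight", {
  truth <- mk_truth(3, list(c(1, 2)))
  W <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  W[2, 1] <- -4     # predicted in the reverse direction only
  rep_dir <- evaluate_network(W, truth)
  rep_und <- evaluate_network(W, truth, undirected = TRUE)
  expect_lt(rep_dir$auprc, 1)
  expect_gt(rep_und$auprc, rep_dir$auprc)
})
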