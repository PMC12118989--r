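test_that("cells are grouped by time label and ordered by time", {
  mat <- matrix(1:12, 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  mp <- withr::local_tempfile(fileext = ".csv")
  mdp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(gene = rownames(mat), mat), mp, row.names = FALSE,
            quote = FALSE)
  writeLines(c("cell_id,time", "c1,1", "c2,0", "c3,1", "c4,0"), mdp)
  ds <- read_expression(mp, mdp)
  expect_equal(length(ds$times), 2L)
  expect_equal(ds$times, c(0, 1))
  expect_equal(n_cells(ds), c(2L, 2L))
  expect_equal(ds$cell_ids[[1L]], c("c2", "c4"))
  expect_equal(unname(ds$matrices[[2L]][, "c3"]), c(7, 8, 9))
})

test_that("metadata errors are caught and named", {
  mat <- matrix(1:12, 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  mp <- withr::local_tempfile(fileext = ".csv")
  mdp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(gene = rownames(mat), mat), mp, row.names = FALSE,
            quote = FALSE)
  writeLines(c("cell_id,time", "c1,0", "c2,0", "c3,1", "c5,1"), mdp)
  expect_error(read_expression(mp, mdp), "c4")
  writeLines(c("cell_id,time", paste0("c", 1:4, ",0")), mdp)
  expect_error(read_expression(mp, mdp), "fewer than 2")
})

test_that("MatrixMarket input matches the dense reader", {
  ds0 <- random_dataset(m = 4L, n = c(3L, 3L), seed = 7)
  dense <- do.call(cbind, ds0$matrices)
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "expr.mtx")
  Matrix::writeMM(Matrix::Matrix(dense, sparse = TRUE), mtx)
  writeLines(rownames(dense), file.path(dir, "genes.txt"))
  writeLines(colnames(dense), file.path(dir, "cells.txt"))
  meta <- file.path(dir, "meta.csv")
  write.csv(data.frame(cell_id = colnames(dense),
                       time = rep(ds0$times, n_cells(ds0))),
            meta, row.names = FALSE, quote = FALSE)
  mp <- file.path(dir, "expr.csv")
  write_expression(ds0, mp, file.path(dir, "meta2.csv"))
  ds_mtx <- read_expression(mtx, meta)
  ds_csv <- read_expression(mp, meta)
  expect_equal(ds_mtx$matrices, ds_csv$matrices, tolerance = 1e-12)
  expect_equal(ds_mtx$gene_names, ds_csv$gene_names)
})

test_that("write then read is the identity on values and grouping", {
  ds0 <- random_dataset(m = 3L, n = c(4L, 5L, 3L), times = c(0, 0.5, 2),
                        seed = 3)
  dir <- withr::local_tempdir()
  write_expression(ds0, file.path(dir, "m.csv"), file.path(dir, "md.csv"))
  ds1 <- read_expression(file.path(dir, "m.csv"), file.path(dir, "md.csv"))
  expect_equal(ds1$times, ds0$times)
  expect_equal(ds1$gene_names, ds0$gene_names)
  expect_equal(ds1$matrices, ds0$matrices, tolerance = 1e-12)
})

test_that("pseudotime quantile binning slices evenly and monotonically", {
  expect_equal(bin_pseudotime(1:10, 5), rep(0:4, each = 2))
  pt <- c(0.9, 0.1, 0.5, 0.7, 0.3, 0.2)
  b <- bin_pseudotime(pt, 2)
  expect_equal(b, c(1L, 0L, 1L, 1L, 0L, 0L))
  ## brute-force sort-and-slice oracle on random pseudotimes
  set.seed(11)
  pt <- runif(100)
  b <- bin_pseudotime(pt, 7)
  sizes <- rep(100 %/% 7, 7); sizes[1:(100 %% 7)] <- sizes[1:(100 %% 7)] + 1
  expect_equal(as.integer(table(b)), sizes)
  oracle <- integer(100)
  oracle[order(pt)] <- rep(0:6, times = sizes)
  expect_equal(b, oracle)
  ## monotone: earlier pseudotime never lands in a later bin
  ord <- order(pt)
  expect_true(all(diff(b[ord]) >= 0))
})

test_that("pseudotime binning handles ties and degenerate input", {
  ## tie at a block boundary goes to the lower bin
  b <- bin_pseudotime(c(1, 2, 2, 3), 2)
  expect_equal(b, c(0L, 0L, 0L, 1L))
  expect_error(bin_pseudotime(rep(1, 5), 2), "identical")
  expect_error(bin_pseudotime(1:3, 1), ">= 2")
})

test_that("edge lists keep the top fraction, ranked and self-loop free", {
  W <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(W, 0.5, out)
  tab <- read.delim(out)
  expect_equal(nrow(tab), 0L)

  W[1, 3] <- 2.5
  write_edge_list(W, 0.01, out)
  tab <- read.delim(out)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$regulator, "g1")
  expect_equal(tab$target, "g3")
  expect_equal(tab$sign, "+")

  set.seed(5)
  W <- matrix(rnorm(100), 10, 10,
              dimnames = list(paste0("g", 1:10), paste0("g", 1:10)))
  edges <- write_edge_list(W, 0.1, out)
  expect_equal(nrow(edges), ceiling(0.1 * 90))
  offd <- abs(W[row(W) != col(W)])
  expect_equal(sort(abs(edges$weight), decreasing = TRUE),
               sort(offd, decreasing = TRUE)[1:9])
  expect_true(all(edges$regulator != edges$target))
  expect_true(all(diff(abs(edges$weight)) <= 0))
})

test_that("ground-truth networks round-trip through edge lists", {
  adj <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  adj["a", "b"] <- 1L; adj["b", "c"] <- -1L
  gt <- ground_truth_network(adj)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ground_truth(gt, path)
  gt2 <- read_ground_truth(path, gene_names = letters[1:3])
  expect_equal(gt2$adjacency, gt$adjacency)
})

test_that("run configuration reads YAML with overrides and validates", {
  cfg <- run_config()
  expect_equal(cfg$alpha, 0.5)
  expect_equal(cfg$epsilon, 0.01)
  expect_equal(cfg$lam, 1)
  expect_equal(cfg$ratio_r, 0.5)
  expect_equal(cfg$lag, 1L)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.3", "epsilon: 0.05", "metric: cosine"), yml)
  cfg <- read_run_config(yml, overrides = list(alpha = 0.7))
  expect_equal(cfg$alpha, 0.7)
  expect_equal(cfg$epsilon, 0.05)
  expect_equal(cfg$metric, "cosine")
  writeLines("nonsense: 1", yml)
  expect_error(read_run_config(yml), "unknown config key")
  expect_error(run_config(alpha = 2), "alpha")
})
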