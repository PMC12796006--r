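test_that("cells aggregate to spot discs with arcsinh means", {
  lat <- toy_lattice(c(0, 100), c(0, 0))
  cells <- data.frame(
    cell_id = paste0("c", 1:4),
    x = c(0, 5, 28, 100), y = c(0, 0, 0, 0),
    M = c(0, 10, 3, 20))
  # c3 sits 28 um from spot 1 and 72 um from spot 2: outside both discs
  agg <- aggregate_cells_to_spots(cells, lat, cofactor = 5)
  sp <- agg$spot_protein
  expect_equal(agg$unassigned, "c3")
  expect_equal(sp$n_cells, c(2L, 1L))
  expect_equal(sp$M[1], (asinh(0 / 5) + asinh(10 / 5)) / 2)
  expect_equal(sp$M[2], asinh(20 / 5))
  # conservation: assigned + unassigned = total
  expect_equal(sum(sp$n_cells) + length(agg$unassigned), nrow(cells))
  expect_error(aggregate_cells_to_spots(cells, lat, cofactor = 0),
               "cofactor")
})

test_that("empty spots carry NA, not zero", {
  lat <- toy_lattice(c(0, 100, 200), c(0, 0, 0))
  cells <- data.frame(cell_id = "c1", x = 0, y = 0, M = 7)
  sp <- aggregate_cells_to_spots(cells, lat)$spot_protein
  expect_equal(sp$n_cells, c(1L, 0L, 0L))
  expect_true(all(is.na(sp$M[2:3])))
})

test_that("kNN weights: hex first ring, row sums, asymmetry", {
  g <- generate_lattice_and_bone(sim_config(n_rows = 7, n_cols = 7, seed = 2,
                                            n_bone_blobs = 0))
  W <- knn_weights(g$lattice, k = 6)
  expect_s4_class(W, "dgCMatrix")
  expect_equal(unname(Matrix::rowSums(W)), rep(1, nrow(g$lattice)))
  # an interior spot's neighbors are exactly the six spots one pitch away
  lat <- g$lattice[order(g$lattice$spot_id), ]
  i <- which(lat$array_row == 3 & lat$array_col == 3)
  nb <- which(W[i, ] > 0)
  d <- sqrt((lat$x[nb] - lat$x[i])^2 + (lat$y[nb] - lat$y[i])^2)
  expect_equal(d, rep(100, 6), tolerance = 1e-9)
  # kNN is directed: corner spots reach further than their in-neighbors
  expect_false(Matrix::isSymmetric(W))
  Wb <- knn_weights(g$lattice, k = 6, row_standardize = FALSE)
  expect_true(all(Wb@x == 1))
  expect_error(knn_weights(g$lattice, k = 0), "k")
  expect_error(knn_weights(g$lattice[1:3, ], k = 6), "more spots")
})

test_that("Lee's L: unit self-weights reduce to 1 / -1", {
  set.seed(23)
  x <- setNames(rnorm(30), sprintf("s%02d", 1:30))
  W <- diag(30)
  dimnames(W) <- list(names(x), names(x))
  expect_equal(lees_l(x, x, W), 1)
  expect_equal(lees_l(x, -x, W), -1)
  expect_error(lees_l(x, setNames(rep(1, 30), names(x)), W), "variance")
})

test_that("Lee's L matches the literal double-sum oracle", {
  g <- generate_lattice_and_bone(sim_config(n_rows = 7, n_cols = 8, seed = 3,
                                            n_bone_blobs = 0))
  lat <- g$lattice[order(g$lattice$spot_id), ][1:50, ]
  set.seed(24)
  x <- setNames(rnorm(50), lat$spot_id)
  y <- setNames(rnorm(50), lat$spot_id)
  for (std in c(TRUE, FALSE)) {
    W <- knn_weights(lat, k = 6, row_standardize = std)
    expect_equal(lees_l(x, y, W),
                 lees_l_oracle(x[rownames(W)], y[rownames(W)], W),
                 tolerance = 1e-10)
  }
  W <- knn_weights(lat, k = 6)
  # symmetry in the two variables and affine invariance
  expect_equal(lees_l(x, y, W), lees_l(y, x, W), tolerance = 1e-12)
  expect_equal(lees_l(2 * x + 3, y, W), lees_l(x, y, W), tolerance = 1e-12)
  expect_equal(lees_l(x, -5 * y + 1, W), -lees_l(x, y, W),
               tolerance = 1e-12)
})

test_that("Lee's L drops spots with missing protein pairwise", {
  g <- generate_lattice_and_bone(sim_config(n_rows = 6, n_cols = 6, seed = 5,
                                            n_bone_blobs = 0))
  W <- knn_weights(g$lattice, k = 4)
  ids <- rownames(W)
  set.seed(25)
  x <- setNames(rnorm(length(ids)), ids)
  y <- setNames(rnorm(length(ids)), ids)
  y[1:5] <- NA
  L <- lees_l(x, y, W)
  keep <- ids[-(1:5)]
  Wk <- W[keep, keep]
  Wk <- Wk / Matrix::rowSums(Wk)
  expect_equal(L, lees_l_oracle(x[keep], y[keep], Wk), tolerance = 1e-10)
})

test_that("permutation inference: determinism and the extreme case", {
  g <- generate_lattice_and_bone(sim_config(n_rows = 7, n_cols = 8, seed = 6,
                                            n_bone_blobs = 0))
  W <- knn_weights(g$lattice, k = 6)
  ids <- rownames(W)
  lat <- g$lattice[match(ids, g$lattice$spot_id), ]
  x <- setNames(lat$x + 0.3 * lat$y, ids)  # strongly autocorrelated
  r1 <- lees_l_permutation(x, x, W, n_perm = 99, seed = 11)
  r2 <- lees_l_permutation(x, x, W, n_perm = 99, seed = 11)
  expect_identical(r1, r2)
  expect_equal(r1$p, 1 / 100)
  expect_error(lees_l_permutation(x, x, W, n_perm = 0), "n_perm")
})

test_that("marker/transcript concordance holds on the default dataset", {
  sim <- default_sim()
  cells <- sim$cells[, setdiff(names(sim$cells), "spot_id")]
  agg <- aggregate_cells_to_spots(cells, sim$lattice)
  sp <- agg$spot_protein
  expect_equal(sum(sp$n_cells) + length(agg$unassigned), nrow(cells))
  W <- knn_weights(sim$lattice, k = 6)
  cd33 <- setNames(sp$CD33, sp$spot_id)
  sc <- default_scores()
  aml <- setNames(rowSums(sc[, grep("^AML_", colnames(sc))]), rownames(sc))
  res <- lees_l_permutation(cd33, aml, W, n_perm = 199, seed = 1)
  expect_gt(res$L, 0)
  expect_lt(res$p, 0.01)
})
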