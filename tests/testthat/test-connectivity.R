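test_that("penetrated voxels follow the half-open boundary geometry", {
  g <- voxel_grid(c(10, 3, 3))
  # 20 points along x spanning 5 voxels
  s <- streamline(cbind(seq(2, 6, length.out = 20), 1, 1))
  expect_identical(as.integer(voxels_penetrated(s, g)),
                   viscdti:::lin_index(g, cbind(3:7, 2L, 2L)))
  # fiber entirely inside one voxel
  s1 <- streamline(cbind(c(4.1, 4.2, 4.3), 1, 1))
  expect_length(voxels_penetrated(s1, g), 1L)
  # a point exactly on the shared face goes to the higher-index voxel
  sf <- streamline(rbind(c(4.5, 1, 1), c(4.5, 1, 1)))
  expect_identical(as.integer(voxels_penetrated(sf, g)),
                   viscdti:::lin_index(g, c(6, 2, 2)))
  # out-of-grid points skipped and counted
  so <- streamline(rbind(c(-5, 1, 1), c(4, 1, 1)))
  out <- voxels_penetrated(so, g)
  expect_identical(attr(out, "n_outside"), 1L)
})

test_that("direct matrix is the union of per-fiber cliques", {
  fx <- make_worked_example()
  v <- fx$voxels
  g <- build_connectivity(fx$fibers, fx$grid)
  expect_true(g$X[v["A"], v["B"]] && g$X[v["A"], v["C"]])
  expect_false(g$X[v["A"], v["D"]])
  expect_identical(g$X, Matrix::t(g$X))
  expect_true(all(Matrix::diag(g$X) == FALSE))
  # degrees as stated for the worked example
  deg <- Matrix::rowSums(g$X)
  expect_equal(unname(deg[v[c("F", "D", "E")]]), c(1, 2, 2))
  # union is idempotent under fiber duplication, invariant to order
  dup <- fiber_set(c(fx$fibers$streamlines,
                     rev(fx$fibers$streamlines)), space = "reference")
  expect_equal(as.matrix(build_direct(dup, fx$grid)), as.matrix(g$X),
               ignore_attr = TRUE)
  # empty set gives an all-zero matrix
  empty <- build_direct(fiber_set(list(), space = "reference"), fx$grid)
  expect_identical(Matrix::nnzero(empty), 0L)
})

test_that("indirect matrix marks two-hop-but-not-one-hop pairs", {
  fx <- make_worked_example()
  v <- fx$voxels
  g <- build_connectivity(fx$fibers, fx$grid)
  expect_true(all(g$Y[v["A"], v[c("D", "E", "F")]]))
  expect_false(g$Y[v["A"], v["B"]])     # direct, hence not indirect
  expect_identical(g$Y, Matrix::t(g$Y))
  expect_identical(Matrix::nnzero(g$X & g$Y), 0L)  # disjoint supports
  # no fibers: no indirect structure
  X0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                             dims = c(5, 5))
  expect_identical(Matrix::nnzero(build_indirect(methods::as(X0, "lMatrix"))), 0L)
})

test_that("VISC reproduces the worked example at both alpha settings", {
  fx <- make_worked_example()
  g <- build_connectivity(fx$fibers, fx$grid)
  A <- fx$voxels["A"]
  expect_equal(unname(compute_visc(g, alpha = 1)$values[A]), 5 / 3)
  expect_equal(unname(compute_visc(g, alpha = 0)$values[A]), 5)
  # isolated voxels report 0, not NaN
  expect_identical(unique(compute_visc(g)$values[-fx$voxels]), 0)
  expect_error(compute_visc(g, alpha = 1.5), "alpha")
})

test_that("VISC agrees with a brute-force two-hop oracle", {
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    A <- random_adjacency(n, p = runif(1, 0.05, 0.3))
    X <- methods::as(Matrix::Matrix(A > 0, sparse = TRUE), "lMatrix")
    Matrix::diag(X) <- FALSE
    got <- visc_index(X, build_indirect(X), alpha = 1)
    expect_equal(got, visc_bruteforce(A), tolerance = 1e-12)
  }
})

test_that("VISC is permutation-equivariant and at least 1 when defined", {
  set.seed(5)
  A <- random_adjacency(30, 0.15)
  X <- methods::as(Matrix::Matrix(A > 0, sparse = TRUE), "lMatrix")
  v <- visc_index(X, build_indirect(X))
  perm <- sample(30)
  Xp <- X[perm, perm]
  vp <- visc_index(Xp, build_indirect(Xp))
  expect_equal(vp, v[perm], tolerance = 1e-12)
  # every indirect neighbour has at least one direct connection
  den <- Matrix::rowSums(build_indirect(X))
  expect_true(all(v[den > 0] >= 1))
})

test_that("fiber count and mean length maps summarise penetration", {
  fx <- make_worked_example()
  v <- fx$voxels
  cnt <- fiber_count_map(fx$fibers, fx$grid)$values
  expect_identical(unname(cnt[v["B"]]), 2)
  expect_identical(unname(cnt[v["F"]]), 1)
  g10 <- voxel_grid(c(10, 3, 3))
  one <- fiber_set(list(straight_streamline(5, y = 1, z = 1)))
  ml <- mean_fiber_length_map(one, g10)$values
  pen <- voxels_penetrated(one$streamlines[[1]], g10)
  expect_equal(unique(ml[pen]), 5)
  expect_true(all(ml[-pen] == 0))
  # no fibers: both maps all zero
  none <- fiber_set(list())
  expect_true(all(fiber_count_map(none, g10)$values == 0))
  expect_true(all(mean_fiber_length_map(none, g10)$values == 0))
})

test_that("chain mode connects only consecutive voxels", {
  g <- voxel_grid(c(10, 3, 3))
  fs <- fiber_set(list(straight_streamline(6, y = 1, z = 1)))
  Xc <- build_direct(fs, g, mode = "chain")
  Xq <- build_direct(fs, g, mode = "clique")
  pen <- voxels_penetrated(fs$streamlines[[1]], g)
  expect_identical(Matrix::nnzero(Xc), 2L * (length(pen) - 1L))
  expect_identical(Matrix::nnzero(Xq),
                   as.integer(length(pen) * (length(pen) - 1L)))
})
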