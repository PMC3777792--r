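test_that("seed lattice respects spacing and the strict FA threshold", {
  g <- voxel_grid(c(10, 10, 10))
  fa8 <- scalar_map(array(0.8, g$dim), "FA", g)
  expect_identical(nrow(generate_seeds(fa8)), 1000L)
  fa1 <- scalar_map(array(0.1, g$dim), "FA", g)
  expect_warning(s <- generate_seeds(fa1), "no seeds")
  expect_identical(nrow(s), 0L)
  # FA exactly at the threshold is excluded ("strictly above")
  fa3 <- scalar_map(array(0.3, g$dim), "FA", g)
  expect_warning(expect_identical(nrow(generate_seeds(fa3)), 0L))
})

test_that("straight uniform field yields straight slab-spanning tracks", {
  ph <- slab_phantom(nx = 20, nyz = 8)
  fa <- compute_fa(ph$field)
  tp <- tracking_params()
  s <- track_fiber(c(10, 3.5, 3.5), ph$field, fa, tp)
  # spans the volume between outermost voxel centers, one step slack
  expect_gte(s$length, 19 - 2 * tp$step)
  expect_true(all(abs(s$points[, 2] - 3.5) < 1e-9))
  expect_true(all(abs(s$points[, 3] - 3.5) < 1e-9))
  expect_identical(unname(s$termination),
                   c("out-of-bounds", "out-of-bounds"))
  # deterministic
  s2 <- track_fiber(c(10, 3.5, 3.5), ph$field, fa, tp)
  expect_identical(s$points, s2$points)
})

test_that("zero-FA background stops propagation immediately", {
  g <- voxel_grid(c(6, 6, 6))
  tf <- uniform_tensor_field(g, diag(3) * 7e-4)   # isotropic, FA = 0
  s <- track_fiber(c(3, 3, 3), tf, compute_fa(tf), tracking_params())
  expect_identical(nrow(s$points), 1L)
  expect_identical(s$length, 0)
  expect_error(track_fiber(c(50, 3, 3), tf, compute_fa(tf),
                           tracking_params()), "outside")
})

test_that("a 90 degree interface triggers the angle criterion", {
  f <- interface_field()
  s <- track_fiber(c(3, 9.5, 1), f, compute_fa(f), tracking_params())
  expect_true("angle" %in% s$termination)
  # the forward half stops at the orientation interface, not beyond
  expect_lt(max(s$points[, 1]), 12)
})

test_that("no streamline turns more than the angle limit per step", {
  tr <- make_tract_phantom(n_x = 24, n_yz = 7)
  tp <- tracking_params(min_length = 3, max_length = 10)
  fs <- track_fibers(tr$field, tp)
  cosmax <- cos(tp$max_angle * pi / 180) - 1e-9
  ok <- vapply(fs$streamlines, function(s) {
    d <- diff(s$points)
    n <- sqrt(rowSums(d^2))
    u <- d / n
    if (nrow(u) < 2) return(TRUE)
    all(rowSums(u[-nrow(u), , drop = FALSE] *
                  u[-1, , drop = FALSE]) >= cosmax)
  }, logical(1))
  expect_true(all(ok))
})

test_that("length filter keeps the inclusive 10-140 mm window", {
  lens <- c(5, 10, 100, 140, 141)
  fs <- fiber_set(lapply(lens, straight_streamline))
  kept <- filter_fibers(fs, tracking_params())
  expect_equal(sort(fiber_lengths(kept)), c(10, 100, 140))
  expect_length(filter_fibers(fiber_set(list())), 0L)
  fifty <- fiber_set(lapply(rep(50, 4), straight_streamline))
  expect_length(filter_fibers(fifty), 4L)
})

test_that("raising the FA stop threshold never grows penetrated volume", {
  tr <- make_tract_phantom(n_x = 30, n_yz = 7, radius = 2.5)
  tp <- tracking_params(min_length = 3, max_length = 10)
  vols <- vapply(c(0.15, 0.25, 0.35), function(thr) {
    p <- tp; p$fa_stop <- thr
    fs <- track_fibers(tr$field, p)
    length(unique(unlist(lapply(fs$streamlines, voxels_penetrated,
                                grid = tr$grid))))
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("fiber warping displaces, clamps, and composes with inverses", {
  g <- voxel_grid(c(12, 12, 12))
  fs <- fiber_set(list(streamline(cbind(seq(2, 9, 0.5), 5, 5))))
  zero <- displacement_field(array(0, c(g$dim, 3)), g)
  expect_identical(warp_fibers(fs, zero)$streamlines[[1]]$points,
                   fs$streamlines[[1]]$points)
  u <- array(0, c(g$dim, 3)); u[, , , 1] <- 1.5; u[, , , 3] <- -2
  tr <- displacement_field(u, g)
  w <- warp_fibers(fs, tr)
  expect_equal(w$streamlines[[1]]$points,
               fs$streamlines[[1]]$points +
                 matrix(c(1.5, 0, -2), 15, 3, byrow = TRUE))
  expect_equal(w$streamlines[[1]]$length, fs$streamlines[[1]]$length)
  expect_identical(w$space, "reference")
  # forward warp then approximate inverse: error within residual bound
  us <- array(0, c(g$dim, 3))
  ctr <- viscdti:::grid_centers(g)
  us[, , , 1] <- 1.2 * sin(2 * pi * ctr[, 2] / 22)
  fwd <- displacement_field(us, g)
  inv <- approximate_inverse(fwd)
  rt <- warp_fibers(warp_fibers(fs, fwd), inv)
  err <- sqrt(rowSums((rt$streamlines[[1]]$points -
                         fs$streamlines[[1]]$points)^2))
  expect_lt(mean(err), inv$residual_mean + 3 * inv$residual_sd + 0.05)
  # clamped out-of-domain points are counted with a warning
  far <- fiber_set(list(streamline(cbind(c(5, 40), 5, 5))))
  expect_warning(wf <- warp_fibers(far, tr), "clamped")
  expect_identical(attr(wf, "n_clamped"), 1L)
})
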