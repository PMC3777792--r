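test_that("worked-example fixture has the canonical six-voxel topology", {
  fx <- make_worked_example()
  expect_length(fx$fibers, 3L)
  sets <- lapply(fx$fibers$streamlines, voxels_penetrated,
                 grid = fx$grid)
  expect_identical(sort(unique(unlist(sets))),
                   sort(unname(fx$voxels)))          # 6 voxels in play
  v <- fx$voxels
  expect_setequal(as.integer(sets[[1]]), unname(v[c("A", "B", "C")]))
  expect_setequal(as.integer(sets[[2]]), unname(v[c("D", "B", "E")]))
  expect_setequal(as.integer(sets[[3]]), unname(v[c("C", "F")]))
})

test_that("simulated signal follows monoexponential attenuation", {
  g <- voxel_grid(c(2, 2, 2))
  dirs <- gradient_scheme(25)
  # isotropic D = 1e-3 I at b = 1000: every direction attenuates by e^-1
  dwi <- synthesize_dwi(uniform_tensor_field(g, diag(3) * 1e-3),
                        dirs, bval = 1000, s0 = 1000)
  expect_equal(as.numeric(dwi$signals[, , , 2:26]),
               rep(1000 * exp(-1), 8 * 25), tolerance = 1e-12)
  # zero tensor: no attenuation anywhere
  dwi0 <- synthesize_dwi(uniform_tensor_field(g, matrix(0, 3, 3)),
                         dirs, bval = 1000, s0 = 500)
  expect_true(all(dwi0$signals == 500))
  # invalid inputs
  expect_error(synthesize_dwi(uniform_tensor_field(g, diag(3) * 1e-3),
                              dirs * 2, 1000), "unit-norm")
  expect_error(synthesize_dwi(uniform_tensor_field(g, -diag(3) * 1e-3),
                              dirs, 1000), "semi-definite")
})

test_that("Rician noise is seeded and reproducible", {
  g <- voxel_grid(c(3, 3, 3))
  tf <- uniform_tensor_field(g, diag(3) * 1e-3)
  d1 <- synthesize_dwi(tf, gradient_scheme(25), 1000,
                       noise_sigma = 20, seed = 11)
  d2 <- synthesize_dwi(tf, gradient_scheme(25), 1000,
                       noise_sigma = 20, seed = 11)
  d3 <- synthesize_dwi(tf, gradient_scheme(25), 1000,
                       noise_sigma = 20, seed = 12)
  expect_identical(d1$signals, d2$signals)
  expect_false(identical(d1$signals, d3$signals))
  expect_true(all(d1$signals >= 0))     # magnitude signal
})

test_that("bundle phantom places oriented tensors and lesions", {
  ph <- slab_phantom()
  fa <- compute_fa(ph$field)
  on <- ph$bundle_mask
  # on-bundle FA for eigenvalues (1.7, 0.3, 0.3)e-3, closed form
  lam <- c(1.7e-3, 3e-4, 3e-4)
  fa_expect <- sqrt(1.5) * sqrt(sum((lam - mean(lam))^2)) /
    sqrt(sum(lam^2))
  expect_equal(unique(round(fa$values[on], 10)), round(fa_expect, 10))
  expect_true(all(fa$values[!on] == 0))  # isotropic background
  # principal direction along the bundle axis
  idx <- which(as.logical(on))[1]
  expect_equal(abs(ph$field$evecs[, 1, idx]), c(1, 0, 0))

  sp <- phantom_spec(c(12, 6, 6), bundles = list(), lesion = list(
    type = "sphere", center = c(6, 3, 3), radius = 2))
  ph2 <- generate_phantom(sp)
  md <- compute_md(ph2$field)$values
  expect_gt(mean(md[ph2$lesion_mask]), mean(md[!ph2$lesion_mask]))
  expect_error(phantom_spec(c(5, 5, 5), lesion = list(
    type = "box", lo = c(1, 1, 1), hi = c(9, 2, 2))), "outside")
})

test_that("tract phantom hits its FA targets and decays to the ends", {
  tr <- make_tract_phantom(n_x = 20, n_yz = 7, radius = 2.5)
  fa <- compute_fa(tr$field)$values
  # peak sits half a voxel from the tract midpoint on an even grid
  expect_equal(max(fa), 0.8 - 0.75 * 0.5 / 9.5, tolerance = 1e-3)
  core <- fa[, 4, 4]
  expect_true(all(diff(core[10:20]) <= 1e-9))  # monotone decay
})

test_that("cohorts are reproducible and degenerate without noise", {
  sp <- phantom_spec(c(8, 5, 5), bundles = list(
    bundle_spec(rbind(c(-1, 2, 2), c(9, 2, 2)), radius = 1.5)),
    lesion = list(type = "box", lo = c(4, 2, 2), hi = c(5, 4, 4)),
    noise_sigma = 25, seed = 99)
  co <- generate_cohort(sp, n_controls = 9)
  expect_length(co$controls, 9L)       # 9 controls + 1 lesioned subject
  expect_s3_class(co$stroke, "tensor_field")
  expect_identical(co, generate_cohort(sp, n_controls = 9))
  expect_error(generate_cohort(sp, n_controls = 1), "n_controls")

  sp0 <- sp; sp0$noise_sigma <- 0
  co0 <- generate_cohort(sp0, n_controls = 3)
  expect_identical(co0$controls[[1]], co0$controls[[2]])
  expect_identical(co0$controls[[2]], co0$controls[[3]])
})
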