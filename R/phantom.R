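#' Fiber-bundle specification for synthetic phantoms
#'
#' Describes one cylindrical white-matter-like bundle: a centerline
#' polyline (mm), a radius, and the on-bundle tensor eigenvalues.
#' Voxels whose center lies within `radius` of the centerline receive
#' an anisotropic tensor oriented along the local centerline tangent.
#' With `taper = TRUE` the eigenvalues blend linearly from the bundle
#' values at the axis to the background values at the rim, producing a
#' radially decaying FA profile (useful for FA-threshold sweeps).
#'
#' @param centerline (n x 3) matrix of mm points, n >= 2.
#' @param radius bundle radius in mm, > 0.
#' @param lambdas length-3 on-bundle eigenvalues (mm^2/s),
#'   `lambda1 > lambda2 = lambda3` for a prolate tensor.
#' @param taper logical; radial eigenvalue taper toward background.
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(centerline, radius,
                        lambdas = c(1.7e-3, 3e-4, 3e-4),
                        taper = FALSE) {
  centerline <- as_points(centerline)
  if (nrow(centerline) < 2L) stop("centerline needs at least 2 points")
  if (radius <= 0) stop("radius must be positive")
  if (any(lambdas <= 0)) stop("eigenvalues must be positive")
  structure(list(centerline = centerline, radius = radius,
                 lambdas = sort(as.numeric(lambdas), decreasing = TRUE),
                 taper = isTRUE(taper)),
            class = "bundle_spec")
}

#' Phantom specification
#'
#' Collects everything needed to generate a reproducible synthetic
#' tensor field: grid geometry, fiber bundles, an optional lesion, the
#' Rician noise level used when simulating diffusion signals, and a
#' random seed. With a fixed seed all derived outputs are
#' bit-reproducible.
#'
#' @param dim grid shape (3 integers).
#' @param vsize voxel size (mm).
#' @param bundles list of [bundle_spec()] objects. Overlapping bundles
#'   are resolved by first-listed precedence.
#' @param background_adc isotropic background diffusivity (mm^2/s).
#' @param lesion optional list describing a lesion in voxel indices:
#'   `list(type = "box", lo = c(i,j,k), hi = c(i,j,k))` or
#'   `list(type = "sphere", center = c(i,j,k), radius = voxels)`.
#'   Lesion voxels are overwritten with an isotropic tensor of elevated
#'   diffusivity (`lesion_md_factor` times the background MD),
#'   mimicking the raised diffusivity of chronic lesions.
#' @param lesion_md_factor multiplier for lesion MD (default 2).
#' @param noise_sigma Rician noise level in signal units (default 0).
#' @param seed random seed for noise realisations.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim, vsize = 1, bundles = list(),
                         background_adc = 7e-4, lesion = NULL,
                         lesion_md_factor = 2, noise_sigma = 0,
                         seed = 1L) {
  grid <- voxel_grid(dim, vsize)
  if (!is.null(lesion)) {
    lesion$type <- match.arg(lesion$type, c("box", "sphere"))
    if (lesion$type == "box") {
      if (any(lesion$lo < 1) || any(lesion$hi > grid$dim))
        stop("lesion box extends outside the grid")
    } else {
      if (any(lesion$center < 1) || any(lesion$center > grid$dim))
        stop("lesion center outside the grid")
    }
  }
  structure(list(grid = grid, bundles = bundles,
                 background_adc = background_adc, lesion = lesion,
                 lesion_md_factor = lesion_md_factor,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared distance from points (n x 3) to a segment [a, b], plus tangent
point_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap <- sweep(pts, 2L, a, "-")
  t <- if (len2 > 0) pmin(pmax(as.vector(ap %*% ab) / len2, 0), 1) else 0
  proj <- outer(t, ab) + matrix(a, nrow(pts), 3L, byrow = TRUE)
  d2 <- rowSums((pts - proj)^2)
  list(d2 = d2, tangent = ab / sqrt(max(len2, .Machine$double.eps)))
}

#' Generate a synthetic tensor field from a phantom specification
#'
#' Voxels within a bundle radius get the bundle tensor oriented along
#' the local centerline tangent (nearest segment); remaining voxels get
#' an isotropic background tensor; lesion voxels (if any) are
#' overwritten with an isotropic tensor of elevated mean diffusivity.
#' Overlapping bundles are resolved by first-listed precedence.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `field` (a `tensor_field`), `bundle_mask`
#'   and `lesion_mask` (logical arrays).
#' @export
#' @examples
#' sp <- phantom_spec(c(12, 7, 7), bundles = list(
#'   bundle_spec(rbind(c(-1, 3, 3), c(12, 3, 3)), radius = 2)))
#' ph <- generate_phantom(sp)
#' round(max(compute_fa(ph$field)$values), 4)  # on-bundle FA
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  nvox <- n_voxels(grid)
  ctr <- grid_centers(grid)
  bg <- spec$background_adc
  evals <- matrix(bg, nvox, 3L)
  evecs <- array(diag(3), dim = c(3L, 3L, nvox))
  assigned <- rep(FALSE, nvox)
  for (b in spec$bundles) {
    best_d2 <- rep(Inf, nvox)
    best_tan <- matrix(0, nvox, 3L)
    cl <- b$centerline
    for (s in seq_len(nrow(cl) - 1L)) {
      ps <- point_segment(ctr, cl[s, ], cl[s + 1L, ])
      upd <- ps$d2 < best_d2
      best_d2[upd] <- ps$d2[upd]
      best_tan[upd, ] <- matrix(ps$tangent, sum(upd), 3L, byrow = TRUE)
    }
    inside <- !assigned & best_d2 <= b$radius^2
    if (!any(inside)) next
    frac <- if (b$taper) sqrt(best_d2[inside]) / b$radius else 0
    lam <- cbind((1 - frac) * b$lambdas[1] + frac * bg,
                 (1 - frac) * b$lambdas[2] + frac * bg,
                 (1 - frac) * b$lambdas[3] + frac * bg)
    evals[inside, ] <- lam
    for (v in which(inside)) {
      e1 <- best_tan[v, ]
      evecs[, , v] <- orthonormal_frame(e1)
    }
    assigned <- assigned | inside
  }
  lesion_mask <- lesion_voxels(spec, grid)
  if (any(lesion_mask)) {
    lmd <- bg * spec$lesion_md_factor
    evals[lesion_mask, ] <- lmd
    evecs[, , which(lesion_mask)] <- diag(3)
    assigned[lesion_mask] <- FALSE
  }
  D <- six_from_eigen(evals, evecs)
  field <- structure(list(D = D, evals = evals, evecs = evecs,
                          valid = rep(TRUE, nvox),
                          neg_flag = rep(FALSE, nvox), grid = grid),
                     class = "tensor_field")
  list(field = field,
       bundle_mask = array(assigned, dim = grid$dim),
       lesion_mask = array(lesion_mask, dim = grid$dim))
}

lesion_voxels <- function(spec, grid) {
  nvox <- n_voxels(grid)
  mask <- rep(FALSE, nvox)
  if (is.null(spec[["lesion"]])) return(mask)
  ijk <- ijk_index(grid, seq_len(nvox))
  if (spec[["lesion"]]$type == "box") {
    inside <- rep(TRUE, nvox)
    for (d in 1:3)
      inside <- inside & ijk[, d] >= spec[["lesion"]]$lo[d] &
        ijk[, d] <= spec[["lesion"]]$hi[d]
    mask <- inside
  } else {
    d2 <- rowSums(sweep(ijk, 2L, spec[["lesion"]]$center, "-")^2)
    mask <- d2 <= spec[["lesion"]]$radius^2
  }
  mask
}

# complete e1 to a right-handed orthonormal frame (columns e1 e2 e3)
orthonormal_frame <- function(e1) {
  e1 <- e1 / sqrt(sum(e1^2))
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3, deparse.level = 0)
}

# per-voxel 6-element tensors from eigen systems
six_from_eigen <- function(evals, evecs) {
  nvox <- nrow(evals)
  D <- matrix(0, nvox, 6L)
  for (v in seq_len(nvox)) {
    R <- evecs[, , v]
    Dm <- R %*% diag(evals[v, ]) %*% t(R)
    D[v, ] <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
  }
  D
}

#' Roughly uniform unit gradient directions
#'
#' Deterministic Fibonacci-sphere scheme mimicking an equally spaced
#' acquisition (the study protocol used 25 noncollinear directions).
#'
#' @param n number of directions (default 25).
#' @return (n x 3) matrix of unit vectors.
#' @export
gradient_scheme <- function(n = 25L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Inverts the monoexponential attenuation model: per voxel and unit
#' gradient `g`, `S = S0 * exp(-b * g' D g)`; the first output volume
#' is the unweighted `S0` channel. When `noise_sigma > 0`, Rician noise
#' is applied by adding two independent Gaussian channels of the stated
#' sigma (signal units) to the complex signal and taking the magnitude.
#'
#' @param field a `tensor_field` (all tensors must be positive
#'   semi-definite).
#' @param directions (ndir x 3) unit gradient directions.
#' @param bval b-value (s/mm^2), > 0.
#' @param s0 unweighted signal level, > 0.
#' @param noise_sigma Rician noise sigma in signal units.
#' @param seed optional seed for the noise realisation.
#' @return a [diffusion_volume()].
#' @export
synthesize_dwi <- function(field, directions, bval, s0 = 1000,
                           noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(field, "tensor_field"))
  directions <- as.matrix(directions)
  if (any(abs(sqrt(rowSums(directions^2)) - 1) > 1e-6))
    stop("gradient directions must be unit-norm")
  if (bval <= 0) stop("'bval' must be positive")
  if (s0 <= 0) stop("'s0' must be positive")
  if (any(field$evals[field$valid, ] < -1e-15))
    stop("tensor field contains non-positive-semi-definite tensors")
  # g' D g for all voxels x directions, from the 6 unique elements
  g <- directions
  Q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             2 * g[, 2] * g[, 3])               # ndir x 6
  adc <- field$D %*% t(Q)                        # nvox x ndir
  sig <- cbind(s0, s0 * exp(-bval * adc))
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(sig)
    sig <- sqrt((sig + rnorm(n, 0, noise_sigma))^2 +
                  rnorm(n, 0, noise_sigma)^2)
  }
  diffusion_volume(array(sig, dim = c(field$grid$dim, ncol(sig))),
                   bval, directions, field$grid)
}

#' Generate a synthetic control cohort plus one lesioned subject
#'
#' Produces `n_controls` noisy realisations of the same phantom and one
#' realisation with the lesion inserted, each simulated, fitted, and
#' returned as a `tensor_field`. This mirrors a study design comparing
#' a single stroke subject against 9 controls. Per-subject noise seeds
#' are derived deterministically from the master seed, so identical
#' seeds give bit-identical cohorts; with `noise_sigma = 0` all
#' controls are identical.
#'
#' @param spec a [phantom_spec()] (its `lesion` slot defines the
#'   lesioned subject; controls are generated without it).
#' @param n_controls number of control subjects, >= 2.
#' @param directions gradient scheme (default [gradient_scheme()]).
#' @param bval,s0 acquisition parameters.
#' @param seed master seed (default `spec$seed`).
#' @return list with `controls` (list of `tensor_field`), `stroke`
#'   (one `tensor_field`), and `lesion_mask`.
#' @export
generate_cohort <- function(spec, n_controls = 9L,
                            directions = gradient_scheme(25L),
                            bval = 1000, s0 = 1000, seed = spec$seed) {
  if (n_controls < 2L)
    stop("'n_controls' must be >= 2 (group test undefined otherwise)")
  spec_ctrl <- spec
  spec_ctrl$lesion <- NULL
  ph_ctrl <- generate_phantom(spec_ctrl)
  ph_les <- generate_phantom(spec)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_controls + 1L)
  controls <- vector("list", n_controls)
  for (i in seq_len(n_controls)) {
    dwi <- synthesize_dwi(ph_ctrl$field, directions, bval, s0,
                          noise_sigma = spec$noise_sigma,
                          seed = sub_seeds[i])
    controls[[i]] <- fit_tensor(dwi)
  }
  dwi_s <- synthesize_dwi(ph_les$field, directions, bval, s0,
                          noise_sigma = spec$noise_sigma,
                          seed = sub_seeds[n_controls + 1L])
  list(controls = controls, stroke = fit_tensor(dwi_s),
       lesion_mask = ph_les$lesion_mask)
}

#' Six-voxel worked-example fiber set
#'
#' Builds the canonical three-fiber, six-voxel configuration used to
#' illustrate the VISC definition: fibers penetrate voxel sets
#' \{A, B, C\}, \{D, B, E\} and \{C, F\} on a 3 x 3 x 1 grid. Voxels B
#' and C are then the direct neighbors of A; D, E and F are its
#' indirect neighbors (degrees F: 1, D: 2, E: 2), so the VISC of A is
#' 5/3. The exact fiber geometry is under-determined by the topology;
#' this is the minimal three-fiber realisation consistent with every
#' stated degree and neighbor relation.
#'
#' @return list with `fibers` (a `fiber_set`), `grid`, and `voxels`
#'   (named vector of linear voxel indices for letters A-F).
#' @export
#' @examples
#' fx <- make_worked_example()
#' gr <- build_connectivity(fx$fibers, fx$grid)
#' compute_visc(gr)$values[fx$voxels["A"]]  # 5/3
make_worked_example <- function() {
  grid <- voxel_grid(c(3L, 3L, 1L), vsize = 1)
  pt <- function(i, j) c(i - 1, j - 1, 0)   # center of voxel (i, j, 1)
  fib <- list(rbind(pt(1, 2), pt(2, 2), pt(2, 1)),   # A B C
              rbind(pt(1, 3), pt(2, 2), pt(3, 3)),   # D B E
              rbind(pt(2, 1), pt(3, 1)))             # C F
  letters6 <- c(A = lin_index(grid, c(1, 2, 1)),
                B = lin_index(grid, c(2, 2, 1)),
                C = lin_index(grid, c(2, 1, 1)),
                D = lin_index(grid, c(1, 3, 1)),
                E = lin_index(grid, c(3, 3, 1)),
                F = lin_index(grid, c(3, 1, 1)))
  fibers <- fiber_set(lapply(fib, function(p)
    streamline(p, termination = c("fixture", "fixture"))),
    space = "reference")
  list(fibers = fibers, grid = grid, voxels = letters6)
}

#' Tract phantom with anisotropy decaying toward the endpoints
#'
#' Builds a cylindrical tract along the x axis whose axial eigenvalue
#' is chosen per voxel so that the FA falls off linearly from
#' `fa_center` at the tract midpoint to `fa_edge` at both termini,
#' emulating a white-matter tract whose anisotropy decays as it
#' approaches cortex. Because the FA varies along the fiber paths,
#' streamline extent — and with it the penetrated volume and the VISC —
#' responds smoothly to the FA stopping threshold, which makes this the
#' reference geometry for threshold-sensitivity sweeps.
#'
#' @param n_x tract-axis grid length (voxels).
#' @param n_yz cross-sectional grid size (voxels).
#' @param radius tract radius (mm).
#' @param fa_center,fa_edge FA at the midpoint / at the termini.
#' @param lambda_perp radial eigenvalue (mm^2/s), held fixed.
#' @param background_adc isotropic background diffusivity.
#' @param vsize voxel size (mm).
#' @return list with `field` (a `tensor_field`), `grid`, `tract_mask`,
#'   and `roi_center` (logical array marking the central core voxels).
#' @export
make_tract_phantom <- function(n_x = 40L, n_yz = 9L, radius = 3,
                               fa_center = 0.8, fa_edge = 0.05,
                               lambda_perp = 3e-4,
                               background_adc = 7e-4, vsize = 1) {
  grid <- voxel_grid(c(n_x, n_yz, n_yz), vsize)
  nvox <- n_voxels(grid)
  ctr <- grid_centers(grid)
  mid <- c(mean(range(ctr[, 1])), mean(range(ctr[, 2])),
           mean(range(ctr[, 3])))
  r2 <- (ctr[, 2] - mid[2])^2 + (ctr[, 3] - mid[3])^2
  inside <- r2 <= radius^2
  half <- (n_x - 1) * vsize / 2
  fa_target <- fa_center + (fa_edge - fa_center) *
    abs(ctr[, 1] - mid[1]) / half
  evals <- matrix(background_adc, nvox, 3L)
  evecs <- array(diag(3), dim = c(3L, 3L, nvox))
  idx <- which(inside)
  l1 <- vapply(fa_target[idx], lambda1_for_fa, numeric(1),
               lambda_perp = lambda_perp)
  evals[idx, 1] <- l1
  evals[idx, 2:3] <- lambda_perp
  field <- structure(list(D = six_from_eigen(evals, evecs),
                          evals = evals, evecs = evecs,
                          valid = rep(TRUE, nvox),
                          neg_flag = rep(FALSE, nvox), grid = grid),
                     class = "tensor_field")
  core <- r2 <= (radius / 2)^2 & abs(ctr[, 1] - mid[1]) <= 2 * vsize
  list(field = field, grid = grid,
       tract_mask = array(inside, dim = grid$dim),
       roi_center = array(core, dim = grid$dim))
}

#' Insert an isotropic lesion into a tensor field
#'
#' Overwrites the voxels of a box or sphere region (voxel indices, see
#' [phantom_spec()]) with an isotropic tensor of the stated
#' diffusivity, emulating the elevated MD and lost anisotropy of a
#' chronic lesion.
#'
#' @param field a `tensor_field`.
#' @param lesion lesion descriptor list (`type`, and `lo`/`hi` or
#'   `center`/`radius`).
#' @param md lesion diffusivity (mm^2/s); default twice a typical
#'   background diffusivity.
#' @return list with `field` (modified copy) and `lesion_mask`.
#' @export
insert_lesion <- function(field, lesion, md = 1.4e-3) {
  stopifnot(inherits(field, "tensor_field"))
  mask <- lesion_voxels(list(lesion = lesion), field$grid)
  if (any(mask)) {
    idx <- which(mask)
    field$evals[idx, ] <- md
    field$evecs[, , idx] <- diag(3)
    field$D[idx, ] <- matrix(c(md, md, md, 0, 0, 0), length(idx), 6L,
                             byrow = TRUE)
  }
  list(field = field, lesion_mask = array(mask, dim = field$grid$dim))
}

# axial eigenvalue of a prolate tensor with given FA and fixed radial
# eigenvalue (monotone in lambda1 > lambda_perp)
lambda1_for_fa <- function(fa, lambda_perp = 3e-4) {
  if (fa <= 0) return(lambda_perp)
  f <- function(l1) fa_from_evals(cbind(l1, lambda_perp, lambda_perp)) - fa
  stats::uniroot(f, c(lambda_perp * (1 + 1e-9), lambda_perp * 1e3),
                 tol = 1e-15)$root
}
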