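#' Diffusion-weighted volume container
#'
#' Bundles a 4D signal array (grid x volumes) with its acquisition
#' geometry. The first volume is the unweighted (b0) channel; the
#' remaining volumes correspond row-wise to `directions`. If several
#' unweighted channels are supplied they are averaged into one.
#'
#' @param signals 4D numeric array, last dimension = number of volumes.
#' @param bval diffusion weighting b-value (s/mm^2), shared by all
#'   weighted volumes.
#' @param directions (ndir x 3) matrix of unit gradient directions for
#'   the weighted volumes (image coordinates, FSL bvec convention).
#' @param grid a [voxel_grid()] describing the spatial axes.
#' @return An object of class `diffusion_volume`.
#' @export
diffusion_volume <- function(signals, bval, directions, grid) {
  if (length(dim(signals)) != 4L) stop("'signals' must be a 4D array")
  if (!all(dim(signals)[1:3] == grid$dim))
    stop("signal grid does not match 'grid'")
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("'directions' must have 3 columns")
  if (dim(signals)[4] != nrow(directions) + 1L)
    stop("number of volumes (", dim(signals)[4], ") must equal ",
         "number of directions + 1 b0 (", nrow(directions) + 1L, ")")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("gradient directions must be unit-norm (within 1e-6)")
  if (any(signals < 0)) stop("signals must be non-negative")
  if (bval <= 0) stop("'bval' must be positive")
  structure(list(signals = signals, bval = as.numeric(bval),
                 directions = directions, grid = grid),
            class = "diffusion_volume")
}

#' @export
print.diffusion_volume <- function(x, ...) {
  cat("<diffusion_volume> ", paste(x$grid$dim, collapse = " x "),
      " voxels, b = ", x$bval, " s/mm^2, ",
      nrow(x$directions), " directions + 1 b0\n", sep = "")
  invisible(x)
}

#' Scalar map container
#'
#' A 3D map of a derived voxel-wise quantity (FA, MD, VISC, fiber
#' count, mean fiber length, ...) together with its grid and a validity
#' mask. Invalid voxels hold 0.
#'
#' @param values 3D numeric array matching `grid`.
#' @param metric name of the quantity.
#' @param grid a [voxel_grid()].
#' @param mask logical array of valid voxels (default: all valid).
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, metric, grid, mask = NULL) {
  values <- array(values, dim = grid$dim)
  if (is.null(mask)) mask <- array(TRUE, dim = grid$dim)
  mask <- array(as.logical(mask), dim = grid$dim)
  values[!mask] <- 0
  structure(list(values = values, metric = metric, grid = grid,
                 mask = mask), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat("<scalar_map> ", x$metric, ", ",
      paste(x$grid$dim, collapse = " x "), " voxels, ",
      sum(x$mask), " valid; range ",
      if (length(v)) paste(signif(range(v), 4), collapse = " .. ")
      else "-", "\n", sep = "")
  invisible(x)
}

map_values <- function(x) {
  if (inherits(x, "scalar_map")) x$values else x
}

#' Fit the diffusion tensor per voxel
#'
#' For each voxel an apparent diffusion coefficient is computed per
#' gradient direction as the log signal loss relative to the unweighted
#' channel, `ADC_k = -log(S_k / S0) / b`, and the six unique elements
#' of the symmetric second-order tensor are estimated by ordinary least
#' squares from `ADC_k = g_k' D g_k`. Each tensor is diagonalised into
#' eigenvalues (sorted `lambda1 >= lambda2 >= lambda3`) and orthonormal
#' eigenvectors. Voxels where `S0 <= 0` or any weighted signal is
#' non-positive cannot enter the log and are masked invalid rather than
#' raising an error. Negative fitted eigenvalues (possible under noise)
#' are retained for downstream FA/MD arithmetic but flagged.
#'
#' @param dwi a [diffusion_volume()]. At least 6 non-collinear
#'   directions are required.
#' @return An object of class `tensor_field` with elements `D`
#'   (nvox x 6 matrix: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `evals`
#'   (nvox x 3, descending), `evecs` (3 x 3 x nvox, columns are
#'   eigenvectors), `valid`, `neg_flag` and `grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(3, 3, 1))
#' D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
#' tf0 <- uniform_tensor_field(g, D)
#' dwi <- synthesize_dwi(tf0, gradient_scheme(25), bval = 1000)
#' tf <- fit_tensor(dwi)
#' max(abs(tf$evals[1, ] - c(1.7, 0.3, 0.3) * 1e-3))
fit_tensor <- function(dwi) {
  stopifnot(inherits(dwi, "diffusion_volume"))
  gdir <- dwi$directions
  ndir <- nrow(gdir)
  if (ndir < 6L) stop("tensor fit needs at least 6 directions")
  G <- cbind(gdir[, 1]^2, gdir[, 2]^2, gdir[, 3]^2,
             2 * gdir[, 1] * gdir[, 2],
             2 * gdir[, 1] * gdir[, 3],
             2 * gdir[, 2] * gdir[, 3])
  if (qr(G)$rank < 6L)
    stop("gradient scheme is rank-deficient for a tensor fit")
  grid <- dwi$grid
  nvox <- n_voxels(grid)
  sig <- matrix(dwi$signals, nrow = nvox)
  s0 <- sig[, 1]
  sw <- sig[, -1, drop = FALSE]
  valid <- s0 > 0 & rowSums(sw <= 0) == 0L
  D <- matrix(0, nvox, 6L)
  evals <- matrix(0, nvox, 3L)
  evecs <- array(0, dim = c(3L, 3L, nvox))
  neg_flag <- rep(FALSE, nvox)
  if (any(valid)) {
    adc <- -log(sw[valid, , drop = FALSE] / s0[valid]) / dwi$bval
    pinv <- solve(crossprod(G), t(G))       # 6 x ndir
    D[valid, ] <- adc %*% t(pinv)
    vidx <- which(valid)
    for (v in vidx) {
      Dm <- matrix(c(D[v, 1], D[v, 4], D[v, 5],
                     D[v, 4], D[v, 2], D[v, 6],
                     D[v, 5], D[v, 6], D[v, 3]), 3L, 3L)
      e <- eigen(Dm, symmetric = TRUE)
      evals[v, ] <- e$values
      evecs[, , v] <- e$vectors
    }
    neg_flag[vidx] <- evals[vidx, 3] < 0
  }
  structure(list(D = D, evals = evals, evecs = evecs, valid = valid,
                 neg_flag = neg_flag, grid = grid),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(x$grid$dim, collapse = " x "),
      " voxels, ", sum(x$valid), " valid",
      if (any(x$neg_flag)) paste0(", ", sum(x$neg_flag),
                                  " flagged (negative eigenvalue)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.tensor_field <- function(object, ...) {
  fa <- compute_fa(object)
  md <- compute_md(object)
  cat("tensor field on ", paste(object$grid$dim, collapse = " x "),
      " grid\n  valid voxels: ", sum(object$valid), "/",
      n_voxels(object$grid), "\n", sep = "")
  if (any(object$valid)) {
    cat("  FA: ", paste(signif(range(fa$values[object$valid]), 4),
                        collapse = " .. "),
        "\n  MD: ", paste(signif(range(md$values[object$valid]), 4),
                          collapse = " .. "), " mm^2/s\n", sep = "")
  }
  invisible(object)
}

#' Mean diffusivity map
#'
#' `MD = (lambda1 + lambda2 + lambda3) / 3` per valid voxel; invalid
#' voxels are 0 and excluded from the mask.
#'
#' @param field a `tensor_field`.
#' @return a [scalar_map()] named `"MD"`.
#' @export
compute_md <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  md <- rowMeans(field$evals)
  md[!field$valid] <- 0
  scalar_map(md, "MD", field$grid, mask = field$valid)
}

#' Fractional anisotropy map
#'
#' The standard normalized eigenvalue-dispersion form:
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`,
#' with `FA = 0` where the eigenvalue norm vanishes. FA is invariant to
#' uniform eigenvalue scaling and lies in \[0, 1\] for non-negative
#' eigenvalues.
#'
#' @param field a `tensor_field`.
#' @return a [scalar_map()] named `"FA"`.
#' @export
compute_fa <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  scalar_map(fa_from_evals(field$evals) * field$valid, "FA",
             field$grid, mask = field$valid)
}

# FA from an (n x 3) eigenvalue matrix
fa_from_evals <- function(ev) {
  ev <- matrix(ev, ncol = 3L)
  m <- rowMeans(ev)
  num <- rowSums((ev - m)^2)
  den <- rowSums(ev^2)
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[den == 0] <- 0
  fa
}

# constant-tensor field over a grid (phantom and test helper)
#' Uniform tensor field
#'
#' Builds a `tensor_field` with the same 3x3 symmetric tensor `D` at
#' every voxel; mostly useful for tests and simple phantoms.
#'
#' @param grid a [voxel_grid()].
#' @param D symmetric 3x3 diffusion tensor (mm^2/s).
#' @return a `tensor_field`.
#' @export
uniform_tensor_field <- function(grid, D) {
  D <- as.matrix(D)
  if (any(abs(D - t(D)) > 1e-12)) stop("'D' must be symmetric")
  nvox <- n_voxels(grid)
  e <- eigen(D, symmetric = TRUE)
  Dsix <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  structure(list(
    D = matrix(Dsix, nvox, 6L, byrow = TRUE),
    evals = matrix(e$values, nvox, 3L, byrow = TRUE),
    evecs = array(e$vectors, dim = c(3L, 3L, nvox)),
    valid = rep(TRUE, nvox),
    neg_flag = rep(FALSE, nvox),
    grid = grid), class = "tensor_field")
}
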