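#' Voxel grid geometry
#'
#' A `voxel_grid` ties a 3D array shape to physical millimetre
#' coordinates. A voxel is identified by the location of its center:
#' voxel `(i, j, k)` (1-based) has its center at
#' `origin + (c(i, j, k) - 1) * vsize` and owns the half-open box
#' `[center - vsize/2, center + vsize/2)` along each axis, so a point
#' lying exactly on a shared face belongs to the higher-index voxel.
#' This convention gives a total one-to-one mapping between voxel
#' indices and image space and is used by every module in the package.
#'
#' @param dim integer length-3 grid shape.
#' @param vsize voxel size in mm (scalar or length 3).
#' @param origin mm coordinate of the center of voxel (1,1,1).
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' g <- voxel_grid(c(10, 10, 5), vsize = 2)
#' coord_to_voxel(g, rbind(c(0, 0, 0), c(1, 0, 0)))  # face point rounds up
voxel_grid <- function(dim, vsize = c(1, 1, 1), origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L))
    stop("'dim' must be three integers >= 1")
  if (length(vsize) == 1L) vsize <- rep(vsize, 3L)
  if (any(vsize <= 0)) stop("voxel size must be positive")
  structure(list(dim = dim, vsize = as.numeric(vsize),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$dim, collapse = " x "),
      " voxels, ", paste(signif(x$vsize, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dim)

#' Convert between mm coordinates and voxel indices
#'
#' `coord_to_voxel` maps points (rows of a matrix, mm) to 1-based voxel
#' indices under the half-open boundary rule; `voxel_to_coord` returns
#' voxel-center coordinates. Points outside the grid yield `NA` rows.
#'
#' @param grid a [voxel_grid()].
#' @param pts numeric matrix (n x 3) of mm coordinates.
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @return integer (n x 3) matrix of indices, or numeric (n x 3) matrix
#'   of mm center coordinates.
#' @export
coord_to_voxel <- function(grid, pts) {
  pts <- as_points(pts)
  ijk <- matrix(NA_integer_, nrow(pts), 3L)
  for (d in 1:3) {
    ijk[, d] <- as.integer(floor((pts[, d] - grid$origin[d]) /
                                   grid$vsize[d] + 0.5)) + 1L
  }
  bad <- ijk < 1L | ijk > matrix(grid$dim, nrow(pts), 3L, byrow = TRUE)
  ijk[rowSums(bad) > 0L, ] <- NA_integer_
  ijk
}

#' @rdname coord_to_voxel
#' @export
voxel_to_coord <- function(grid, ijk) {
  ijk <- as_points(ijk)
  sweep(sweep(ijk - 1, 2L, grid$vsize, "*"), 2L, grid$origin, "+")
}

as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  if (ncol(pts) != 3L) stop("points must have 3 columns")
  storage.mode(pts) <- "double"
  pts
}

# linear index <-> (i,j,k), both 1-based, column-major like R arrays
lin_index <- function(grid, ijk) {
  ijk <- as_points(ijk)
  as.integer(ijk[, 1] + (ijk[, 2] - 1) * grid$dim[1] +
               (ijk[, 3] - 1) * grid$dim[1] * grid$dim[2])
}

ijk_index <- function(grid, lin) {
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% grid$dim[1]
  j <- (lin0 %/% grid$dim[1]) %% grid$dim[2]
  k <- lin0 %/% (grid$dim[1] * grid$dim[2])
  unname(cbind(i, j, k) + 1L)
}

# all voxel centers as an (nvox x 3) matrix, column-major voxel order
grid_centers <- function(grid) {
  ax <- lapply(1:3, function(d)
    grid$origin[d] + (seq_len(grid$dim[d]) - 1) * grid$vsize[d])
  cbind(rep(ax[[1]], times = grid$dim[2] * grid$dim[3]),
        rep(rep(ax[[2]], each = grid$dim[1]), times = grid$dim[3]),
        rep(ax[[3]], each = grid$dim[1] * grid$dim[2]))
}

#' Trilinear interpolation of a 3D volume
#'
#' Samples `vol` (an array matching `grid`) at arbitrary mm points.
#' Values are interpolated between the 8 surrounding voxel centers;
#' coordinates beyond the outermost centers are either clamped to the
#' boundary value (`rule = "clamp"`) or given `fill` (`rule = "fill"`).
#'
#' @param vol numeric 3D array with `dim(vol) == grid$dim`.
#' @param grid a [voxel_grid()].
#' @param pts (n x 3) mm coordinates.
#' @param rule out-of-domain handling, `"clamp"` or `"fill"`.
#' @param fill value used outside the domain when `rule = "fill"`.
#' @return numeric vector of length `nrow(pts)`.
#' @export
interp_trilinear <- function(vol, grid, pts, rule = c("clamp", "fill"),
                             fill = 0) {
  rule <- match.arg(rule)
  pts <- as_points(pts)
  n <- nrow(pts)
  # continuous 0-based voxel coordinates (centers at integers)
  u <- sweep(sweep(pts, 2L, grid$origin, "-"), 2L, grid$vsize, "/")
  out_dom <- rep(FALSE, n)
  for (d in 1:3) out_dom <- out_dom | u[, d] < 0 | u[, d] > grid$dim[d] - 1
  uc <- pmin(pmax(u, 0), matrix(grid$dim - 1, n, 3L, byrow = TRUE))
  i0 <- pmin(floor(uc), matrix(grid$dim - 2L, n, 3L, byrow = TRUE))
  i0[, grid$dim == 1L] <- 0  # degenerate axis
  f <- uc - i0
  f[, grid$dim == 1L] <- 0
  val <- numeric(n)
  dims <- grid$dim
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) f[, 1] else 1 - f[, 1]) *
         (if (cy) f[, 2] else 1 - f[, 2]) *
         (if (cz) f[, 3] else 1 - f[, 3])
    ii <- pmin(i0[, 1] + cx, dims[1] - 1L)
    jj <- pmin(i0[, 2] + cy, dims[2] - 1L)
    kk <- pmin(i0[, 3] + cz, dims[3] - 1L)
    lin <- 1L + ii + jj * dims[1] + kk * dims[1] * dims[2]
    val <- val + w * vol[lin]
  }
  if (rule == "fill") val[out_dom] <- fill
  val
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Convolves each axis with a 1D Gaussian kernel of the stated full
#' width at half maximum (mm). Edges are handled by renormalising the
#' kernel over the in-volume support, so constant volumes are preserved
#' exactly.
#'
#' @param vol 3D array.
#' @param grid a [voxel_grid()] giving voxel sizes.
#' @param fwhm_mm full width at half maximum in mm (scalar).
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(vol, grid, fwhm_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- vol
  for (d in 1:3) {
    n <- grid$dim[d]
    if (n == 1L) next
    s <- sigma_mm / grid$vsize[d]          # sigma in voxels
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half:half)^2) / (2 * s^2))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- i + (-half:half)
      ok <- idx >= 1L & idx <= n
      K[i, idx[ok]] <- k[ok] / sum(k[ok])  # renormalised at edges
    }
    out <- apply_along(out, d, function(m) K %*% m)
  }
  out
}

# apply a matrix operator f (acting on axis-d fibres stacked as columns
# of a matrix) along axis d of a 3D array
apply_along <- function(arr, d, f) {
  dm <- dim(arr)
  perm <- c(d, setdiff(1:3, d))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dm[d])
  m <- f(m)
  a <- array(m, dim = dm[perm])
  aperm(a, order(perm))
}
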