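#' Voxels penetrated by a streamline
#'
#' Returns the ordered set of unique voxel linear indices containing at
#' least one streamline point, under the half-open voxel boundary rule
#' (a point exactly on a shared face belongs to the higher-index
#' voxel). Points outside the grid are skipped and counted in the
#' `"n_outside"` attribute.
#'
#' @param s a [streamline()] or an (n x 3) point matrix (mm, grid
#'   frame).
#' @param grid a [voxel_grid()].
#' @return integer vector of linear voxel indices, in order of first
#'   penetration.
#' @export
voxels_penetrated <- function(s, grid) {
  pts <- if (inherits(s, "streamline")) s$points else as_points(s)
  ijk <- coord_to_voxel(grid, pts)
  inside <- !is.na(ijk[, 1])
  lin <- lin_index(grid, ijk[inside, , drop = FALSE])
  out <- unique(lin)
  attr(out, "n_outside") <- sum(!inside)
  out
}

#' Build the voxel-wise connectivity graph of a fiber set
#'
#' The direct matrix `X` is binary, symmetric, with zero diagonal:
#' `x_ij = 1` iff voxels i and j are both penetrated by at least one
#' common fiber. Each fiber therefore contributes a clique over its
#' penetrated voxel set (its per-fiber matrix), and `X` is the union of
#' these cliques — so `X` is idempotent under fiber duplication and
#' invariant to fiber order. A `"chain"` mode is provided for
#' sensitivity analysis, connecting only consecutively penetrated
#' voxels along each fiber. The indirect matrix `Y` marks voxel pairs
#' that share a directly connected voxel but are not directly connected
#' themselves: `y_ij = 1` iff `i != j`, `(X X)_ij > 0` and `x_ij = 0`.
#' Both matrices are stored sparsely over the full grid dimension; a
#' dense N x N matrix is never materialised.
#'
#' @param fibers a [fiber_set()] (points in the grid frame).
#' @param grid a [voxel_grid()].
#' @param mode `"clique"` (the definitional reading) or `"chain"`.
#' @return An object of class `connectivity_graph` with sparse logical
#'   matrices `X` and `Y`, the grid, and the per-fiber penetrated voxel
#'   sets.
#' @export
#' @examples
#' fx <- make_worked_example()
#' g <- build_connectivity(fx$fibers, fx$grid)
#' Matrix::rowSums(g$X)[fx$voxels]  # voxel degrees
build_connectivity <- function(fibers, grid,
                               mode = c("clique", "chain")) {
  mode <- match.arg(mode)
  X <- build_direct(fibers, grid, mode)
  voxel_sets <- attr(X, "voxel_sets")
  attr(X, "voxel_sets") <- NULL
  structure(list(X = X, Y = build_indirect(X), grid = grid,
                 voxel_sets = voxel_sets, mode = mode),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat("<connectivity_graph> ", nrow(x$X), " voxels; ",
      Matrix::nnzero(x$X) / 2, " direct and ",
      Matrix::nnzero(x$Y) / 2, " indirect pairs (",
      x$mode, " mode)\n", sep = "")
  invisible(x)
}

#' Direct connectivity matrix
#'
#' Lower-level entry point of [build_connectivity()]; see there for the
#' definition.
#'
#' @inheritParams build_connectivity
#' @return sparse symmetric logical matrix (`Matrix::lsparseMatrix`)
#'   with attribute `"voxel_sets"` (per-fiber penetrated voxels).
#' @export
build_direct <- function(fibers, grid, mode = c("clique", "chain")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fibers, "fiber_set"))
  nvox <- n_voxels(grid)
  voxel_sets <- lapply(fibers$streamlines, voxels_penetrated, grid = grid)
  ii <- integer(0); jj <- integer(0)
  for (v in voxel_sets) {
    v <- as.integer(v)
    n <- length(v)
    if (n < 2L) next
    if (mode == "clique") {
      prs <- combn(sort(v), 2L)
      ii <- c(ii, prs[1L, ]); jj <- c(jj, prs[2L, ])
    } else {
      ii <- c(ii, v[-n]); jj <- c(jj, v[-1L])
    }
  }
  keep <- ii != jj
  X <- Matrix::sparseMatrix(i = c(ii[keep], jj[keep]),
                            j = c(jj[keep], ii[keep]),
                            dims = c(nvox, nvox))   # pattern, dups collapse
  X <- methods::as(X, "lMatrix")
  Matrix::diag(X) <- FALSE
  X <- Matrix::drop0(X)
  attr(X, "voxel_sets") <- voxel_sets
  X
}

#' Indirect connectivity matrix
#'
#' `y_ij = 1` iff `i != j`, i and j have a common direct neighbor
#' (`(X X)_ij > 0`) and are not directly connected (`x_ij = 0`).
#' Computed in sparse boolean arithmetic.
#'
#' @param X sparse symmetric logical direct matrix.
#' @return sparse symmetric logical matrix `Y` with zero diagonal and
#'   `X & Y` empty.
#' @export
build_indirect <- function(X) {
  Xn <- X * 1                            # numeric sparse copy
  B <- Xn %*% Xn                         # (X X)_ij = common neighbors
  B@x <- as.numeric(B@x > 0)             # boolean indicator, still sparse
  Y <- Matrix::drop0(B - B * Xn)         # knock out direct pairs
  Matrix::diag(Y) <- 0
  methods::as(Matrix::drop0(Y) > 0, "lMatrix")
}

#' Voxel-wise indirect structural connectivity (VISC)
#'
#' For voxel i with indirect-neighbor indicator row `y_(i)` and direct
#' matrix `X`, the index is the total number of direct connections of
#' its indirect neighbors divided by the number of indirect neighbors
#' raised to the contrast exponent `alpha`:
#' \deqn{VISC_\alpha(i) = \frac{y_{(i)} X 1}{(y_{(i)} 1)^\alpha}}
#' With `alpha = 1` this is the mean direct-connection count over the
#' indirect neighborhood; with `alpha = 0` the denominator is 1 and the
#' index equals the raw numerator (total connections). Voxels with no
#' indirect neighbors get 0 by convention (matching the
#' "nonzero-VISC" filtering used downstream).
#'
#' @param graph a [build_connectivity()] result, or a sparse direct
#'   matrix `X` (in which case `Y` is derived).
#' @param alpha contrast exponent in \[0, 1\].
#' @return a [scalar_map()] named `"VISC"` when a graph with a grid is
#'   supplied, otherwise a numeric vector.
#' @export
compute_visc <- function(graph, alpha = 1) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (inherits(graph, "connectivity_graph")) {
    v <- visc_index(graph$X, graph$Y, alpha)
    scalar_map(v, "VISC", graph$grid)
  } else {
    X <- graph
    visc_index(X, build_indirect(X), alpha)
  }
}

#' @rdname compute_visc
#' @param X,Y sparse direct and indirect matrices.
#' @export
visc_index <- function(X, Y, alpha = 1) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  deg <- Matrix::rowSums(X)              # direct connections per voxel
  num <- as.numeric(Y %*% deg)           # y_(i) X 1
  den <- Matrix::rowSums(Y)              # y_(i) 1
  out <- numeric(length(den))
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]^alpha
  out
}

#' Fiber count and mean fiber length maps
#'
#' Per voxel, `fiber_count_map` counts the fibers penetrating it and
#' `mean_fiber_length_map` averages the physical lengths of those
#' fibers (0 where no fiber penetrates).
#'
#' @param fibers a [fiber_set()].
#' @param grid a [voxel_grid()].
#' @return a [scalar_map()].
#' @export
fiber_count_map <- function(fibers, grid) {
  nvox <- n_voxels(grid)
  cnt <- numeric(nvox)
  for (s in fibers$streamlines) {
    v <- voxels_penetrated(s, grid)
    cnt[v] <- cnt[v] + 1
  }
  scalar_map(cnt, "fiber_count", grid)
}

#' @rdname fiber_count_map
#' @export
mean_fiber_length_map <- function(fibers, grid) {
  nvox <- n_voxels(grid)
  cnt <- numeric(nvox)
  tot <- numeric(nvox)
  for (s in fibers$streamlines) {
    v <- voxels_penetrated(s, grid)
    cnt[v] <- cnt[v] + 1
    tot[v] <- tot[v] + s$length
  }
  m <- numeric(nvox)
  m[cnt > 0] <- tot[cnt > 0] / cnt[cnt > 0]
  scalar_map(m, "mean_fiber_length", grid)
}
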