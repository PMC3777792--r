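# shared builders for synthetic tensor fields used across test files

# tensor field with an arbitrary per-voxel eigen system
field_from_eigen <- function(grid, evals, evecs) {
  structure(list(D = viscdti:::six_from_eigen(evals, evecs),
                 evals = evals, evecs = evecs,
                 valid = rep(TRUE, nrow(evals)),
                 neg_flag = rep(FALSE, nrow(evals)), grid = grid),
            class = "tensor_field")
}

# slab with principal direction flipping 90 degrees at x = x_split
interface_field <- function(dim = c(20, 20, 3), x_split = 10,
                            lambdas = c(1.7e-3, 3e-4, 3e-4)) {
  grid <- voxel_grid(dim)
  nvox <- prod(dim)
  evals <- matrix(lambdas, nvox, 3L, byrow = TRUE)
  evecs <- array(0, dim = c(3L, 3L, nvox))
  ctr <- viscdti:::grid_centers(grid)
  for (v in seq_len(nvox)) {
    e1 <- if (ctr[v, 1] < x_split) c(1, 0, 0) else c(0, 1, 0)
    evecs[, , v] <- viscdti:::orthonormal_frame(e1)
  }
  field_from_eigen(grid, evals, evecs)
}

# straight-bundle slab phantom (constant FA inside the bundle)
slab_phantom <- function(nx = 20, nyz = 8, radius = 2.2) {
  spec <- phantom_spec(c(nx, nyz, nyz), bundles = list(
    bundle_spec(rbind(c(-2, (nyz - 1) / 2, (nyz - 1) / 2),
                      c(nx + 2, (nyz - 1) / 2, (nyz - 1) / 2)),
                radius = radius)))
  generate_phantom(spec)
}

# a streamline of an exact physical length along x
straight_streamline <- function(len, y = 0, z = 0, step = 0.5) {
  n <- max(2L, as.integer(round(len / step)) + 1L)
  x <- seq(0, len, length.out = n)
  streamline(cbind(x, y, z))
}

# brute-force VISC oracle: per-node mean degree over 2-hop-but-not-
# 1-hop neighbours, enumerated independently of the matrix algebra
visc_bruteforce <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    direct <- which(A[i, ] > 0)
    two_hop <- integer(0)
    for (k in direct) two_hop <- union(two_hop, which(A[k, ] > 0))
    indirect <- setdiff(two_hop, c(i, direct))
    out[i] <- if (length(indirect)) sum(deg[indirect]) / length(indirect)
      else 0
  }
  out
}

# random sparse symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- stats::rbinom(sum(up), 1L, p)
  A + t(A)
}
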