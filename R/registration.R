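#' Displacement field container
#'
#' A per-voxel 3D displacement in mm on a fixed-space grid: the field
#' maps the center of each fixed-grid voxel to a physical location in
#' the moving (subject) space, `y = x + u(x)`. Diagnostics accumulated
#' by the producing operation (iteration logs, inverse-composition
#' residuals) ride along as extra elements.
#'
#' @param u 4D numeric array, `dim = c(grid$dim, 3)`, mm.
#' @param grid the fixed-space [voxel_grid()].
#' @param ... further diagnostic elements.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(u, grid, ...) {
  u <- array(u, dim = c(grid$dim, 3L))
  if (any(!is.finite(u))) stop("displacement field must be finite")
  structure(list(u = u, grid = grid, ...), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat("<displacement_field> ", paste(x$grid$dim, collapse = " x "),
      " voxels; |u| mean ", signif(mean(mag), 4), " mm, max ",
      signif(max(mag), 4), " mm\n", sep = "")
  if (!is.null(x$residual_mean))
    cat("  inverse-composition residual ",
        signif(x$residual_mean, 4), " +/- ",
        signif(x$residual_sd, 4), " mm\n", sep = "")
  invisible(x)
}

#' Nine-parameter affine registration
#'
#' Optimises 3 translations (mm), 3 rotations (radians) and 3
#' anisotropic scales minimising the mean squared intensity difference
#' between the fixed image and the resampled moving image, by gradient
#' descent (numeric gradient, backtracking step control) over a
#' coarse-to-fine resolution schedule. The transform maps fixed-space
#' coordinates to moving-space coordinates about the volume center:
#' `y = R(rot) diag(scale) (x - c) + c + trans`. Deterministic given a
#' fixed initialisation; if the iteration cap is hit without
#' convergence the best parameters so far are returned with
#' `converged = FALSE`.
#'
#' @param fixed,moving 3D arrays on `grid`.
#' @param grid a [voxel_grid()].
#' @param init optional initial `affine_params`.
#' @param resolutions coarse-to-fine working resolutions (mm).
#' @param max_iter gradient-descent iterations per resolution.
#' @return An object of class `affine_params`: list with `translation`,
#'   `rotation`, `scale`, `cost`, `converged`.
#' @export
affine_register <- function(fixed, moving, grid, init = NULL,
                            resolutions = c(4, 2, 1), max_iter = 100L) {
  fixed <- map_values(fixed); moving <- map_values(moving)
  par <- if (is.null(init)) c(rep(0, 6), rep(1, 3))
         else c(init$translation, init$rotation, init$scale)
  converged <- FALSE
  for (res in sort(resolutions, decreasing = TRUE)) {
    f <- max(1L, round(res / min(grid$vsize)))
    dsf <- downsample_image(fixed, grid, f)
    dsm <- downsample_image(moving, grid, f)
    opt <- descend_affine(par, dsf$img, dsm$img, dsf$grid, max_iter)
    par <- opt$par
    converged <- opt$converged
  }
  if (!converged)
    warning("affine registration did not converge; returning best so far")
  structure(list(translation = par[1:3], rotation = par[4:6],
                 scale = par[7:9], cost = affine_cost(par, fixed, moving, grid),
                 converged = converged),
            class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat("<affine_params> t = (", paste(signif(x$translation, 4),
                                     collapse = ", "),
      ") mm; r = (", paste(signif(x$rotation, 4), collapse = ", "),
      ") rad; s = (", paste(signif(x$scale, 4), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

rotation_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

# map fixed-space points (n x 3 mm) into moving space
affine_map <- function(par, pts, center) {
  R <- rotation_matrix(par[4:6])
  S <- diag(pmax(par[7:9], 1e-3))
  sweep(sweep(pts, 2L, center, "-") %*% t(R %*% S), 2L,
        center + par[1:3], "+")
}

affine_cost <- function(par, fixed, moving, grid) {
  ctr <- grid_centers(grid)
  c0 <- colMeans(ctr)
  y <- affine_map(par, ctr, c0)
  mw <- interp_trilinear(moving, grid, y, rule = "clamp")
  mean((as.numeric(fixed) - mw)^2)
}

descend_affine <- function(par, fixed, moving, grid, max_iter) {
  sc <- c(rep(mean(grid$vsize), 3), rep(0.02, 3), rep(0.02, 3))
  cost <- affine_cost(par, fixed, moving, grid)
  lr <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- vapply(seq_along(par), function(k) {
      h <- sc[k] * 1e-2
      pp <- par; pp[k] <- pp[k] + h
      pm <- par; pm[k] <- pm[k] - h
      (affine_cost(pp, fixed, moving, grid) -
         affine_cost(pm, fixed, moving, grid)) / (2 * h)
    }, numeric(1))
    step <- g * sc^2
    gn <- sqrt(sum((g * sc)^2))
    if (gn < 1e-12) { converged <- TRUE; break }
    improved <- FALSE
    while (lr > 1e-10) {
      cand <- par - lr * step
      cnew <- affine_cost(cand, fixed, moving, grid)
      if (cnew < cost - 1e-15) {
        par <- cand; cost <- cnew; improved <- TRUE
        lr <- lr * 1.5
        break
      }
      lr <- lr / 2
    }
    if (!improved) { converged <- TRUE; break }
  }
  list(par = par, cost = cost, converged = converged)
}

# integer-factor block-mean downsampling
downsample_image <- function(img, grid, f) {
  if (f <= 1L) return(list(img = img, grid = grid))
  dm <- dim(img)
  nd <- pmax(dm %/% f, 1L)
  out <- array(0, dim = nd)
  cnt <- array(0, dim = nd)
  idx <- lapply(1:3, function(d) pmin((seq_len(dm[d]) - 1L) %/% f + 1L, nd[d]))
  for (k in seq_len(dm[3])) {
    sl <- img[, , k]
    acc <- rowsum(sl, idx[[1]], reorder = TRUE)
    acc <- t(rowsum(t(acc), idx[[2]], reorder = TRUE))
    out[, , idx[[3]][k]] <- out[, , idx[[3]][k]] + acc
    cnt[, , idx[[3]][k]] <- cnt[, , idx[[3]][k]] +
      outer(tabulate(idx[[1]], nd[1]), tabulate(idx[[2]], nd[2]))
  }
  list(img = out / cnt,
       grid = voxel_grid(nd, grid$vsize * f,
                         grid$origin + (f - 1) / 2 * grid$vsize))
}

#' Histogram matching
#'
#' Monotone intensity remap so that source quantiles match reference
#' quantiles. The source cumulative distribution is evaluated on a
#' fixed number of bins and mapped through the inverse empirical
#' distribution of the reference, so matched output takes values
#' actually present in the reference.
#'
#' @param source,reference numeric arrays (any shape, nonempty).
#' @param nbins number of source histogram bins (default 256).
#' @return array shaped like `source` with remapped intensities. A
#'   constant source is returned unchanged with a warning.
#' @export
histogram_match <- function(source, reference, nbins = 256L) {
  source <- map_values(source); reference <- map_values(reference)
  if (!length(source) || !length(reference))
    stop("source and reference must be nonempty")
  rng <- range(source)
  if (diff(rng) == 0) {
    warning("constant source image; returned unchanged")
    return(source)
  }
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(source, br, rightmost.closed = TRUE), 1L),
              nbins)
  cdf <- cumsum(tabulate(bin, nbins)) / length(source)
  p <- cdf[bin]
  out <- quantile(reference, probs = p, type = 1L, names = FALSE)
  array(out, dim = if (is.null(dim(source))) length(source)
        else dim(source))
}

# central-difference spatial gradient, mm units; list of 3 arrays
image_gradient <- function(img, grid) {
  lapply(1:3, function(d) {
    n <- dim(img)[d]
    if (n == 1L) return(array(0, dim = dim(img)))
    apply_along(img, d, function(m) {
      gm <- m
      gm[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * grid$vsize[d])
      gm[1, ] <- (m[2, ] - m[1, ]) / grid$vsize[d]
      gm[n, ] <- (m[n, ] - m[n - 1, ]) / grid$vsize[d]
      gm
    })
  })
}

#' Demons deformable registration with lesion masking
#'
#' Iterative intensity-driven registration producing a dense
#' displacement field from fixed to moving space. Each iteration
#' applies the classic fixed-image-gradient demons force with the
#' standard stabilised denominator,
#' `du = (f - m(x+u)) grad(f) / (|grad(f)|^2 + (f - m(x+u))^2)`,
#' followed by a regularising Gaussian smoothing of the field. Voxels
#' whose current mapping lands inside the lesion mask (defined in
#' moving space) are frozen: their displacement is not updated, and the
#' smoothing is mask-aware (normalised convolution over free voxels
#' only), so displacements are never mixed across the frozen/free
#' boundary. This lets tissue surrounding a lesion register while the
#' lesion content itself is preserved. Voxels on a zero-gradient
#' plateau are skipped for that iteration.
#'
#' @param fixed,moving 3D arrays on `grid`, pre-aligned by an affine.
#' @param grid a [voxel_grid()].
#' @param lesion_mask optional logical/0-1 array in moving space.
#' @param iterations number of demons iterations.
#' @param smooth_fwhm_mm regularisation kernel FWHM (mm).
#' @param init optional initial [displacement_field()].
#' @return a [displacement_field()] with an `mse_trace` diagnostic.
#' @export
demons_register <- function(fixed, moving, grid, lesion_mask = NULL,
                            iterations = 50L, smooth_fwhm_mm = 2,
                            init = NULL) {
  fixed <- map_values(fixed); moving <- map_values(moving)
  u <- if (is.null(init)) array(0, dim = c(grid$dim, 3L)) else init$u
  ctr <- grid_centers(grid)
  grf <- image_gradient(fixed, grid)
  g1 <- as.numeric(grf[[1]]); g2 <- as.numeric(grf[[2]])
  g3 <- as.numeric(grf[[3]])
  gn2 <- g1^2 + g2^2 + g3^2
  fvec <- as.numeric(fixed)
  nvox <- n_voxels(grid)
  mse_trace <- numeric(iterations)
  lmask <- if (is.null(lesion_mask)) NULL else
    array(as.numeric(as.logical(lesion_mask)), dim = grid$dim)
  for (it in seq_len(iterations)) {
    uv <- matrix(u, nvox, 3L)
    y <- ctr + uv
    mw <- interp_trilinear(moving, grid, y, rule = "clamp")
    diffv <- mw - fvec
    mse_trace[it] <- mean(diffv^2)
    frozen <- if (is.null(lmask)) rep(FALSE, nvox) else
      interp_trilinear(lmask, grid, y, rule = "fill") > 0.5
    den <- gn2 + diffv^2
    ok <- den > 1e-12 & !frozen
    upd <- matrix(0, nvox, 3L)
    upd[ok, 1] <- -diffv[ok] * g1[ok] / den[ok]
    upd[ok, 2] <- -diffv[ok] * g2[ok] / den[ok]
    upd[ok, 3] <- -diffv[ok] * g3[ok] / den[ok]
    uv <- uv + upd
    # edge-preserving (mask-aware) smoothing over free voxels
    w <- array(as.numeric(!frozen), dim = grid$dim)
    ws <- gaussian_smooth(w, grid, smooth_fwhm_mm)
    free <- !frozen & as.numeric(ws) > 1e-12
    for (d in 1:3) {
      comp <- array(uv[, d] * !frozen, dim = grid$dim)
      sm <- gaussian_smooth(comp, grid, smooth_fwhm_mm) / pmax(ws, 1e-12)
      uv[free, d] <- as.numeric(sm)[free]
    }
    u <- array(uv, dim = c(grid$dim, 3L))
  }
  displacement_field(u, grid, mse_trace = mse_trace,
                     n_frozen_last = sum(frozen))
}

#' Approximate inverse of a displacement field
#'
#' Iterative scatter-and-smooth scheme: a candidate inverse field is
#' initialised to zero; at each iteration, for every fixed-grid point
#' `x` the forward map `y = x + u(x)` is evaluated, the inverse at the
#' grid node nearest `y` is forced to point back (`v = x - y`,
#' collisions averaged), and the field is smoothed with a Gaussian of
#' the stated FWHM. Defaults: 10 iterations, 2 mm FWHM. The returned
#' field carries a per-voxel composition-residual magnitude map
#' `|y + v(y) - x|`, its mean and standard deviation, and the
#' per-iteration residual trace.
#'
#' @param field a [displacement_field()] (forward, fixed -> moving).
#' @param iterations number of adjust/smooth passes.
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @return a [displacement_field()] for the approximate inverse with
#'   diagnostics `residual_map`, `residual_mean`, `residual_sd`,
#'   `residual_trace`, `n_outside`.
#' @export
approximate_inverse <- function(field, iterations = 10L, fwhm_mm = 2) {
  stopifnot(inherits(field, "displacement_field"))
  grid <- field$grid
  nvox <- n_voxels(grid)
  ctr <- grid_centers(grid)
  uv <- matrix(field$u, nvox, 3L)
  y <- ctr + uv
  # nearest grid node to each forward-mapped point (clamped, counted)
  node <- matrix(0L, nvox, 3L)
  outside <- rep(FALSE, nvox)
  for (d in 1:3) {
    raw <- round((y[, d] - grid$origin[d]) / grid$vsize[d]) + 1
    outside <- outside | raw < 1 | raw > grid$dim[d]
    node[, d] <- pmin(pmax(as.integer(raw), 1L), grid$dim[d])
  }
  nlin <- lin_index(grid, node)
  neg <- ctr - y                        # forced inverse value
  v <- matrix(0, nvox, 3L)
  residual_trace <- numeric(iterations)
  res <- NULL
  for (it in seq_len(iterations)) {
    hits <- tabulate(nlin, nvox)
    for (d in 1:3) {
      acc <- rowsum(neg[, d], nlin)
      idx <- as.integer(rownames(acc))
      vd <- v[, d]
      vd[idx] <- acc[, 1] / hits[idx]   # collisions averaged
      v[, d] <- as.numeric(gaussian_smooth(array(vd, grid$dim),
                                           grid, fwhm_mm))
    }
    v_at_y <- vapply(1:3, function(d)
      interp_trilinear(array(v[, d], grid$dim), grid, y, rule = "clamp"),
      numeric(nvox))
    res <- sqrt(rowSums((y + v_at_y - ctr)^2))
    residual_trace[it] <- mean(res)
  }
  displacement_field(array(v, dim = c(grid$dim, 3L)), grid,
                     residual_map = array(res, dim = grid$dim),
                     residual_mean = mean(res), residual_sd = sd(res),
                     residual_trace = residual_trace,
                     n_outside = sum(outside))
}
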