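#' Tractography parameters
#'
#' Deterministic streamline tracking settings. Defaults follow the
#' standard FACT-style protocol for single-tensor data: 0.1 mm
#' integration step, 60 degree maximum curvature, FA stopping threshold
#' 0.15 (letting fibers run into gray matter), seeding on a uniform
#' 1 mm lattice wherever FA exceeds 0.3 (strictly), and exclusion of
#' fibers shorter than 10 mm or longer than 140 mm (boundaries kept,
#' since only strictly shorter/longer fibers are excluded).
#'
#' @param step integration step (mm), > 0.
#' @param max_angle maximum curvature angle (degrees), evaluated over a
#'   one-voxel look-back so that the criterion acts at the voxel scale
#'   rather than per 0.1 mm sub-step.
#' @param fa_stop FA stopping threshold, in (0, 1).
#' @param fa_seed seeding FA threshold (strictly above), in (0, 1).
#' @param seed_spacing seed lattice spacing (mm).
#' @param min_length,max_length fiber length filter bounds (mm),
#'   inclusive.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(step = 0.1, max_angle = 60, fa_stop = 0.15,
                            fa_seed = 0.3, seed_spacing = 1,
                            min_length = 10, max_length = 140) {
  if (step <= 0) stop("'step' must be positive")
  if (fa_stop <= 0 || fa_stop >= 1 || fa_seed <= 0 || fa_seed >= 1)
    stop("FA thresholds must lie strictly between 0 and 1")
  if (min_length >= max_length)
    stop("'min_length' must be less than 'max_length'")
  structure(list(step = step, max_angle = max_angle, fa_stop = fa_stop,
                 fa_seed = fa_seed, seed_spacing = seed_spacing,
                 min_length = min_length, max_length = max_length),
            class = "tracking_params")
}

#' Streamline container
#'
#' An ordered 3D polyline in mm, with its arc length and the
#' termination reason of each propagation direction (`"low-FA"`,
#' `"angle"`, `"out-of-bounds"`, `"max-length"`).
#'
#' @param points (n x 3) matrix of mm coordinates.
#' @param seed_index index of the seed that produced the streamline.
#' @param termination character length 2 (forward, backward reasons).
#' @return An object of class `streamline`.
#' @export
streamline <- function(points, seed_index = NA_integer_,
                       termination = c(NA_character_, NA_character_)) {
  points <- as_points(points)
  structure(list(points = points, length = polyline_length(points),
                 seed_index = seed_index, termination = termination),
            class = "streamline")
}

polyline_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' @export
print.streamline <- function(x, ...) {
  cat("<streamline> ", nrow(x$points), " points, ",
      signif(x$length, 4), " mm (",
      paste(x$termination, collapse = " / "), ")\n", sep = "")
  invisible(x)
}

#' Fiber set container
#'
#' A list of [streamline()] objects with a source-space tag
#' (`"subject"` or `"reference"`) and tracking provenance.
#'
#' @param streamlines list of `streamline` objects.
#' @param space source space tag.
#' @param params the [tracking_params()] used (optional).
#' @return An object of class `fiber_set`.
#' @export
fiber_set <- function(streamlines, space = "subject", params = NULL) {
  stopifnot(all(vapply(streamlines, inherits, TRUE, "streamline")))
  structure(list(streamlines = streamlines, space = space,
                 params = params),
            class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  lens <- fiber_lengths(x)
  cat("<fiber_set> ", length(x$streamlines), " fibers (",
      x$space, " space)", sep = "")
  if (length(lens))
    cat(", length ", paste(signif(range(lens), 4), collapse = " .. "),
        " mm", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.fiber_set <- function(x) length(x$streamlines)

#' Fiber lengths
#' @param fibers a `fiber_set`.
#' @return numeric vector of physical lengths (mm).
#' @export
fiber_lengths <- function(fibers) {
  vapply(fibers$streamlines, function(s) s$length, numeric(1))
}

#' Generate tractography seed points
#'
#' Places a regular lattice with the stated spacing over the volume,
#' anchored at the center of the first voxel, and keeps a point iff the
#' trilinearly interpolated FA at it strictly exceeds the seeding
#' threshold.
#'
#' @param fa_map FA [scalar_map()].
#' @param params a [tracking_params()].
#' @return (n x 3) matrix of seed coordinates (mm); may have zero rows
#'   (with a warning).
#' @export
generate_seeds <- function(fa_map, params = tracking_params()) {
  stopifnot(inherits(fa_map, "scalar_map"))
  grid <- fa_map$grid
  ax <- lapply(1:3, function(d) {
    extent <- (grid$dim[d] - 1) * grid$vsize[d]
    grid$origin[d] + seq(0, extent, by = params$seed_spacing)
  })
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  dimnames(pts) <- NULL
  fa <- interp_trilinear(fa_map$values, grid, pts, rule = "fill")
  keep <- fa > params$fa_seed          # strictly above
  if (!any(keep)) warning("no seeds: FA nowhere above the threshold")
  pts[keep, , drop = FALSE]
}

# principal-eigenvector components as nvox x 3 matrix
e1_matrix <- function(field) {
  t(field$evecs[, 1, ])
}

#' Track a single streamline
#'
#' Integrates the FA-weighted principal-eigenvector direction field
#' bidirectionally from the seed with a 4th-order Runge-Kutta scheme.
#' The field is interpolated trilinearly with per-corner sign alignment
#' to the current heading (eigenvectors carry an arbitrary sign).
#' Propagation in each direction stops when the local FA falls below
#' the stopping threshold, when the heading turns by more than the
#' maximum angle over a one-voxel look-back, at the volume boundary, or
#' at the length budget (each half-track is capped at `max_length / 2`
#' so a completed fiber respects the total maximum length); the two
#' half-tracks are then concatenated.
#'
#' @param seed length-3 mm coordinate inside the volume.
#' @param field a `tensor_field`.
#' @param fa_map FA [scalar_map()] (computed from `field` if missing).
#' @param params a [tracking_params()].
#' @param seed_index bookkeeping index stored on the streamline.
#' @return a [streamline()].
#' @export
track_fiber <- function(seed, field, fa_map = NULL,
                        params = tracking_params(),
                        seed_index = NA_integer_) {
  stopifnot(inherits(field, "tensor_field"))
  if (is.null(fa_map)) fa_map <- compute_fa(field)
  grid <- field$grid
  seed <- as.numeric(seed)
  u <- (seed - grid$origin) / grid$vsize
  if (any(u < -0.5) || any(u > grid$dim - 0.5))
    stop("seed lies outside the volume")
  e1 <- e1_matrix(field)
  fa <- as.numeric(fa_map$values) * field$valid
  ijk <- coord_to_voxel(grid, seed)
  h0 <- e1[lin_index(grid, ijk), ]
  if (sum(h0^2) == 0) h0 <- c(1, 0, 0)
  reasons <- c("low-FA", "angle", "out-of-bounds", "max-length")
  fwd <- cpp_track_half(seed, h0, fa, e1, grid$dim, grid$vsize,
                        grid$origin, params$step, params$max_angle,
                        params$fa_stop, params$max_length / 2)
  bwd <- cpp_track_half(seed, -h0, fa, e1, grid$dim, grid$vsize,
                        grid$origin, params$step, params$max_angle,
                        params$fa_stop, params$max_length / 2)
  pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               fwd$points[-1L, , drop = FALSE])
  streamline(pts, seed_index = seed_index,
             termination = c(reasons[fwd$reason], reasons[bwd$reason]))
}

#' Track all seeds into a fiber set
#'
#' Convenience wrapper running [track_fiber()] over a seed matrix and
#' applying the length filter. Tracking is deterministic: identical
#' inputs give identical streamlines.
#'
#' @param field a `tensor_field`.
#' @param params a [tracking_params()].
#' @param seeds optional (n x 3) seed matrix; defaults to
#'   [generate_seeds()] on the field's FA map.
#' @param filter apply [filter_fibers()] (default TRUE).
#' @param space source-space tag for the result.
#' @return a [fiber_set()].
#' @export
track_fibers <- function(field, params = tracking_params(),
                         seeds = NULL, filter = TRUE,
                         space = "subject") {
  fa_map <- compute_fa(field)
  if (is.null(seeds)) seeds <- generate_seeds(fa_map, params)
  sl <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds)))
    sl[[i]] <- track_fiber(seeds[i, ], field, fa_map, params,
                           seed_index = i)
  fs <- fiber_set(sl, space = space, params = params)
  if (filter) filter_fibers(fs, params) else fs
}

#' Length-filter a fiber set
#'
#' Keeps fibers whose physical length lies within
#' `[min_length, max_length]` (inclusive: only strictly shorter or
#' longer fibers are excluded).
#'
#' @param fibers a `fiber_set`.
#' @param params a [tracking_params()].
#' @return the filtered `fiber_set`.
#' @export
filter_fibers <- function(fibers, params = tracking_params()) {
  lens <- fiber_lengths(fibers)
  # small tolerance so accumulated floating-point error in the
  # step-wise arc length cannot flip the inclusive boundaries
  eps <- 1e-9
  keep <- lens >= params$min_length - eps &
    lens <= params$max_length + eps
  fiber_set(fibers$streamlines[keep], space = fibers$space,
            params = params)
}

#' Warp a fiber set through a displacement field
#'
#' Displaces every streamline point by the trilinearly interpolated
#' field value and recomputes lengths; the source-space tag is flipped.
#' Points outside the field domain are clamped to the boundary value
#' and counted (a warning reports the count).
#'
#' @param fibers a `fiber_set`.
#' @param dfield a `displacement_field` (see [demons_register()]).
#' @return the warped `fiber_set` (attribute `"n_clamped"` carries the
#'   out-of-domain point count).
#' @export
warp_fibers <- function(fibers, dfield) {
  stopifnot(inherits(dfield, "displacement_field"))
  grid <- dfield$grid
  n_clamped <- 0L
  warped <- lapply(fibers$streamlines, function(s) {
    p <- s$points
    u <- (sweep(p, 2L, grid$origin, "-"))
    u <- sweep(u, 2L, grid$vsize, "/")
    out <- rowSums(u < 0 | u > matrix(grid$dim - 1, nrow(p), 3L,
                                      byrow = TRUE)) > 0
    n_clamped <<- n_clamped + sum(out)
    disp <- vapply(1:3, function(d)
      interp_trilinear(dfield$u[, , , d], grid, p, rule = "clamp"),
      numeric(nrow(p)))
    streamline(p + matrix(disp, nrow(p), 3L), seed_index = s$seed_index,
               termination = s$termination)
  })
  if (n_clamped > 0L)
    warning(n_clamped, " fiber points outside the field domain were clamped")
  out <- fiber_set(warped,
                   space = if (identical(fibers$space, "subject"))
                     "reference" else "subject",
                   params = fibers$params)
  attr(out, "n_clamped") <- n_clamped
  out
}
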