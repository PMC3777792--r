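#' Read and write scalar maps as NIfTI
#'
#' Maps are stored as double-precision NIfTI volumes; voxel size and
#' origin are carried in the NIfTI geometry so a write/read round trip
#' preserves data and grid exactly.
#'
#' @param map a [scalar_map()].
#' @param path file path (`.nii` / `.nii.gz`).
#' @param metric metric name to attach on read.
#' @return `read_map` returns a [scalar_map()].
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  write_volume(map$values, map$grid, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path, metric = "map") {
  vol <- read_volume(path)
  scalar_map(vol$values, metric, vol$grid)
}

# internal: 3D/4D array + grid <-> NIfTI
write_volume <- function(values, grid, path) {
  img <- RNifti::asNifti(structure(values, pixdim = grid$vsize),
                         datatype = "double")
  aff <- diag(4)
  diag(aff)[1:3] <- grid$vsize
  aff[1:3, 4] <- grid$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  vsize <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4]
  dm <- dim(img)
  grid <- voxel_grid(dm[1:3], vsize, origin)
  list(values = array(as.numeric(img), dim = dm), grid = grid)
}

#' Read and write diffusion-weighted data (NIfTI + FSL bval/bvec)
#'
#' The gradient table uses the FSL dialect: `.bval` is one row of
#' b-values, `.bvec` three rows (x, y, z components in image
#' coordinates), one column per volume. On read, volume and direction
#' counts are validated against each other (a mismatch is an error
#' naming the offending file), multiple b0 channels are averaged into
#' one, and the b0 channel is moved first.
#'
#' @param dwi a [diffusion_volume()].
#' @param prefix output path prefix (writes `<prefix>.nii`,
#'   `<prefix>.bval`, `<prefix>.bvec`).
#' @param nii_path,bval_path,bvec_path input paths.
#' @return `read_dwi` returns a [diffusion_volume()].
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "diffusion_volume"))
  write_volume(dwi$signals, dwi$grid, paste0(prefix, ".nii"))
  bvals <- c(0, rep(dwi$bval, nrow(dwi$directions)))
  bvecs <- rbind(0, dwi$directions)     # one row per volume, transpose out
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(t(bvecs), 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")),
    paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname write_dwi
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path) {
  vol <- read_volume(nii_path)
  if (length(dim(vol$values)) != 4L)
    stop("not a 4D volume: ", nii_path)
  nvol <- dim(vol$values)[4]
  bvals <- scan(bval_path, quiet = TRUE)
  if (length(bvals) != nvol)
    stop("bval count (", length(bvals), ") does not match volumes (",
         nvol, ") in ", bval_path)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) != 3L || ncol(bv) != nvol)
    stop("bvec must be 3 x ", nvol, " in ", bvec_path)
  is_b0 <- bvals == 0
  if (!any(is_b0)) stop("no b0 channel in ", bval_path)
  bnz <- unique(bvals[!is_b0])
  if (length(bnz) != 1L)
    stop("multiple nonzero b-values in ", bval_path,
         "; single-shell data expected")
  sig <- matrix(vol$values, ncol = nvol)
  s0 <- rowMeans(sig[, is_b0, drop = FALSE])   # average multiple b0s
  sw <- sig[, !is_b0, drop = FALSE]
  arr <- array(cbind(s0, sw), dim = c(vol$grid$dim, sum(!is_b0) + 1L))
  diffusion_volume(arr, bnz, t(bv[, !is_b0, drop = FALSE]), vol$grid)
}

#' Read and write streamlines (plain-text polyline dialect)
#'
#' A simple tab-separated track format: comment header lines carrying
#' the space tag, then one row per point with columns `fiber`, `x`,
#' `y`, `z` (mm, full double precision, so round trips preserve
#' coordinates beyond float32).
#'
#' @param fibers a [fiber_set()].
#' @param path file path.
#' @return `read_streamlines` returns a [fiber_set()].
#' @export
write_streamlines <- function(fibers, path) {
  stopifnot(inherits(fibers, "fiber_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# viscdti streamlines v1",
               paste0("# space=", fibers$space),
               "fiber\tx\ty\tz"), con)
  for (i in seq_along(fibers$streamlines)) {
    p <- fibers$streamlines[[i]]$points
    writeLines(paste(i, format(p[, 1], digits = 17, trim = TRUE),
                     format(p[, 2], digits = 17, trim = TRUE),
                     format(p[, 3], digits = 17, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  hdr <- readLines(path, n = 10L)
  space <- sub("^# space=", "", grep("^# space=", hdr, value = TRUE))
  if (!length(space)) space <- "subject"
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  sl <- lapply(split(tab, tab$fiber), function(df)
    streamline(as.matrix(df[, c("x", "y", "z")])))
  names(sl) <- NULL
  fiber_set(sl, space = space)
}

#' Read an integer-coded ROI label image
#'
#' @param path NIfTI path.
#' @return list with `values` (integer 3D array) and `grid`.
#' @export
read_labels <- function(path) {
  vol <- read_volume(path)
  list(values = array(as.integer(round(vol$values)),
                      dim = vol$grid$dim),
       grid = vol$grid)
}

#' Read and write pipeline configurations
#'
#' Configurations are plain lists serialised as YAML or JSON (by file
#' extension) and round-trip losslessly through their file
#' representation.
#'
#' @param config a named list (see [run_pipeline()]).
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_config` returns the list.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
}

#' Export a connectivity graph
#'
#' Writes the sparse direct and indirect matrices in Matrix Market
#' coordinate format plus a voxel-index table (TSV) mapping matrix rows
#' to grid indices for the voxels that carry any connection.
#'
#' @param graph a `connectivity_graph`.
#' @param prefix output path prefix.
#' @export
write_connectivity <- function(graph, prefix) {
  Matrix::writeMM(methods::as(graph$X * 1, "CsparseMatrix"),
                  paste0(prefix, "_direct.mtx"))
  Matrix::writeMM(methods::as(graph$Y * 1, "CsparseMatrix"),
                  paste0(prefix, "_indirect.mtx"))
  active <- which(Matrix::rowSums(graph$X) + Matrix::rowSums(graph$Y) > 0)
  ijk <- ijk_index(graph$grid, active)
  write.table(data.frame(index = active, i = ijk[, 1], j = ijk[, 2],
                         k = ijk[, 3]),
              paste0(prefix, "_voxels.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
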