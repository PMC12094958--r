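# Internal constructors and small grid utilities.

#' Construct a CTVolume
#'
#' @param data 3D numeric array
#' @param spacing voxel spacing in mm (default 1 mm isotropic)
#' @param transform 4x4 voxel-to-world affine; defaults to a diagonal
#'   scaling by \code{spacing}
#' @return a \linkS4class{CTVolume}
#' @export
newVolume <- function(data, spacing = c(1, 1, 1), transform = NULL) {
  storage.mode(data) <- "double"
  if (is.null(transform)) transform <- diag(c(spacing, 1))
  new("CTVolume", data = data, spacing = as.numeric(spacing),
      transform = transform)
}

#' Construct a LabelMap
#'
#' @param data 3D integer array of class ids
#' @param scheme a \linkS4class{LabelScheme} or scheme name
#' @param spacing voxel spacing in mm
#' @param transform 4x4 voxel-to-world affine
#' @return a \linkS4class{LabelMap}
#' @export
newLabelMap <- function(data, scheme, spacing = c(1, 1, 1),
                        transform = NULL) {
  if (is.character(scheme)) scheme <- labelScheme(scheme)
  storage.mode(data) <- "integer"
  if (is.null(transform)) transform <- diag(c(spacing, 1))
  new("LabelMap", data = data, scheme = scheme,
      spacing = as.numeric(spacing), transform = transform)
}

#' Construct a ProbabilityMap
#'
#' @param data 4D numeric array (x, y, z, class), simplex-normalized
#' @param scheme a \linkS4class{LabelScheme} or scheme name
#' @param spacing voxel spacing in mm
#' @param transform 4x4 voxel-to-world affine
#' @return a \linkS4class{ProbabilityMap}
#' @export
newProbabilityMap <- function(data, scheme, spacing = c(1, 1, 1),
                              transform = NULL) {
  if (is.character(scheme)) scheme <- labelScheme(scheme)
  storage.mode(data) <- "double"
  if (is.null(transform)) transform <- diag(c(spacing, 1))
  new("ProbabilityMap", data = data, scheme = scheme,
      spacing = as.numeric(spacing), transform = transform)
}

#' Apply a voxel-to-world affine to 0-based voxel indices
#'
#' @param transform 4x4 affine
#' @param index numeric vector of length 3, or an n x 3 matrix, 0-based
#' @return world coordinates (mm), same shape as \code{index}
#' @export
voxelToWorld <- function(transform, index) {
  single <- is.null(dim(index))
  m <- rbind(t(matrix(as.numeric(index), ncol = 3L)), 1)
  out <- t((transform %*% m)[1:3, , drop = FALSE])
  if (single) drop(out) else out
}

# per-voxel argmax over the class axis of a (x,y,z,K) array; ties take the
# lowest class index. Returns a 3D array of 0-based class ids.
.argmaxClasses <- function(p4) {
  d <- dim(p4)
  m <- matrix(p4, prod(d[1:3]), d[4L])
  idx <- max.col(m, ties.method = "first") - 1L
  array(as.integer(idx), d[1:3])
}

# one-hot encode an integer label array against K classes (ids 0..K-1);
# returns a (x,y,z,K) double array
.oneHot <- function(lab, K) {
  d <- dim(lab)
  n <- prod(d)
  out <- numeric(n * K)
  out[seq_len(n) + n * as.numeric(lab)] <- 1
  array(out, c(d, K))
}

# softmax over the 4th axis of a (x,y,z,K) array
.softmax4 <- function(z) {
  d <- dim(z)
  m <- matrix(z, prod(d[1:3]), d[4L])
  mx <- m[, 1L]
  for (k in seq_len(d[4L])[-1L]) mx <- pmax(mx, m[, k])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  array(p, d)
}

# stop() with a classed condition so callers can discriminate error kinds
.stopWith <- function(class, fmt, ...) {
  stop(structure(class = c(class, "cmfelsegError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1L))))
}

# shared-geometry check used by grid operations
.checkSameGrid <- function(a, b, what = "inputs") {
  da <- dim(voxels(a)); db <- dim(voxels(b))
  if (!all(da[1:3] == db[1:3]))
    .stopWith("contractError", "%s must share one voxel grid", what)
  invisible(TRUE)
}
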