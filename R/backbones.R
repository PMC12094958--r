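# Three scaled volumetric encoder-decoder segmenter families behind one
# prediction contract:
#   residual_unet     — residual blocks per stage (V-Net trait)
#   dynamic_unet      — plain double-conv stages with a documented
#                       channel-derivation rule (nnU-Net trait, simplified)
#   large_kernel_unet — depthwise large-kernel spatial mixing with pointwise
#                       channel mixing per stage (3D UX-Net trait)
# These are analogues built for desk-scale experiments, not replicas of the
# published clinical architectures.

#' Configure a segmenter backbone
#'
#' @param family "residual_unet", "dynamic_unet" or "large_kernel_unet"
#' @param nClasses per-head class counts: a single count for the coarse
#'   stage, \code{c(33, 5)} for the dual-head fine stage
#' @param depth encoder levels (>= 2); each extra level halves resolution
#'   and doubles channels (capped at 8x base width)
#' @param baseWidth channels at full resolution (>= 4)
#' @param kernelSize spatial-mixing kernel of the large-kernel family
#'   (odd, >= 5)
#' @param normalization "instance" (default) or "none"
#' @param activation "relu" (default) or "leakyrelu"
#' @param inChannels image channels (1 for CT)
#' @return a validated \linkS4class{BackboneConfig}
#' @export
backboneConfig <- function(family, nClasses, depth = 3L, baseWidth = 8L,
                           kernelSize = 5L, normalization = "instance",
                           activation = "relu", inChannels = 1L) {
  tryCatch(
    new("BackboneConfig", family = as.character(family),
        inChannels = as.integer(inChannels),
        nClasses = as.integer(nClasses), depth = as.integer(depth),
        baseWidth = as.integer(baseWidth),
        kernelSize = as.integer(kernelSize),
        normalization = normalization, activation = activation),
    error = function(e)
      .stopWith("configurationError", "%s", conditionMessage(e)))
}

#' Build a segmenter with deterministic initialization
#'
#' Network inputs are the per-volume z-scored intensities plus three
#' normalized voxel-coordinate channels (a coordinate-augmented stem):
#' several CMF structures share CT intensity and are distinguished by
#' position, so the coordinate channels give every patch its place in the
#' scan. Outputs are per-voxel class probabilities per head, softmax
#' normalized (per-voxel sums equal 1 within 1e-6).
#'
#' @param config a \linkS4class{BackboneConfig}
#' @param seed initialization seed
#' @return an untrained \linkS4class{Segmenter}
#' @examples
#' seg <- buildSegmenter(backboneConfig("residual_unet", 10), seed = 1)
#' @export
buildSegmenter <- function(config, seed = 1L) {
  if (is.character(config))
    .stopWith("configurationError", "config must be a BackboneConfig")
  stopifnot(is(config, "BackboneConfig"))
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v))
    .stopWith("configurationError", paste(v, collapse = "; "))
  params <- .withSeed(seed, .initParams(config))
  new("Segmenter", config = config, params = params, trained = FALSE,
      seed = as.integer(seed))
}

#' Total trainable parameter count of a segmenter
#' @param seg a \linkS4class{Segmenter}
#' @return integer parameter count
#' @export
nParams <- function(seg) .paramCount(seg@params)

# spatial size the network needs: every axis divisible by 2^(depth-1)
.gridMultiple <- function(config) 2L^(config@depth - 1L)

# forward pass to per-head probability arrays on one patch
.segForward <- function(seg, patch, mu, sigma, fullShape, origin,
                        keepCache = FALSE) {
  x <- .networkInput(patch, mu, sigma, fullShape, origin)
  fw <- .unetFwd(seg@config, seg@params, x, keepCache = keepCache)
  fw$probs <- lapply(fw$logits, .softmax4)
  fw
}

#' Patch-based inference with overlapping-window blending
#'
#' Runs the segmenter over sliding windows, blends overlapping windows with
#' weights that sum to 1 at every voxel, and renormalizes each per-voxel
#' class vector onto the simplex. Volumes smaller than the patch are
#' symmetrically zero-padded and the output cropped back, so the output
#' grid always equals the input grid.
#'
#' @param model a \linkS4class{Segmenter}
#' @param volume a \linkS4class{CTVolume}
#' @param patch cubic window edge; NULL (default) uses the whole padded
#'   volume as one window. Must be a multiple of 2^(depth-1).
#' @param overlap fractional window overlap in [0, 1)
#' @return a \linkS4class{ProbabilityMap} for a single-head model (class
#'   count 10/33/5 selects the matching scheme); a list of per-head
#'   ProbabilityMaps for a dual-head model
#' @export
slidingWindowPredict <- function(model, volume, patch = NULL,
                                 overlap = 0.5) {
  stopifnot(is(model, "Segmenter"), is(volume, "CTVolume"))
  arrs <- .swPredictArrays(model, volume@data, patch, overlap)
  maps <- lapply(arrs, function(a) {
    sch <- .schemeForCount(dim(a)[4L])
    newProbabilityMap(a, sch, volume@spacing, volume@transform)
  })
  if (length(maps) == 1L) maps[[1L]] else maps
}

.schemeForCount <- function(K) {
  switch(as.character(K),
         "10" = labelScheme("coarse"),
         "33" = labelScheme("fine"),
         "5" = labelScheme("parity"),
         .stopWith("contractError",
                   "no canonical scheme with %d classes", K))
}

# core sliding-window engine on plain arrays; returns a list of per-head
# (x,y,z,K) probability arrays
.swPredictArrays <- function(model, vol, patch = NULL, overlap = 0.5) {
  cfg <- model@config
  m <- .gridMultiple(cfg)
  sh <- dim(vol)
  padded <- as.integer(ceiling(sh / m) * m)
  if (is.null(patch)) patch <- max(padded)
  patch <- as.integer(patch)
  if (patch %% m != 0L)
    .stopWith("sizeError", "patch must be a multiple of %d", m)
  padded <- pmax(padded, patch)
  if (any(patch > padded))
    .stopWith("sizeError", "patch exceeds the padded volume bound")
  if (overlap < 0 || overlap >= 1)
    .stopWith("sizeError", "overlap must lie in [0, 1)")

  pad <- padded - sh
  lo <- pad %/% 2L
  pv <- array(0, padded)
  pv[lo[1L] + seq_len(sh[1L]), lo[2L] + seq_len(sh[2L]),
     lo[3L] + seq_len(sh[3L])] <- vol
  mu <- mean(vol); sigma <- max(sd(vol), 1e-8)

  starts <- lapply(1:3, function(i) {
    n <- padded[i]
    if (n == patch) return(0L)
    stride <- max(1L, as.integer(round(patch * (1 - overlap))))
    unique(c(seq(0L, n - patch, by = stride), n - patch))
  })
  nH <- length(cfg@nClasses)
  acc <- lapply(seq_len(nH), function(h)
    array(0, c(padded, cfg@nClasses[h])))
  wsum <- array(0, padded)
  for (sx in starts[[1L]]) for (sy in starts[[2L]]) for (sz in starts[[3L]]) {
    ix <- sx + seq_len(patch); iy <- sy + seq_len(patch)
    iz <- sz + seq_len(patch)
    pp <- pv[ix, iy, iz, drop = FALSE]
    dim(pp) <- c(patch, patch, patch)
    fw <- .segForward(model, pp, mu, sigma, padded, c(sx, sy, sz))
    for (h in seq_len(nH))
      acc[[h]][ix, iy, iz, ] <- acc[[h]][ix, iy, iz, , drop = FALSE] +
        fw$probs[[h]]
    wsum[ix, iy, iz] <- wsum[ix, iy, iz] + 1
  }
  out <- lapply(seq_len(nH), function(h) {
    a <- acc[[h]] / as.vector(wsum)
    a <- a[lo[1L] + seq_len(sh[1L]), lo[2L] + seq_len(sh[2L]),
           lo[3L] + seq_len(sh[3L]), , drop = FALSE]
    # renormalize onto the simplex
    s <- rowSums(matrix(a, prod(sh), dim(a)[4L]))
    a / array(s, dim(a))
  })
  out
}

#' Normalized sliding-window blending weights
#'
#' Accumulates the blending weights alone (no model involved) over a grid,
#' exposing the weight field the prediction path divides by. After
#' normalization the field is exactly 1 everywhere.
#'
#' @param shape 3D grid shape
#' @param patch window edge
#' @param overlap fractional overlap
#' @return 3D array of normalized accumulated weights
#' @export
slidingWindowWeights <- function(shape, patch, overlap = 0.5) {
  shape <- as.integer(rep(shape, length.out = 3L))
  patch <- as.integer(patch)
  starts <- lapply(1:3, function(i) {
    n <- shape[i]
    if (n == patch) return(0L)
    stride <- max(1L, as.integer(round(patch * (1 - overlap))))
    unique(c(seq(0L, n - patch, by = stride), n - patch))
  })
  wsum <- array(0, shape)
  for (sx in starts[[1L]]) for (sy in starts[[2L]]) for (sz in starts[[3L]])
    wsum[sx + seq_len(patch), sy + seq_len(patch), sz + seq_len(patch)] <-
      wsum[sx + seq_len(patch), sy + seq_len(patch), sz + seq_len(patch)] + 1
  wsum / wsum
}

#' Save / load a segmenter checkpoint
#'
#' Single-file archive embedding the \linkS4class{BackboneConfig} and all
#' parameters.
#'
#' @param seg a \linkS4class{Segmenter}
#' @param path checkpoint path
#' @return \code{path} invisibly; \code{loadSegmenter} returns the model
#' @export
saveSegmenter <- function(seg, path) {
  stopifnot(is(seg, "Segmenter"))
  saveRDS(list(config = seg@config, params = seg@params,
               trained = seg@trained, seed = seg@seed), path)
  invisible(path)
}

#' @rdname saveSegmenter
#' @export
loadSegmenter <- function(path) {
  if (!file.exists(path))
    .stopWith("notFoundError", "checkpoint not found: %s", path)
  x <- readRDS(path)
  new("Segmenter", config = x$config, params = x$params,
      trained = x$trained, seed = x$seed)
}
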