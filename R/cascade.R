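# Two-stage coarse-to-fine pipeline: 10-class coarse segmentation of the
# whole volume, dentition ROI extraction from the coarse tooth foreground,
# synchronous crop/resample, dual-head (33-class / 5-class) fine
# segmentation inside the ROI, adjacent-tooth identity correction, and
# paste-back to the full grid.

.stage <- function(name, expr) {
  tryCatch(expr, cmfelsegError = function(e) {
    e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
    stop(e)
  })
}

#' Coarse 10-class segmentation of a full volume
#'
#' @param model a single-head \linkS4class{Segmenter} with 10 classes
#' @param volume a \linkS4class{CTVolume}
#' @param patch,overlap sliding-window settings
#' @return \code{list(labels = coarse LabelMap, prob = ProbabilityMap)};
#'   labels are the per-voxel argmax (ties take the lowest class id)
#' @export
segmentCoarse <- function(model, volume, patch = NULL, overlap = 0.5) {
  stopifnot(is(model, "Segmenter"))
  cfg <- model@config
  if (length(cfg@nClasses) != 1L || cfg@nClasses[1L] != 10L)
    .stopWith("contractError",
              "coarse segmentation expects a single-head 10-class model")
  prob <- slidingWindowPredict(model, volume, patch, overlap)
  labels <- newLabelMap(.argmaxClasses(prob@data), prob@scheme,
                        volume@spacing, volume@transform)
  list(labels = labels, prob = prob)
}

#' Extract the dentition region of interest from a coarse label map
#'
#' The tight bounding box of all voxels labeled upper teeth (8) or lower
#' teeth (9), dilated by \code{margin} voxels per axis and clipped to the
#' grid; half-open [lower, upper) convention.
#'
#' @param coarse a coarse-scheme \linkS4class{LabelMap}
#' @param margin dilation margin in voxels (default 3)
#' @param target resample target shape recorded in the box (default: the
#'   box extent, i.e. a pure crop)
#' @return an \linkS4class{ROIBox}
#' @export
extractTeethROI <- function(coarse, margin = 3L, target = NULL) {
  stopifnot(is(coarse, "LabelMap"))
  if (coarse@scheme@name != "coarse")
    .stopWith("contractError", "extractTeethROI expects a coarse-scheme map")
  sh <- dim(coarse@data)
  idx <- which(coarse@data == .COARSE_UPPER_TEETH |
                 coarse@data == .COARSE_LOWER_TEETH)
  if (!length(idx))
    .stopWith("emptyForegroundError",
              "no dentition foreground (coarse ids 8/9) in the label map")
  co <- arrayInd(idx, sh) - 1L
  lower <- pmax(0L, apply(co, 2L, min) - as.integer(margin))
  upper <- pmin(sh, apply(co, 2L, max) + 1L + as.integer(margin))
  if (is.null(target)) target <- upper - lower
  new("ROIBox", lower = as.integer(lower), upper = as.integer(upper),
      sourceShape = as.integer(sh),
      targetShape = as.integer(rep(target, length.out = 3L)))
}

# trilinear sampling of arr at fractional 0-based coords given per axis
.trilinear <- function(arr, cx, cy, cz) {
  sh <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 0), n - 1)
  cx <- cl(cx, sh[1L]); cy <- cl(cy, sh[2L]); cz <- cl(cz, sh[3L])
  x0 <- pmin(floor(cx), sh[1L] - 1); y0 <- pmin(floor(cy), sh[2L] - 1)
  z0 <- pmin(floor(cz), sh[3L] - 1)
  x1 <- pmin(x0 + 1, sh[1L] - 1); y1 <- pmin(y0 + 1, sh[2L] - 1)
  z1 <- pmin(z0 + 1, sh[3L] - 1)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  ts <- c(length(cx), length(cy), length(cz))
  w3 <- function(wx, wy, wz)
    array(rep(wx, times = prod(ts[2:3])), ts) *
    array(rep(rep(wy, each = ts[1L]), times = ts[3L]), ts) *
    array(rep(wz, each = prod(ts[1:2])), ts)
  out <- array(0, ts)
  for (cz_ in list(list(z0, 1 - fz), list(z1, fz)))
    for (cy_ in list(list(y0, 1 - fy), list(y1, fy)))
      for (cx_ in list(list(x0, 1 - fx), list(x1, fx)))
        out <- out + w3(cx_[[2L]], cy_[[2L]], cz_[[2L]]) *
          arr[cx_[[1L]] + 1, cy_[[1L]] + 1, cz_[[1L]] + 1, drop = FALSE]
  out
}

#' Synchronously crop and resample a volume and its labels
#'
#' Image and labels are cropped to the same half-open box and resampled to
#' the box's target shape. Labels always use nearest-neighbour
#' interpolation (the output label set is a subset of the input set);
#' image interpolation defaults to trilinear with nearest available.
#' Geometry metadata is updated so world coordinates stay correct: the
#' world position of output voxel (0,0,0) equals that of the input voxel
#' at the box's lower corner when no resampling occurs.
#'
#' @param volume a \linkS4class{CTVolume}, or NULL for labels-only
#' @param labels a \linkS4class{LabelMap}, or NULL for image-only
#' @param box an \linkS4class{ROIBox}
#' @param target target shape (default: the box's recorded target)
#' @param imageInterpolation "trilinear" (default) or "nearest"
#' @return \code{list(volume = , labels = )} (either may be NULL)
#' @export
cropResample <- function(volume, labels, box, target = NULL,
                         imageInterpolation = c("trilinear", "nearest")) {
  imageInterpolation <- match.arg(imageInterpolation)
  stopifnot(is(box, "ROIBox"))
  if (is.null(target)) target <- box@targetShape
  target <- as.integer(rep(target, length.out = 3L))
  if (any(target < 1L))
    .stopWith("sizeError", "degenerate target shape: %s",
              paste(target, collapse = "x"))
  ref <- if (!is.null(volume)) volume else labels
  if (is.null(ref)) .stopWith("contractError", "need a volume or labels")
  sh <- dim(voxels(ref))
  if (any(box@upper > sh) )
    .stopWith("contractError", "box does not fit the input grid")
  extent <- box@upper - box@lower
  scale <- extent / target
  # centre-aligned sample coordinates per axis (0-based, source frame)
  coords <- lapply(1:3, function(i)
    box@lower[i] + (seq_len(target[i]) - 0.5) * scale[i] - 0.5)
  nn <- lapply(1:3, function(i)
    pmin(pmax(as.integer(floor(coords[[i]] + 0.5)), box@lower[i]),
         box@upper[i] - 1L))
  # updated affine: new index -> old index -> world
  M <- diag(4)
  diag(M)[1:3] <- scale
  M[1:3, 4L] <- box@lower + 0.5 * scale - 0.5
  newTransform <- ref@transform %*% M
  newSpacing <- ref@spacing * scale
  outVol <- NULL
  outLab <- NULL
  if (!is.null(volume)) {
    stopifnot(is(volume, "CTVolume"))
    dv <- if (imageInterpolation == "nearest" || all(scale == 1)) {
      volume@data[nn[[1L]] + 1L, nn[[2L]] + 1L, nn[[3L]] + 1L, drop = FALSE]
    } else {
      .trilinear(volume@data, coords[[1L]], coords[[2L]], coords[[3L]])
    }
    dim(dv) <- target
    outVol <- newVolume(dv, newSpacing, newTransform)
  }
  if (!is.null(labels)) {
    stopifnot(is(labels, "LabelMap"))
    dl <- labels@data[nn[[1L]] + 1L, nn[[2L]] + 1L, nn[[3L]] + 1L,
                      drop = FALSE]
    dim(dl) <- target
    outLab <- newLabelMap(dl, labels@scheme, newSpacing, newTransform)
  }
  list(volume = outVol, labels = outLab)
}

#' Dual-head fine segmentation of a dentition ROI
#'
#' @param model a dual-head \linkS4class{Segmenter} with classes c(33, 5)
#' @param roiVolume the cropped/resampled ROI \linkS4class{CTVolume}
#' @param patch,overlap sliding-window settings
#' @return \code{list(p33 = fine ProbabilityMap, p5 = parity
#'   ProbabilityMap)} on the ROI grid, both simplex-valid
#' @export
segmentFine <- function(model, roiVolume, patch = NULL, overlap = 0.5) {
  stopifnot(is(model, "Segmenter"))
  cfg <- model@config
  if (!(length(cfg@nClasses) == 2L && all(cfg@nClasses == c(33L, 5L))))
    .stopWith("contractError",
              "fine segmentation expects a dual-head model with classes c(33, 5)")
  maps <- slidingWindowPredict(model, roiVolume, patch, overlap)
  list(p33 = maps[[1L]], p5 = maps[[2L]])
}

#' Correct tooth identities using the parity head and adjacency
#'
#' Starts from the per-voxel argmax of the 33-class head, splits every
#' tooth id into connected components, and checks each component's
#' jaw/parity group against the vote of the 5-class head. A component whose
#' 33-class id conflicts with the parity vote, with mean voted-class
#' confidence at least \code{tau}, is relabeled to the FDI id that (a)
#' keeps the component's current arch side (mislabeling between adjacent
#' same-side teeth is the failure mode the parity head detects), (b)
#' matches the voted jaw/parity group, and (c) preserves within-quadrant
#' ordering against already-accepted components, using the
#' anterior-posterior centroid coordinate, which grows monotonically from
#' incisors to molars along each arch quadrant. Among admissible ids the
#' one with maximal summed 33-class probability wins (ties take the lowest
#' id). Components are processed in descending size; parity-consistent
#' components are never changed, so the operation is idempotent on
#' consistent inputs.
#'
#' @param p33 fine-scheme \linkS4class{ProbabilityMap}
#' @param p5 parity-scheme \linkS4class{ProbabilityMap} on the same grid
#' @param tau confidence threshold in [0, 1] (default 0.6)
#' @return a fine-scheme \linkS4class{LabelMap}
#' @export
combinationCorrect <- function(p33, p5, tau = 0.6) {
  stopifnot(is(p33, "ProbabilityMap"), is(p5, "ProbabilityMap"))
  if (p33@scheme@name != "fine" || p5@scheme@name != "parity")
    .stopWith("contractError", "need fine (p33) and parity (p5) maps")
  .checkSameGrid(p33, p5, "p33 and p5")
  if (tau < 0 || tau > 1) .stopWith("contractError", "tau must be in [0, 1]")
  sh <- dim(p33@data)[1:3]
  n <- prod(sh)
  labs <- .argmaxClasses(p33@data)
  lab5 <- .argmaxClasses(p5@data)
  p33m <- matrix(p33@data, n, 33L)
  p5m <- matrix(p5@data, n, 5L)
  parityOf <- unname(.parityOfFineId())        # parity id per fine id 1..32

  ids <- setdiff(sort(unique(as.vector(labs))), 0L)
  if (!length(ids)) return(.asFineMap(labs, p33))

  comps <- list()
  for (id in ids) {
    mask <- array(0L, sh); mask[labs == id] <- 1L
    cc <- label_components_cpp(mask, sh, 26L)
    for (ci in seq_len(max(cc))) {
      vox <- which(cc == ci)
      comps[[length(comps) + 1L]] <- list(id = id, vox = vox,
                                          size = length(vox))
    }
  }
  ord <- order(-vapply(comps, `[[`, 0, "size"),
               vapply(comps, `[[`, 0L, "id"))
  accepted <- data.frame(quadrant = integer(), position = integer(),
                         archY = numeric())
  # right quadrants (FDI 1, 4) pair with left quadrants (2, 3) per jaw
  quadOf <- function(jaw, sideRight) {
    if (jaw == "upper") (if (sideRight) 1L else 2L)
    else (if (sideRight) 4L else 3L)
  }
  for (ci in ord) {
    comp <- comps[[ci]]
    votes <- lab5[comp$vox]
    votes <- votes[votes > 0L]
    curPar <- parityOf[comp$id]
    cent <- colMeans(arrayInd(comp$vox, sh) - 1L)
    finalId <- comp$id
    if (length(votes)) {
      tab <- tabulate(votes, nbins = 4L)
      voted <- which.max(tab)                      # ties: lowest class id
      conf <- mean(p5m[comp$vox, voted + 1L])
      if (voted != curPar && conf >= tau) {
        jaw <- if (voted <= 2L) "upper" else "lower"
        curQuad <- fineIdToFdi(comp$id) %/% 10L
        quadrant <- quadOf(jaw, curQuad %in% c(1L, 4L))
        par_pos <- if (voted %in% c(1L, 3L)) c(1L, 3L, 5L, 7L) else
          c(2L, 4L, 6L, 8L)
        cand <- fdiToFineId(quadrant * 10L + par_pos)
        # ordering constraint against accepted components in this quadrant:
        # FDI position must grow with the anterior-posterior coordinate
        prior <- accepted[accepted$quadrant == quadrant, , drop = FALSE]
        ok <- vapply(seq_along(cand), function(j) {
          p_ <- par_pos[j]
          all(sign(p_ - prior$position) == sign(cent[2L] - prior$archY))
        }, logical(1L))
        cand <- cand[ok]
        if (length(cand)) {
          mass <- colSums(p33m[comp$vox, cand + 1L, drop = FALSE])
          finalId <- cand[which.max(mass)]         # ties: lowest id
        }
      }
    }
    labs[comp$vox] <- finalId
    fdi <- fineIdToFdi(finalId)
    accepted[nrow(accepted) + 1L, ] <- list(fdi %/% 10L, fdi %% 10L,
                                            cent[2L])
  }
  .asFineMap(labs, p33)
}

.asFineMap <- function(labs, ref) {
  newLabelMap(labs, labelScheme("fine"), ref@spacing, ref@transform)
}

#' Paste an ROI label map back onto the full grid
#'
#' Nearest-neighbour resample of the ROI labels back to the box extent,
#' embedded at the box location with background elsewhere. When the box's
#' target equals its extent, paste after crop is the identity inside the
#' box.
#'
#' @param fineRoi a \linkS4class{LabelMap} shaped to the box target
#' @param box the \linkS4class{ROIBox} used for cropping
#' @param fullShape shape of the full grid
#' @param spacing,transform geometry of the full grid (defaults: unit)
#' @return a \linkS4class{LabelMap} on the full grid
#' @export
pasteBack <- function(fineRoi, box, fullShape, spacing = c(1, 1, 1),
                      transform = NULL) {
  stopifnot(is(fineRoi, "LabelMap"), is(box, "ROIBox"))
  fullShape <- as.integer(rep(fullShape, length.out = 3L))
  if (!all(dim(fineRoi@data) == box@targetShape))
    .stopWith("contractError",
              "ROI labels shaped %s do not match the box target %s",
              paste(dim(fineRoi@data), collapse = "x"),
              paste(box@targetShape, collapse = "x"))
  if (any(box@upper > fullShape))
    .stopWith("contractError", "box does not fit the full grid")
  extent <- box@upper - box@lower
  out <- array(0L, fullShape)
  src <- lapply(1:3, function(i) {
    v <- seq_len(extent[i]) - 1L
    pmin(pmax(as.integer(floor((v + 0.5) * box@targetShape[i] /
                                 extent[i])), 0L),
         box@targetShape[i] - 1L)
  })
  blk <- fineRoi@data[src[[1L]] + 1L, src[[2L]] + 1L, src[[3L]] + 1L,
                      drop = FALSE]
  out[box@lower[1L] + seq_len(extent[1L]),
      box@lower[2L] + seq_len(extent[2L]),
      box@lower[3L] + seq_len(extent[3L])] <- blk
  newLabelMap(out, fineRoi@scheme, spacing, transform)
}

#' Run the full coarse-to-fine cascade on one volume
#'
#' Composition of \code{segmentCoarse}, \code{extractTeethROI},
#' \code{cropResample}, \code{segmentFine}, \code{combinationCorrect} and
#' \code{pasteBack}. When the coarse stage finds no dentition, the cascade
#' falls back to a whole-volume ROI; the fallback is flagged on the result.
#'
#' @param coarseModel single-head 10-class \linkS4class{Segmenter}
#' @param fineModel dual-head \linkS4class{Segmenter} with classes c(33, 5)
#' @param volume a \linkS4class{CTVolume}
#' @param config a \linkS4class{PipelineConfig} (ROI margin, fine target
#'   shape, correction threshold tau)
#' @param keepProbs retain per-stage probability arrays on the result
#' @return a \linkS4class{CascadeResult}
#' @export
runCascade <- function(coarseModel, fineModel, volume,
                       config = loadPipelineConfig(), keepProbs = FALSE) {
  stopifnot(is(volume, "CTVolume"))
  sh <- dim(volume@data)
  cs <- .stage("coarse", segmentCoarse(coarseModel, volume))
  fallback <- FALSE
  box <- tryCatch(
    .stage("roi", extractTeethROI(cs$labels, config@roiMargin)),
    emptyForegroundError = function(e) NULL)
  if (is.null(box)) {
    fallback <- TRUE
    box <- new("ROIBox", lower = c(0L, 0L, 0L), upper = as.integer(sh),
               sourceShape = as.integer(sh),
               targetShape = rep(config@fineTargetShape, 3L))
  } else {
    box@targetShape <- rep(config@fineTargetShape, 3L)
  }
  roi <- .stage("crop", cropResample(volume, NULL, box))
  fine <- .stage("fine", segmentFine(fineModel, roi$volume))
  corrected <- .stage("correct",
                      combinationCorrect(fine$p33, fine$p5, config@tau))
  fineFull <- .stage("paste",
                     pasteBack(corrected, box, sh, volume@spacing,
                               volume@transform))
  toothVox <- fineFull@data > 0L
  disagreement <- if (any(toothVox)) {
    mean(!(cs$labels@data[toothVox] %in%
             c(.COARSE_UPPER_TEETH, .COARSE_LOWER_TEETH)))
  } else 0
  new("CascadeResult", coarse = cs$labels, fine = fineFull, roi = box,
      coarseProb = if (keepProbs) cs$prob@data else NULL,
      fineProb = if (keepProbs) fine$p33@data else NULL,
      disagreement = disagreement, roiFallback = fallback)
}
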