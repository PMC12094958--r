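#' @name accessors
#' @title Accessors for cmfelseg containers
#' @description Slot access goes through these generics; user code should
#'   never reach into slots directly.
#' @param x a cmfelseg object
NULL

#' @describeIn accessors voxel data array
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @describeIn accessors voxel spacing in mm
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @describeIn accessors 4x4 voxel-to-world affine
#' @export
setGeneric("worldTransform", function(x) standardGeneric("worldTransform"))

#' @describeIn accessors the label scheme of a map
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @describeIn accessors ordered class ids of a scheme
#' @export
setGeneric("classIds", function(x) standardGeneric("classIds"))

#' @describeIn accessors class labels of a scheme
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @describeIn accessors number of classes
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

setMethod("voxels", "CTVolume", function(x) x@data)
setMethod("voxels", "LabelMap", function(x) x@data)
setMethod("voxels", "ProbabilityMap", function(x) x@data)
setMethod("spacing", "CTVolume", function(x) x@spacing)
setMethod("spacing", "LabelMap", function(x) x@spacing)
setMethod("spacing", "ProbabilityMap", function(x) x@spacing)
setMethod("worldTransform", "CTVolume", function(x) x@transform)
setMethod("worldTransform", "LabelMap", function(x) x@transform)
setMethod("worldTransform", "ProbabilityMap", function(x) x@transform)
setMethod("scheme", "LabelMap", function(x) x@scheme)
setMethod("scheme", "ProbabilityMap", function(x) x@scheme)
setMethod("classIds", "LabelScheme", function(x) x@ids)
setMethod("classLabels", "LabelScheme", function(x) x@labels)
setMethod("nClasses", "LabelScheme", function(x) length(x@ids))
setMethod("nClasses", "LabelMap", function(x) length(x@scheme@ids))
setMethod("nClasses", "ProbabilityMap", function(x) length(x@scheme@ids))

setMethod("show", "LabelScheme", function(object) {
  cat(sprintf("LabelScheme '%s' with %d classes\n", object@name,
              length(object@ids)))
  n <- min(length(object@ids), 6L)
  cat(paste(sprintf("  %2d %s", object@ids[seq_len(n)],
                    object@labels[seq_len(n)]), collapse = "\n"), "\n")
  if (length(object@ids) > n) cat(sprintf("  ... %d more\n",
                                          length(object@ids) - n))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("CTVolume %dx%dx%d, spacing %s mm, range [%.1f, %.1f]\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 3),
                                      collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  present <- sort(unique(as.vector(object@data)))
  cat(sprintf("LabelMap %dx%dx%d on scheme '%s', %d/%d classes present\n",
              d[1], d[2], d[3], object@scheme@name, length(present),
              length(object@scheme@ids)))
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProbabilityMap %dx%dx%d, %d classes on scheme '%s'\n",
              d[1], d[2], d[3], d[4], object@scheme@name))
})

setMethod("show", "ROIBox", function(object) {
  cat(sprintf("ROIBox [%s) -> [%s) of grid %s, target %s\n",
              paste(object@lower, collapse = ","),
              paste(object@upper, collapse = ","),
              paste(object@sourceShape, collapse = "x"),
              paste(object@targetShape, collapse = "x")))
})

setMethod("show", "PhantomSample", function(object) {
  d <- dim(object@volume@data)
  nteeth <- sum(object@placements$present)
  cat(sprintf("PhantomSample %dx%dx%d (seed %d): %d teeth present\n",
              d[1], d[2], d[3], object@seed, nteeth))
})

setMethod("show", "Segmenter", function(object) {
  cfg <- object@config
  cat(sprintf(
    "Segmenter family '%s': depth %d, base width %d, head(s) %s [%s]\n",
    cfg@family, cfg@depth, cfg@baseWidth,
    paste(cfg@nClasses, collapse = "+"),
    if (object@trained) "trained" else "untrained"))
})

setMethod("show", "EnsembleWeights", function(object) {
  cat("EnsembleWeights:\n")
  for (t in seq_along(object@epsilon))
    cat(sprintf("  model %d: eps = %.4f, alpha = %.4f, w = %.4f\n",
                t, object@epsilon[t], object@alpha[t], object@w[t]))
})

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf(
    "CascadeResult: ROI [%s)-[%s)%s, stage disagreement %.3f\n",
    paste(object@roi@lower, collapse = ","),
    paste(object@roi@upper, collapse = ","),
    if (object@roiFallback) " (whole-volume fallback)" else "",
    object@disagreement))
})

setMethod("show", "GradeReport", function(object) {
  cat(sprintf("GradeReport: overall %s\n", object@overall))
  for (nm in names(object@grades))
    cat(sprintf("  %-28s %s\n", nm, object@grades[nm]))
})
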