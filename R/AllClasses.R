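# Central S4 containers. All voxel grids are column-major R arrays with axis
# order (x, y, z); voxel indices are 0-based in every exported interface and
# boxes follow the half-open [lower, upper) convention.

setClassUnion("ArrayOrNULL", c("array", "NULL"))

#' LabelScheme: a named, ordered class taxonomy for label maps
#'
#' Three canonical schemes exist. \code{coarse} has 10 classes: background
#' plus facial soft tissue, upper skull, mandible, cervical vertebra, hyoid,
#' pharyngeal cavity, inferior alveolar nerve, upper teeth, lower teeth.
#' \code{fine} has 33 classes: background plus the 32 FDI tooth codes
#' (11..18, 21..28, 31..38, 41..48 map to ids 1..32 in ascending FDI order).
#' \code{parity} has 5 classes: background plus upper-odd, upper-even,
#' lower-odd, lower-even tooth groups. Class id 0 is always background.
#'
#' @slot name scheme name, one of "coarse", "fine", "parity"
#' @slot ids integer class ids, starting at 0
#' @slot labels human-readable class labels, parallel to \code{ids}
#' @export
setClass("LabelScheme",
  representation(name = "character", ids = "integer", labels = "character"))

setValidity("LabelScheme", function(object) {
  msg <- character()
  if (!(object@name %in% c("coarse", "fine", "parity")))
    msg <- c(msg, "scheme name must be one of 'coarse', 'fine', 'parity'")
  if (length(object@ids) != length(object@labels))
    msg <- c(msg, "ids and labels must have equal length")
  if (length(object@ids) && object@ids[1L] != 0L)
    msg <- c(msg, "class id 0 (background) must come first")
  expected <- c(coarse = 10L, fine = 33L, parity = 5L)[object@name]
  if (!is.na(expected) && length(object@ids) != expected)
    msg <- c(msg, sprintf("scheme '%s' must have exactly %d classes",
                          object@name, expected))
  if (anyDuplicated(object@ids)) msg <- c(msg, "class ids must be unique")
  if (length(msg)) msg else TRUE
})

#' CTVolume: a 3D scalar image with voxel geometry
#'
#' @slot data 3D numeric array of voxel intensities (CT-like arbitrary units)
#' @slot spacing voxel spacing (sx, sy, sz) in mm, all > 0
#' @slot transform 4x4 affine mapping 0-based voxel indices to world (mm)
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", transform = "matrix"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "volume data must have exactly 3 axes")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (!all(dim(object@transform) == c(4L, 4L)))
    msg <- c(msg, "transform must be a 4x4 matrix")
  else if (abs(det(object@transform)) < 1e-12)
    msg <- c(msg, "transform must be invertible")
  if (length(msg)) msg else TRUE
})

#' LabelMap: an integer segmentation on a volume grid
#'
#' @slot data 3D integer array; every value must be a class id of the scheme
#' @slot scheme the \linkS4class{LabelScheme} the ids refer to
#' @slot spacing voxel spacing in mm
#' @slot transform 4x4 voxel-to-world affine
#' @export
setClass("LabelMap",
  representation(data = "array", scheme = "LabelScheme",
                 spacing = "numeric", transform = "matrix"))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "label data must have exactly 3 axes")
  if (!is.integer(object@data))
    msg <- c(msg, "label data must be integer-typed")
  else {
    bad <- !(object@data %in% object@scheme@ids)
    if (any(bad))
      msg <- c(msg, sprintf(
        "%d voxel(s) carry ids not in scheme '%s' (e.g. %s)",
        sum(bad), object@scheme@name,
        paste(head(setdiff(unique(object@data[bad]), object@scheme@ids), 3L),
              collapse = ", ")))
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (!all(dim(object@transform) == c(4L, 4L)))
    msg <- c(msg, "transform must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' ProbabilityMap: per-class soft predictions on a volume grid
#'
#' Stored as a 4D array (x, y, z, class) whose per-voxel class vector lies on
#' the probability simplex (sums to 1 within 1e-6). Class order follows the
#' scheme's id order, so slice \code{[,,,1]} is background.
#'
#' @slot data 4D numeric array (x, y, z, class)
#' @slot scheme the \linkS4class{LabelScheme} indexing the class axis
#' @slot spacing voxel spacing in mm
#' @slot transform 4x4 voxel-to-world affine
#' @export
setClass("ProbabilityMap",
  representation(data = "array", scheme = "LabelScheme",
                 spacing = "numeric", transform = "matrix"))

setValidity("ProbabilityMap", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L)
    msg <- c(msg, "probability data must have 4 axes (x, y, z, class)")
  else if (d[4L] != length(object@scheme@ids))
    msg <- c(msg, "class axis must match the scheme's class count")
  else {
    rng <- range(object@data)
    if (rng[1L] < -1e-6 || rng[2L] > 1 + 1e-6)
      msg <- c(msg, "probabilities must lie in [0, 1]")
    sums <- rowSums(matrix(object@data, prod(d[1:3]), d[4L]))
    if (max(abs(sums - 1)) > 1e-6)
      msg <- c(msg, "per-voxel class probabilities must sum to 1 within 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' ROIBox: a half-open axis-aligned crop box with a resample target
#'
#' @slot lower 0-based inclusive lower corner (voxels)
#' @slot upper 0-based exclusive upper corner (voxels)
#' @slot sourceShape shape of the grid the box indexes into
#' @slot targetShape shape the cropped block is resampled to
#' @export
setClass("ROIBox",
  representation(lower = "integer", upper = "integer",
                 sourceShape = "integer", targetShape = "integer"))

setValidity("ROIBox", function(object) {
  msg <- character()
  for (s in c("lower", "upper", "sourceShape", "targetShape"))
    if (length(slot(object, s)) != 3L)
      msg <- c(msg, sprintf("%s must have length 3", s))
  if (!length(msg)) {
    if (any(object@upper <= object@lower))
      msg <- c(msg, "box must satisfy lower < upper on every axis")
    if (any(object@lower < 0L) || any(object@upper > object@sourceShape))
      msg <- c(msg, "box must lie within the source grid")
    if (any(object@targetShape < 1L))
      msg <- c(msg, "target shape must be positive on every axis")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: generation parameters for synthetic CMF phantoms
#'
#' Geometry is in voxel units on the stated grid; intensities are CT-like
#' arbitrary units chosen to preserve the contrast ordering a CT segmenter
#' exploits (air < soft tissue < bone < teeth < bracket metal).
#'
#' @slot shape grid shape in voxels, each axis >= 32
#' @slot spacing voxel spacing in mm
#' @slot skullRadii ellipsoid semi-axes of the cranial shell (voxels)
#' @slot skullThickness shell thickness (voxels)
#' @slot mandibleRadii (major-x, major-y) radii of the mandibular arch
#' @slot mandibleTube tube radius of the mandibular arch body
#' @slot vertebraCount number of cervical vertebral bodies in the stack
#' @slot vertebraRadius cylinder radius of a vertebral body
#' @slot pharynxRadius radius of the pharyngeal airway tube
#' @slot nerveRadius radius of the inferior alveolar nerve canals
#'   (deliberately thin so the difficulty of tubular structures is kept)
#' @slot hyoidRadius tube radius of the hyoid arc (deliberately thin)
#' @slot teethPerQuadrant teeth placed per FDI quadrant, 0..8
#' @slot toothRadius tooth cylinder radius (voxels)
#' @slot toothHeight tooth height (voxels)
#' @slot missingProb probability a tooth is absent; either one value for all
#'   teeth or a vector of 32 values named by FDI code
#' @slot intensities named means: softTissue, bone, tooth, bracket, air
#' @slot noiseSigma additive Gaussian noise standard deviation
#' @slot bracketProb probability a present tooth carries a metal bracket
#' @slot streakAmplitude amplitude of radial metal-streak artifacts
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 skullRadii = "numeric", skullThickness = "numeric",
                 mandibleRadii = "numeric", mandibleTube = "numeric",
                 vertebraCount = "integer", vertebraRadius = "numeric",
                 pharynxRadius = "numeric", nerveRadius = "numeric",
                 hyoidRadius = "numeric",
                 teethPerQuadrant = "integer", toothRadius = "numeric",
                 toothHeight = "numeric", toothGap = "numeric",
                 missingProb = "numeric", intensities = "numeric",
                 noiseSigma = "numeric", bracketProb = "numeric",
                 streakAmplitude = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 32L))
    msg <- c(msg, "grid shape must be >= 32 voxels on every axis")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  radii <- c(object@skullRadii, object@skullThickness, object@mandibleRadii,
             object@mandibleTube, object@vertebraRadius, object@pharynxRadius,
             object@nerveRadius, object@hyoidRadius, object@toothRadius,
             object@toothHeight)
  if (any(radii <= 0)) msg <- c(msg, "all structure radii must be positive")
  if (object@teethPerQuadrant < 0L || object@teethPerQuadrant > 8L)
    msg <- c(msg, "teethPerQuadrant must be in [0, 8]")
  if (!(length(object@missingProb) %in% c(1L, 32L)))
    msg <- c(msg, "missingProb must have length 1 or 32")
  if (any(object@missingProb < 0 | object@missingProb > 1))
    msg <- c(msg, "missingProb values must lie in [0, 1]")
  if (object@bracketProb < 0 || object@bracketProb > 1)
    msg <- c(msg, "bracketProb must lie in [0, 1]")
  need <- c("softTissue", "bone", "tooth", "bracket", "air")
  if (!all(need %in% names(object@intensities)))
    msg <- c(msg, paste("intensities must name:", paste(need, collapse = ", ")))
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomSample: a generated phantom with its ground truth
#'
#' @slot volume the CT-like \linkS4class{CTVolume}
#' @slot coarse coarse-scheme \linkS4class{LabelMap} (10 classes)
#' @slot fine fine-scheme \linkS4class{LabelMap} (33 classes)
#' @slot spec the \linkS4class{PhantomSpec} used
#' @slot seed the generation seed
#' @slot placements per-tooth placement record: FDI code, presence, centroid
#'   (0-based voxels) and arch angle, used for arch-ordering audits
#' @export
setClass("PhantomSample",
  representation(volume = "CTVolume", coarse = "LabelMap", fine = "LabelMap",
                 spec = "PhantomSpec", seed = "integer",
                 placements = "data.frame"))

setValidity("PhantomSample", function(object) {
  msg <- character()
  dv <- dim(object@volume@data)
  if (!all(dv == dim(object@coarse@data)) || !all(dv == dim(object@fine@data)))
    msg <- c(msg, "volume, coarse and fine grids must share one shape")
  if (length(msg)) msg else TRUE
})

#' BackboneConfig: configuration of a volumetric segmenter family
#'
#' @slot family one of "residual_unet", "dynamic_unet", "large_kernel_unet"
#' @slot inChannels image input channels (1 for CT)
#' @slot nClasses per-head class counts; length 1 for a single-head coarse
#'   model, \code{c(33, 5)} for the dual-head fine model
#' @slot depth encoder levels (>= 2)
#' @slot baseWidth channels at the finest level (>= 4)
#' @slot kernelSize spatial-mixing kernel of the large-kernel family
#'   (odd, >= 5; ignored by the other families)
#' @slot normalization "instance" or "none"
#' @slot activation "relu" or "leakyrelu"
#' @export
setClass("BackboneConfig",
  representation(family = "character", inChannels = "integer",
                 nClasses = "integer", depth = "integer",
                 baseWidth = "integer", kernelSize = "integer",
                 normalization = "character", activation = "character"))

setValidity("BackboneConfig", function(object) {
  msg <- character()
  fams <- c("residual_unet", "dynamic_unet", "large_kernel_unet")
  if (!(object@family %in% fams))
    msg <- c(msg, paste0("unknown family '", object@family, "'; expected one of ",
                         paste(fams, collapse = ", ")))
  if (object@depth < 2L) msg <- c(msg, "depth must be >= 2")
  if (object@baseWidth < 4L) msg <- c(msg, "baseWidth must be >= 4")
  if (any(object@nClasses < 2L)) msg <- c(msg, "every head needs >= 2 classes")
  if (!(length(object@nClasses) %in% c(1L, 2L)))
    msg <- c(msg, "nClasses must describe 1 or 2 heads")
  if (object@family == "large_kernel_unet" &&
      (object@kernelSize < 5L || object@kernelSize %% 2L == 0L))
    msg <- c(msg, "large-kernel size must be odd and >= 5")
  if (!(object@normalization %in% c("instance", "none")))
    msg <- c(msg, "normalization must be 'instance' or 'none'")
  if (!(object@activation %in% c("relu", "leakyrelu")))
    msg <- c(msg, "activation must be 'relu' or 'leakyrelu'")
  if (length(msg)) msg else TRUE
})

#' Segmenter: a trainable volumetric segmentation model
#'
#' Holds the network parameters of one backbone family together with its
#' \linkS4class{BackboneConfig}. The forward contract: a single-channel
#' patch of shape s^3 maps to per-class probabilities of shape (s^3, classes)
#' per head, simplex-normalized per voxel.
#'
#' @slot config the \linkS4class{BackboneConfig}
#' @slot params nested list of parameter arrays
#' @slot trained logical training-state flag
#' @slot seed initialization seed
#' @export
setClass("Segmenter",
  representation(config = "BackboneConfig", params = "list",
                 trained = "logical", seed = "integer"))

#' CascadeResult: output of the two-stage coarse-to-fine pipeline
#'
#' Fine tooth voxels are not forced inside coarse tooth voxels; the stages
#' may disagree and the disagreement fraction is kept as a diagnostic.
#'
#' @slot coarse coarse \linkS4class{LabelMap} on the full grid
#' @slot fine fine \linkS4class{LabelMap} on the full grid (background
#'   outside the ROI)
#' @slot roi the dentition \linkS4class{ROIBox}
#' @slot coarseProb optional retained coarse probability data
#' @slot fineProb optional retained fine (33-class) ROI probability data
#' @slot disagreement fraction of fine tooth voxels outside the coarse
#'   tooth foreground
#' @slot roiFallback TRUE when no dentition was found and the whole-volume
#'   ROI fallback was taken
#' @export
setClass("CascadeResult",
  representation(coarse = "LabelMap", fine = "LabelMap", roi = "ROIBox",
                 coarseProb = "ArrayOrNULL", fineProb = "ArrayOrNULL",
                 disagreement = "numeric", roiFallback = "logical"))

#' EnsembleWeights: AdaBoost-style vote weights for ensemble fusion
#'
#' For each model t, \code{alpha[t] = 0.5 * log((1 - epsilon[t]) / epsilon[t])}
#' exactly; normalized weights \code{w = alpha / sum(alpha)} when
#' \code{sum(alpha) > 0}, uniform otherwise.
#'
#' @slot epsilon per-model clipped error rates
#' @slot alpha per-model vote weights from the AdaBoost closed form
#' @slot w normalized fusion weights (sum to 1)
#' @slot order model indices in boosting order (descending unweighted Dice)
#' @slot sampleIds calibration sample identifiers
#' @slot sampleWeights final boosting weights over calibration samples
#' @slot rule misclassification rule settings (Dice threshold, clip bounds)
#' @export
setClass("EnsembleWeights",
  representation(epsilon = "numeric", alpha = "numeric", w = "numeric",
                 order = "integer", sampleIds = "character",
                 sampleWeights = "numeric", rule = "list"))

setValidity("EnsembleWeights", function(object) {
  msg <- character()
  n <- length(object@epsilon)
  if (length(object@alpha) != n || length(object@w) != n)
    msg <- c(msg, "epsilon, alpha and w must have equal length")
  if (any(object@epsilon <= 0) || any(object@epsilon > 0.5 + 1e-12))
    msg <- c(msg, "epsilon must lie in (0, 0.5] after clipping")
  expected <- 0.5 * log((1 - object@epsilon) / object@epsilon)
  if (n && max(abs(object@alpha - expected)) > 1e-12)
    msg <- c(msg, "alpha must equal 0.5*log((1-eps)/eps)")
  if (n && (any(object@w < 0) || abs(sum(object@w) - 1) > 1e-9))
    msg <- c(msg, "w must be nonnegative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' GradeReport: four-grade segmentation quality rubric
#'
#' The overall grade is "A" only if every category is "A"; otherwise it is
#' the worst category grade. Automated Dice thresholds stand in for human
#' grading and are clearly a proxy.
#'
#' @slot grades per-category grades, named, each in A/B/C/D
#' @slot overall the overall grade
#' @slot thresholds named Dice cut-offs c(A = , B = , C = )
#' @export
setClass("GradeReport",
  representation(grades = "character", overall = "character",
                 thresholds = "numeric"))

#' FineLossConfig: weights of the dual-head fine-stage loss
#'
#' The fine-stage training objective is
#' \code{lambda1 * Ldice(p33, G33) + lambda2 * Ldice(p5, G5)} where the
#' 33-class head carries individual FDI teeth and the 5-class head carries
#' the jaw/parity groups.
#'
#' @slot lambda1 weight of the 33-class Dice term (>= 0)
#' @slot lambda2 weight of the 5-class Dice term (>= 0)
#' @slot smooth smoothing constant of the soft Dice ratio (> 0)
#' @export
setClass("FineLossConfig",
  representation(lambda1 = "numeric", lambda2 = "numeric", smooth = "numeric"))

setValidity("FineLossConfig", function(object) {
  msg <- character()
  if (object@lambda1 < 0 || object@lambda2 < 0)
    msg <- c(msg, "lambda1 and lambda2 must be >= 0")
  if (object@lambda1 + object@lambda2 <= 0)
    msg <- c(msg, "lambda1 + lambda2 must be > 0")
  if (object@smooth <= 0) msg <- c(msg, "smooth must be > 0")
  if (length(msg)) msg else TRUE
})

#' TrainConfig: training-loop hyperparameters
#'
#' @slot epochs training epochs (>= 1)
#' @slot batchSize patches per gradient step (>= 1)
#' @slot lr learning rate (> 0)
#' @slot momentum SGD momentum coefficient
#' @slot optimizer optimizer name: "adam" (default) or "sgd" (momentum SGD)
#' @slot patchSize cubic training patch edge (must be divisible by
#'   2^(depth-1) of the model trained)
#' @slot patchesPerSample random patches drawn per sample per epoch
#' @slot ceWeight weight of the auxiliary voxel-wise cross-entropy term in
#'   the training objective (0 trains on the pure Dice loss)
#' @slot balancedSampling centre half of the training patches on a random
#'   voxel of a randomly chosen present foreground class
#' @slot augment random flip augmentation along x
#' @slot seed training seed
#' @slot fold cross-validation fold index (bookkeeping only)
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer", lr = "numeric",
                 momentum = "numeric", optimizer = "character",
                 patchSize = "integer", patchesPerSample = "integer",
                 ceWeight = "numeric", balancedSampling = "logical",
                 augment = "logical", seed = "integer", fold = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@lr <= 0) msg <- c(msg, "learning rate must be > 0")
  if (!(object@optimizer %in% c("adam", "sgd")))
    msg <- c(msg, "optimizer must be 'adam' or 'sgd'")
  if (length(msg)) msg else TRUE
})

#' PipelineConfig: validated end-to-end pipeline configuration
#'
#' @slot phantom phantom-generator settings
#' @slot backbones list of three backbone settings
#' @slot training training hyperparameter settings
#' @slot lambda1,lambda2 fine-loss weights (lambda1, lambda2 >= 0, sum > 0)
#' @slot roiMargin dentition ROI dilation margin in voxels (>= 0)
#' @slot fineTargetShape cubic grid edge the dentition ROI is resampled to
#'   for the fine stage
#' @slot tau correction confidence threshold in [0, 1]
#' @slot epsClip AdaBoost error-rate clip bounds inside (0, 1)
#' @slot diceThreshold per-sample mean-Dice misclassification threshold D*
#' @slot gradeThresholds named Dice cut-offs c(A = , B = , C = )
#' @slot seed global random seed
#' @export
setClass("PipelineConfig",
  representation(phantom = "list", backbones = "list", training = "list",
                 lambda1 = "numeric", lambda2 = "numeric",
                 roiMargin = "numeric", fineTargetShape = "integer",
                 tau = "numeric",
                 epsClip = "numeric", diceThreshold = "numeric",
                 gradeThresholds = "numeric", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@lambda1 < 0 || object@lambda2 < 0)
    msg <- c(msg, "lambda1 and lambda2 must be >= 0")
  if (object@lambda1 + object@lambda2 <= 0)
    msg <- c(msg, "lambda1 + lambda2 must be > 0")
  if (object@tau < 0 || object@tau > 1)
    msg <- c(msg, "tau must lie in [0, 1]")
  if (object@roiMargin < 0) msg <- c(msg, "roiMargin must be >= 0")
  if (length(object@fineTargetShape) != 1L || object@fineTargetShape < 8L)
    msg <- c(msg, "fineTargetShape must be a single edge length >= 8")
  if (length(object@epsClip) != 2L || any(object@epsClip <= 0) ||
      any(object@epsClip >= 1) || object@epsClip[1L] >= object@epsClip[2L])
    msg <- c(msg, "epsClip must be increasing bounds inside (0, 1)")
  th <- object@gradeThresholds
  if (!all(c("A", "B", "C") %in% names(th)) ||
      !(th["A"] > th["B"] && th["B"] > th["C"]))
    msg <- c(msg, "gradeThresholds must satisfy A > B > C")
  if (length(msg)) msg else TRUE
})
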