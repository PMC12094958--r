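# NIfTI-1 I/O for volumes and label maps, plus pipeline configuration.
# The on-disk format is .nii/.nii.gz; label maps carry a sidecar JSON file
# recording the label scheme. DICOM ingestion is out of scope: the synthetic
# workflow never needs it.

.niftiGeometry <- function(img) {
  xf <- RNifti::xform(img)
  transform <- matrix(as.numeric(xf), 4L, 4L)
  list(spacing = as.numeric(RNifti::pixdim(img))[1:3], transform = transform)
}

.asNiftiWithGeometry <- function(data, spacing, transform) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  aff <- structure(transform, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  img
}

#' Read a volume from a NIfTI file
#'
#' @param path path to a .nii or .nii.gz file
#' @return a \linkS4class{CTVolume} with spacing and voxel-to-world
#'   transform taken from the file header; voxel values unmodified
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    .stopWith("notFoundError", "file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    .stopWith("formatError", "cannot read '%s': %s",
                              path, conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) { img <- img[, , , 1L]; d <- dim(img) }
  if (length(d) != 3L)
    .stopWith("formatError", "'%s' is not a 3D volume (found %d axes)",
              path, length(d))
  geom <- .niftiGeometry(img)
  newVolume(array(as.numeric(img), d), geom$spacing, geom$transform)
}

#' Write a volume to a NIfTI file
#'
#' @param volume a \linkS4class{CTVolume}
#' @param path output path (.nii or .nii.gz)
#' @return \code{path}, invisibly
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  img <- .asNiftiWithGeometry(volume@data, volume@spacing, volume@transform)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".scheme.json")
}

#' Write a label map to a NIfTI file with a scheme sidecar
#'
#' The voxel ids are stored integer-typed and round-trip exactly; the scheme
#' name is recorded in a JSON sidecar next to the image
#' (\code{<stem>.scheme.json}). The map is validated against its scheme
#' before anything is written.
#'
#' @param labels a \linkS4class{LabelMap}
#' @param path output path (.nii or .nii.gz)
#' @return \code{path}, invisibly
#' @export
writeLabelMap <- function(labels, path) {
  stopifnot(is(labels, "LabelMap"))
  validObject(labels)
  img <- .asNiftiWithGeometry(labels@data, labels@spacing, labels@transform)
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(
    list(scheme = labels@scheme@name,
         classes = data.frame(id = labels@scheme@ids,
                              label = labels@scheme@labels)),
    .sidecarPath(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a label map written by \code{writeLabelMap}
#'
#' @param path path to the NIfTI file; the scheme is taken from the JSON
#'   sidecar unless \code{scheme} is given
#' @param scheme optional scheme name or \linkS4class{LabelScheme} override
#' @return a \linkS4class{LabelMap}
#' @export
readLabelMap <- function(path, scheme = NULL) {
  if (!file.exists(path))
    .stopWith("notFoundError", "file not found: %s", path)
  if (is.null(scheme)) {
    sc <- .sidecarPath(path)
    if (!file.exists(sc))
      .stopWith("formatError",
                "no scheme sidecar at '%s'; pass `scheme` explicitly", sc)
    scheme <- jsonlite::read_json(sc)$scheme
  }
  if (is.character(scheme)) scheme <- labelScheme(scheme)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    .stopWith("formatError", "'%s' is not a 3D label map", path)
  geom <- .niftiGeometry(img)
  newLabelMap(array(as.integer(img), dim(img)), scheme,
              geom$spacing, geom$transform)
}

# ---------------------------------------------------------------------------
# Pipeline configuration

.configDefaults <- function() {
  list(
    phantom = list(shape = 64L, spacing = 1.0, teethPerQuadrant = 8L,
                   missingProb = 0.0, noiseSigma = 30.0, bracketProb = 0.0,
                   streakAmplitude = 150.0),
    backbones = list(
      list(family = "residual_unet", depth = 3L, baseWidth = 8L),
      list(family = "dynamic_unet", depth = 3L, baseWidth = 8L),
      list(family = "large_kernel_unet", depth = 3L, baseWidth = 8L,
           kernelSize = 5L)),
    training = list(epochs = 4L, batchSize = 1L, lr = 0.05, momentum = 0.9,
                    optimizer = "sgd", patchSize = 32L,
                    patchesPerSample = 4L, augment = FALSE),
    lambda1 = 0.5, lambda2 = 0.5,
    roiMargin = 3L, fineTargetShape = 64L, tau = 0.6,
    epsClip = c(1e-4, 0.5), diceThreshold = 0.95,
    gradeThresholds = c(A = 0.95, B = 0.90, C = 0.80),
    seed = 42L)
}

.checkKnownKeys <- function(user, defaults, prefix = "") {
  if (!is.list(user)) return(invisible(TRUE))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    .stopWith("validationError", "unknown config key(s): %s",
              paste0(prefix, unknown, collapse = ", "))
  for (nm in names(user))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      .checkKnownKeys(user[[nm]], defaults[[nm]], paste0(prefix, nm, "."))
  invisible(TRUE)
}

#' Load and validate the pipeline configuration
#'
#' Reads a YAML configuration file, fills unset keys with the documented
#' defaults, rejects unknown keys by name, and validates every invariant
#' (loss weights lambda1, lambda2 >= 0 with positive sum — default 0.5/0.5;
#' tau in [0,1], default 0.6; ROI margin >= 0, default 3; AdaBoost error
#' clip bounds inside (0,1)).
#'
#' @param path path to a YAML file, or NULL for the full default config
#' @return a validated \linkS4class{PipelineConfig}
#' @export
loadPipelineConfig <- function(path = NULL) {
  defaults <- .configDefaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      .stopWith("notFoundError", "config file not found: %s", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    .checkKnownKeys(user, defaults)
  }
  cfg <- modifyList(defaults, user)
  gth <- unlist(cfg$gradeThresholds)
  if (is.null(names(gth)) || !any(nzchar(names(gth))))
    names(gth) <- c("A", "B", "C")
  tryCatch(
    new("PipelineConfig",
        phantom = cfg$phantom, backbones = cfg$backbones,
        training = cfg$training,
        lambda1 = as.numeric(cfg$lambda1),
        lambda2 = as.numeric(cfg$lambda2),
        roiMargin = as.numeric(cfg$roiMargin),
        fineTargetShape = as.integer(cfg$fineTargetShape),
        tau = as.numeric(cfg$tau),
        epsClip = as.numeric(unlist(cfg$epsClip)),
        diceThreshold = as.numeric(cfg$diceThreshold),
        gradeThresholds = gth,
        seed = as.integer(cfg$seed)),
    error = function(e)
      .stopWith("validationError", "invalid configuration: %s",
                conditionMessage(e)))
}
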