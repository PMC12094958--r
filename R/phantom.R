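# Synthetic CMF phantom generator. Structures are analytic solids
# (ellipsoid shells, elliptical-arc tubes, cylinders, capped tooth columns)
# rasterized onto the voxel grid, which keeps generation cheap and the
# ground truth exact. Axis convention: x left-right, y anterior(low) to
# posterior(high), z inferior(low) to superior(high).

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Construct a phantom specification
#'
#' Geometry defaults are tuned for a 64-voxel cube at 1 mm isotropic
#' spacing and scale proportionally with the grid; any argument can be
#' overridden. Intensity defaults (soft tissue 40, bone 700, teeth 1200,
#' bracket 3000, air -900; noise sigma 30) preserve the contrast ordering a
#' CT segmenter relies on. The hyoid and the nerve canals are deliberately
#' thin (radius <= 2 voxels) so the difficulty of tubular structures is
#' present in the synthetic data.
#'
#' @param shape grid shape (scalar or length 3), every axis >= 32
#' @param spacing voxel spacing in mm
#' @param teethPerQuadrant teeth per FDI quadrant, 0..8
#' @param missingProb per-tooth absence probability (length 1, or 32 in
#'   ascending FDI order)
#' @param noiseSigma additive Gaussian noise sd
#' @param bracketProb probability a present tooth carries a metal bracket
#' @param streakAmplitude metal-streak artifact amplitude
#' @param ... overrides for the geometric slots of
#'   \linkS4class{PhantomSpec} (skullRadii, mandibleRadii, toothRadius, ...)
#' @return a validated \linkS4class{PhantomSpec}
#' @examples
#' spec <- phantomSpec(shape = 64, missingProb = 0)
#' @export
phantomSpec <- function(shape = 64L, spacing = 1.0, teethPerQuadrant = 8L,
                        missingProb = 0.0, noiseSigma = 30.0,
                        bracketProb = 0.0, streakAmplitude = 150.0, ...) {
  shape <- as.integer(rep(shape, length.out = 3L))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  s <- min(shape) / 64                       # proportional geometry scale
  geo <- list(skullRadii = s * c(18, 20, 15), skullThickness = s * 3,
              mandibleRadii = s * c(13, 15), mandibleTube = s * 3,
              vertebraCount = 3L, vertebraRadius = s * 5,
              pharynxRadius = s * 2.5, nerveRadius = max(1, s * 1.2),
              hyoidRadius = max(1, s * 1.4),
              toothRadius = max(1.4, s * 1.8), toothHeight = s * 6,
              toothGap = s * 1.0)
  geo <- modifyList(geo, list(...))
  obj <- new("PhantomSpec", shape = shape, spacing = spacing,
             skullRadii = geo$skullRadii, skullThickness = geo$skullThickness,
             mandibleRadii = geo$mandibleRadii, mandibleTube = geo$mandibleTube,
             vertebraCount = as.integer(geo$vertebraCount),
             vertebraRadius = geo$vertebraRadius,
             pharynxRadius = geo$pharynxRadius, nerveRadius = geo$nerveRadius,
             hyoidRadius = geo$hyoidRadius,
             teethPerQuadrant = as.integer(teethPerQuadrant),
             toothRadius = geo$toothRadius, toothHeight = geo$toothHeight,
             toothGap = geo$toothGap,
             missingProb = as.numeric(missingProb),
             intensities = c(softTissue = 40, bone = 700, tooth = 1200,
                             bracket = 3000, air = -900),
             noiseSigma = as.numeric(noiseSigma),
             bracketProb = as.numeric(bracketProb),
             streakAmplitude = as.numeric(streakAmplitude))
  validObject(obj)
  obj
}

# dental-arch layout shared by the generator and the correction stage:
# angle 0 is the anterior midline, negative angles are patient-right
# (FDI quadrants 1 and 4), position |angle| grows toward the molars.
.archAngles <- function() {
  pos <- (seq_len(8L) - 0.5) * (100 / 8) * pi / 180   # 6.25..93.75 degrees
  list(q1 = -pos, q2 = pos, q3 = pos, q4 = -pos)
}

# radial coordinates of grid points about an arch centre
.archPolar <- function(X, Y, cx, cy) {
  list(phi = atan2(X - cx, -(Y - cy)),                 # 0 at anterior midline
       rho = sqrt((X - cx)^2 + (Y - cy)^2))
}

# radius of the ellipse (a, b) at arch angle phi
.archRadius <- function(phi, a, b) {
  a * b / sqrt((b * sin(phi))^2 + (a * cos(phi))^2)
}

.phantomLayout <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  sh <- spec@shape
  c0 <- (sh - 1) / 2
  s <- min(sh) / 64
  list(cx = c0[1L], cy = c0[2L], s = s,
       softCenter = c(c0[1L], c0[2L], c0[3L] + 2 * s),
       softRadii = c(0.42, 0.42, 0.47) * sh,
       skullCenter = c(c0[1L], c0[2L], c0[3L] + 10 * s),
       skullZmin = c0[3L] + 4 * s,
       mandZ = c(12, 20) * s, mandCenterY = c0[2L] + 2 * s,
       upperArch = list(a = 14 * s, b = 16 * s, cy = c0[2L] - 2 * s,
                        z0 = 27 * s, z1 = 27 * s + spec@toothHeight),
       lowerArch = list(a = 13 * s, b = 15 * s, cy = c0[2L] - 1 * s,
                        z0 = 25 * s - spec@toothHeight, z1 = 25 * s),
       vertCenter = c(c0[1L], c0[2L] + 22 * s), vertZ = c(4, 26) * s,
       pharynxCenter = c(c0[1L], c0[2L] + 12 * s), pharynxZ = c(6, 40) * s,
       hyoidCenter = c(c0[1L], c0[2L] + 6 * s), hyoidZ = 9 * s,
       hyoidRadii = c(8, 6) * s,
       nerveZ = 16 * s, nerveInset = 2 * s)
}

# centre (x, y, z) and arch angle of every FDI tooth for a spec
.toothCentres <- function(spec) {
  lay <- .phantomLayout(spec)
  ang <- .archAngles()
  out <- data.frame(fdi = fdiCodes())
  out$quadrant <- out$fdi %/% 10L
  out$position <- out$fdi %% 10L
  out$angle <- NA_real_; out$x <- NA_real_; out$y <- NA_real_
  out$z0 <- NA_real_; out$z1 <- NA_real_
  for (i in seq_len(nrow(out))) {
    q <- out$quadrant[i]; p <- out$position[i]
    a <- ang[[q]][p]
    arch <- if (q <= 2L) lay$upperArch else lay$lowerArch
    r <- .archRadius(a, arch$a, arch$b)
    out$angle[i] <- a
    out$x[i] <- lay$cx + r * sin(a)
    out$y[i] <- arch$cy - r * cos(a)
    out$z0[i] <- arch$z0
    out$z1[i] <- arch$z1
  }
  out
}

#' Generate a synthetic CMF phantom
#'
#' Deterministically rasterizes a soft-tissue envelope, cranial shell,
#' mandibular arch, cervical vertebral column, hyoid arc, pharyngeal airway,
#' bilateral inferior alveolar nerve canals and up to 32 FDI-numbered teeth
#' in two dental arches; assigns CT-like intensities plus Gaussian noise;
#' and returns the volume with exact coarse (10-class) and fine (33-class)
#' ground-truth label maps. A pure function of \code{(spec, seed)}.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param seed integer generation seed
#' @return a \linkS4class{PhantomSample}
#' @examples
#' p <- generatePhantom(phantomSpec(missingProb = 0), seed = 1)
#' table(voxels(p@coarse))[1:4]
#' @export
generatePhantom <- function(spec, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  seed <- as.integer(seed)
  sh <- spec@shape
  lay <- .phantomLayout(spec)

  # capacity checks: every structure must fit the grid
  if (any(lay$softRadii * 2 > sh))
    .stopWith("capacityError", "grid too small for the soft-tissue envelope")
  if (lay$skullCenter[3L] + spec@skullRadii[3L] > sh[3L])
    .stopWith("capacityError", "grid too small for the skull shell")
  archMax <- max(lay$upperArch$a, lay$upperArch$b,
                 lay$lowerArch$a, lay$lowerArch$b) + spec@toothRadius
  if (2 * archMax + 4 > min(sh[1:2]))
    .stopWith("capacityError", "grid too small for the dental arches")

  X <- array(rep(seq_len(sh[1L]) - 1, times = prod(sh[2:3])), sh)
  Y <- array(rep(rep(seq_len(sh[2L]) - 1, each = sh[1L]), times = sh[3L]), sh)
  Z <- array(rep(seq_len(sh[3L]) - 1, each = prod(sh[1:2])), sh)

  coarse <- array(0L, sh)

  # 1 facial soft tissue: ellipsoid envelope
  sc <- lay$softCenter; sr <- lay$softRadii
  soft <- ((X - sc[1L]) / sr[1L])^2 + ((Y - sc[2L]) / sr[2L])^2 +
    ((Z - sc[3L]) / sr[3L])^2 <= 1
  coarse[soft] <- 1L

  # 4 cervical vertebra: one continuous column with per-body bulges so the
  # class stays a single connected component
  vz <- seq(lay$vertZ[1L], lay$vertZ[2L], length.out = spec@vertebraCount + 1L)
  bulge <- 0.75 + 0.25 * abs(cos(pi * spec@vertebraCount *
                                   (Z - lay$vertZ[1L]) /
                                   max(1, diff(lay$vertZ))))
  vert <- (X - lay$vertCenter[1L])^2 + (Y - lay$vertCenter[2L])^2 <=
    (spec@vertebraRadius * bulge)^2 &
    Z >= lay$vertZ[1L] & Z <= lay$vertZ[2L]
  coarse[vert & soft] <- 4L

  # 2 upper skull: upper cap of an ellipsoid shell
  kc <- lay$skullCenter; kr <- spec@skullRadii
  q <- ((X - kc[1L]) / kr[1L])^2 + ((Y - kc[2L]) / kr[2L])^2 +
    ((Z - kc[3L]) / kr[3L])^2
  inner <- (kr - spec@skullThickness) / kr
  skull <- q <= 1 & q >= min(inner)^2 & Z >= lay$skullZmin
  coarse[skull] <- 2L

  # 6 pharyngeal cavity: air tube
  phar <- (X - lay$pharynxCenter[1L])^2 + (Y - lay$pharynxCenter[2L])^2 <=
    spec@pharynxRadius^2 & Z >= lay$pharynxZ[1L] & Z <= lay$pharynxZ[2L]
  coarse[phar & soft] <- 6L

  # 3 mandible: elliptical arch tube
  mp <- .archPolar(X, Y, lay$cx, lay$mandCenterY)
  mandR <- .archRadius(mp$phi, spec@mandibleRadii[1L], spec@mandibleRadii[2L])
  mand <- abs(mp$rho - mandR) <= spec@mandibleTube &
    abs(mp$phi) <= 110 * pi / 180 &
    Z >= lay$mandZ[1L] & Z <= lay$mandZ[2L]
  coarse[mand] <- 3L

  # 5 hyoid: thin anterior arc below the mandible
  hp <- .archPolar(X, Y, lay$cx, lay$hyoidCenter[2L])
  hyR <- .archRadius(hp$phi, lay$hyoidRadii[1L], lay$hyoidRadii[2L])
  hyoid <- abs(hp$rho - hyR) <= spec@hyoidRadius &
    abs(hp$phi) <= 80 * pi / 180 & abs(Z - lay$hyoidZ) <= spec@hyoidRadius
  coarse[hyoid] <- 5L

  # 7 inferior alveolar nerve: thin bilateral canals inside the mandible
  nerve <- abs(mp$rho - (mandR - lay$nerveInset)) <= spec@nerveRadius &
    abs(mp$phi) >= 20 * pi / 180 & abs(mp$phi) <= 100 * pi / 180 &
    abs(Z - lay$nerveZ) <= spec@nerveRadius
  coarse[nerve & mand] <- 7L

  # teeth: decide presence, then rasterize capped columns
  centres <- .toothCentres(spec)
  mprob <- if (length(spec@missingProb) == 1L)
    rep(spec@missingProb, 32L) else spec@missingProb
  sample_ <- .withSeed(seed, list(missing = runif(32L) < mprob,
                                  noise = rnorm(prod(sh), 0, spec@noiseSigma)))
  centres$present <- !sample_$missing &
    centres$position <= spec@teethPerQuadrant
  fine <- array(0L, sh)
  for (i in seq_len(nrow(centres))) {
    if (!centres$present[i]) next
    ci <- centres[i, ]
    tooth <- (X - ci$x)^2 + (Y - ci$y)^2 <= spec@toothRadius^2 &
      Z >= ci$z0 & Z <= ci$z1
    if (!any(tooth))
      .stopWith("capacityError", "grid too small to place tooth FDI %d",
                ci$fdi)
    fine[tooth] <- fdiToFineId(ci$fdi)
    coarse[tooth] <- if (ci$quadrant <= 2L) .COARSE_UPPER_TEETH else
      .COARSE_LOWER_TEETH
  }

  inten <- spec@intensities
  lut <- c(-1000, inten[["softTissue"]], rep(inten[["bone"]], 4L),
           inten[["air"]], inten[["softTissue"]] + 20,
           rep(inten[["tooth"]], 2L))
  vol <- array(lut[coarse + 1L] + sample_$noise, sh)

  placements <- centres[, c("fdi", "quadrant", "position", "present",
                            "angle", "x", "y", "z0", "z1")]
  transform <- diag(c(spec@spacing, 1))
  new("PhantomSample",
      volume = newVolume(vol, spec@spacing, transform),
      coarse = newLabelMap(coarse, labelScheme("coarse"), spec@spacing,
                           transform),
      fine = newLabelMap(fine, labelScheme("fine"), spec@spacing, transform),
      spec = spec, seed = seed, placements = placements)
}

#' Add metal-bracket artifacts to a phantom volume
#'
#' With bracket probability p per present tooth, attaches a high-intensity
#' metal blob to the tooth's buccal (arch-outward) face and adds radial
#' streaks of the configured amplitude in the bracket's axial plane.
#' Deterministic per seed; label maps are never modified.
#'
#' @param volume the phantom \linkS4class{CTVolume}
#' @param fine the matching fine \linkS4class{LabelMap}
#' @param spec the \linkS4class{PhantomSpec} (bracketProb, streakAmplitude)
#' @param seed integer seed
#' @return a new \linkS4class{CTVolume} with artifacts added
#' @export
addArtifacts <- function(volume, fine, spec, seed = 1L) {
  stopifnot(is(volume, "CTVolume"), is(fine, "LabelMap"),
            is(spec, "PhantomSpec"))
  .checkSameGrid(volume, fine, "volume and fine labels")
  if (spec@bracketProb <= 0) return(volume)
  sh <- dim(volume@data)
  lay <- .phantomLayout(spec)
  ids <- setdiff(sort(unique(as.vector(fine@data))), 0L)
  if (!length(ids)) return(volume)
  draw <- .withSeed(seed, runif(32L))
  out <- volume@data
  X <- array(rep(seq_len(sh[1L]) - 1, times = prod(sh[2:3])), sh)
  Y <- array(rep(rep(seq_len(sh[2L]) - 1, each = sh[1L]), times = sh[3L]), sh)
  Z <- array(rep(seq_len(sh[3L]) - 1, each = prod(sh[1:2])), sh)
  centres <- .toothCentres(spec)
  for (id in ids) {
    if (draw[id] >= spec@bracketProb) next
    ci <- centres[centres$fdi == fineIdToFdi(id), ]
    arch <- if (ci$quadrant <= 2L) lay$upperArch else lay$lowerArch
    # outward unit direction from the arch centre through the tooth centre
    dx <- ci$x - lay$cx; dy <- ci$y - arch$cy
    nrm <- sqrt(dx^2 + dy^2)
    bx <- ci$x + dx / nrm * (spec@toothRadius + 1.6)
    by <- ci$y + dy / nrm * (spec@toothRadius + 1.6)
    bz <- (ci$z0 + ci$z1) / 2
    blob <- (X - bx)^2 + (Y - by)^2 + (Z - bz)^2 <= 1.25^2
    out[blob] <- spec@intensities[["bracket"]]
    # radial streaks in the bracket's axial plane
    band <- abs(Z - bz) <= 1
    phi <- atan2(Y - by, X - bx)
    r <- sqrt((X - bx)^2 + (Y - by)^2)
    streak <- spec@streakAmplitude * cos(8 * phi) * exp(-r / 12)
    out[band] <- out[band] + streak[band]
  }
  newVolume(out, volume@spacing, volume@transform)
}
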