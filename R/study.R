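# End-to-end desk-scale studies: shared drivers for the test suite and the
# acceptance script, so both run exactly the same computation.

#' Train the three backbone families and evaluate the fused ensemble
#'
#' Generates training and held-out phantoms, trains a coarse model per
#' family and a dual-head fine model per family (on ground-truth dentition
#' ROI crops), calibrates AdaBoost vote weights on the training phantoms,
#' and evaluates individual cascades and the fused ensemble on the
#' held-out phantoms.
#'
#' @param nTrain,nHold training and held-out phantom counts
#' @param seed master seed; all phantom seeds, initialization seeds and
#'   training seeds derive from it
#' @param shape phantom grid edge
#' @param epochs,patchesPerSample,patchSize,lr coarse-stage training budget
#' @param fineEpochs fine-stage training budget
#' @param nCalib calibration-subset size for the vote weights
#' @param families the three backbone families
#' @return a list with per-model and fused coarse Dice tables, ensemble
#'   weights, and the trained models
#' @keywords internal
runRecoveryStudy <- function(nTrain = 20L, nHold = 5L, seed = 1L,
                             shape = 64L, epochs = 10L,
                             patchesPerSample = 4L, patchSize = 24L,
                             lr = 0.006, fineEpochs = 3L, nCalib = 8L,
                             families = c("residual_unet", "dynamic_unet",
                                          "large_kernel_unet")) {
  # keep derived seeds well inside 32-bit integer range
  seed <- as.integer(seed) %% 10000L
  spec <- phantomSpec(shape = shape, missingProb = 0.1)
  train <- lapply(seq_len(nTrain),
                  function(i) generatePhantom(spec, seed = seed * 1000L + i))
  hold <- lapply(seq_len(nHold),
                 function(i) generatePhantom(spec,
                                             seed = seed * 1000L + 500L + i))
  cfg <- loadPipelineConfig()

  # ground-truth ROI crops for fine-stage training
  finePairs <- lapply(train, function(s) {
    box <- extractTeethROI(s@coarse, cfg@roiMargin,
                           target = cfg@fineTargetShape)
    out <- cropResample(s@volume, s@fine, box)
    list(volume = out$volume, labels = out$labels)
  })

  models <- list()
  history <- list()
  for (t in seq_along(families)) {
    fam <- families[t]
    coarseSeg <- buildSegmenter(
      backboneConfig(fam, 10L, depth = 3L, baseWidth = 8L,
                     normalization = "none"), seed = seed + t)
    rc <- trainSegmenter(coarseSeg, train, "coarse",
                         trainConfig(epochs = epochs, lr = lr,
                                     patchSize = patchSize,
                                     patchesPerSample = patchesPerSample,
                                     seed = seed + 10L * t))
    fineSeg <- buildSegmenter(
      backboneConfig(fam, c(33L, 5L), depth = 3L, baseWidth = 8L,
                     normalization = "none"), seed = seed + 100L + t)
    rf <- trainSegmenter(fineSeg, finePairs, "fine",
                         trainConfig(epochs = fineEpochs, lr = lr,
                                     patchSize = 32L,
                                     patchesPerSample = 2L,
                                     seed = seed + 200L + t),
                         fineLossConfig(cfg@lambda1, cfg@lambda2))
    rm(coarseSeg, fineSeg)
    models[[t]] <- list(coarse = rc$model, fine = rf$model)
    history[[fam]] <- list(coarse = rc$history, fine = rf$history)
  }

  # calibrate vote weights on a subset of the training phantoms
  calModels <- lapply(models, function(m)
    function(s) segmentCoarse(m$coarse, s@volume)$labels)
  weights <- calibrateWeights(calModels, train[seq_len(min(nCalib, nTrain))],
                              diceThreshold = cfg@diceThreshold,
                              epsClip = cfg@epsClip, config = cfg)

  # held-out evaluation: individual cascades and the fused ensemble
  perModel <- vector("list", length(families))
  fusedTabs <- list()
  fineTabs <- list()
  for (i in seq_along(hold)) {
    s <- hold[[i]]
    probs <- vector("list", length(models))
    for (t in seq_along(models)) {
      cs <- segmentCoarse(models[[t]]$coarse, s@volume)
      probs[[t]] <- cs$prob
      perModel[[t]] <- rbind(perModel[[t]],
                             perClassMetrics(cs$labels, s@coarse,
                                             sampleId = sprintf("h%02d", i)))
    }
    fusedRes <- runELSeg(models, weights, s@volume, cfg)
    fusedTabs[[i]] <- perClassMetrics(fusedRes@coarse, s@coarse,
                                      sampleId = sprintf("h%02d", i))
    fineTabs[[i]] <- perClassMetrics(fusedRes@fine, s@fine,
                                     sampleId = sprintf("h%02d", i))
  }
  names(perModel) <- families
  list(weights = weights, perModel = perModel,
       fused = do.call(rbind, fusedTabs),
       fusedFine = do.call(rbind, fineTabs),
       history = history, models = models, holdout = hold)
}

# mean Dice of selected class labels from a metric table
.meanDiceOf <- function(tab, labels = NULL) {
  if (!is.null(labels)) tab <- tab[tab$classLabel %in% labels, , drop = FALSE]
  mean(tab$dice, na.rm = TRUE)
}

#' Noisy-oracle ensemble study
#'
#' Three synthetic segmenters corrupt phantom ground truth at independent
#' voxel error rates, vote weights are calibrated, and fused predictions
#' are compared against the individual models.
#'
#' @param rates per-model voxel error rates
#' @param nPhantoms number of phantoms
#' @param shape phantom grid edge
#' @param seed master seed
#' @return list with per-model and fused voxel error rates and mean
#'   foreground Dice
#' @keywords internal
runNoisyOracleStudy <- function(rates = c(0.10, 0.20, 0.30),
                                nPhantoms = 10L, shape = 48L, seed = 1L) {
  seed <- as.integer(seed) %% 10000L
  spec <- phantomSpec(shape = shape, missingProb = 0.1)
  phantoms <- lapply(seq_len(nPhantoms),
                     function(i) generatePhantom(spec,
                                                 seed = seed * 100L + i))
  corrupt <- function(gt, rate, s) {
    set.seed(s)
    lab <- gt@data
    K <- nClasses(gt@scheme)
    flip <- which(stats::runif(length(lab)) < rate)
    if (length(flip)) {
      shift <- sample.int(K - 1L, length(flip), replace = TRUE)
      lab[flip] <- (lab[flip] + shift) %% K
    }
    newLabelMap(lab, gt@scheme, gt@spacing, gt@transform)
  }
  softify <- function(lab, K, conf = 0.9) {
    oh <- .oneHot(lab@data, K)
    p <- oh * conf + (1 - conf) / K
    s <- rowSums(matrix(p, length(lab@data), K))
    newProbabilityMap(p / array(s, dim(p)), lab@scheme, lab@spacing,
                      lab@transform)
  }
  models <- lapply(seq_along(rates), function(t) {
    force(t)
    function(s) corrupt(s@coarse, rates[t], seed * 1000L + t * 37L + s@seed)
  })
  weights <- calibrateWeights(models, phantoms)
  voxErr <- matrix(NA_real_, nPhantoms, length(rates))
  dice <- matrix(NA_real_, nPhantoms, length(rates))
  fusedErr <- numeric(nPhantoms)
  fusedDice <- numeric(nPhantoms)
  for (i in seq_len(nPhantoms)) {
    s <- phantoms[[i]]
    gt <- voxels(s@coarse)
    probs <- lapply(seq_along(models), function(t) {
      lab <- models[[t]](s)
      voxErr[i, t] <<- mean(voxels(lab) != gt)
      dice[i, t] <<- .meanDiceOf(perClassMetrics(lab, s@coarse))
      softify(lab, 10L)
    })
    fused <- fuseProbabilityMaps(probs, weights)
    fusedErr[i] <- mean(voxels(fused$labels) != gt)
    fusedDice[i] <- .meanDiceOf(perClassMetrics(fused$labels, s@coarse))
  }
  list(weights = weights, voxErr = voxErr, dice = dice,
       fusedErr = fusedErr, fusedDice = fusedDice)
}

#' Parity-correction recovery study
#'
#' Constructs fixtures with exactly one parity-inconsistent tooth
#' component whose runner-up probability mass identifies the true FDI id,
#' runs the correction, and scores recovery plus idempotence.
#'
#' @param n number of fixtures
#' @param seed master seed
#' @param tau correction confidence threshold
#' @return list with recovery count and idempotence flag
#' @keywords internal
runParityRecoveryStudy <- function(n = 100L, seed = 1L, tau = 0.6) {
  seed <- as.integer(seed) %% 10000L
  recovered <- 0L
  consistentUntouched <- TRUE
  for (i in seq_len(n)) {
    fx <- .parityFixture(seed = seed * 1000L + i)
    corrected <- combinationCorrect(fx$p33, fx$p5, tau = tau)
    pv <- which(fx$truth == fx$trueId)
    if (all(corrected@data[pv] == fx$trueId)) recovered <- recovered + 1L
    argm <- .argmaxClasses(fx$p33@data)
    others <- which(!(argm %in% c(0L, fx$wrongId)))
    if (!all(corrected@data[others] == argm[others]))
      consistentUntouched <- FALSE
  }
  list(recovered = recovered, n = n,
       consistentUntouched = consistentUntouched)
}

# constructed fixture: a one-quadrant dentition ROI with one planted
# parity-inconsistent component and an unambiguous runner-up id
.parityFixture <- function(seed = 1L, planted = TRUE, conf5 = 0.95,
                           shape = c(20L, 20L, 20L)) {
  set.seed(seed)
  q <- sample(1:4, 1L)
  j <- sample(2:4, 1L)
  centre <- c(shape[1L] / 2, shape[2L] / 2)
  radius <- 9
  angles <- c(6, 34, 62, 90) * pi / 180
  sideSign <- if (q %in% c(1L, 4L)) -1 else 1
  z0 <- shape[3L] / 2
  lab <- array(0L, shape)
  X <- array(rep(seq_len(shape[1L]) - 1, prod(shape[2:3])), shape)
  Y <- array(rep(rep(seq_len(shape[2L]) - 1, each = shape[1L]), shape[3L]),
             shape)
  Z <- array(rep(seq_len(shape[3L]) - 1, each = prod(shape[1:2])), shape)
  truth <- integer(4L)
  for (pos in 1:4) {
    a <- angles[pos] * sideSign
    cx <- centre[1L] + radius * sin(a)
    cy <- centre[2L] - radius * cos(a)
    m <- (X - cx)^2 + (Y - cy)^2 <= 1.2^2 & abs(Z - z0) <= 2
    truth[pos] <- fdiToFineId(q * 10L + pos)
    lab[m] <- truth[pos]
  }
  trueId <- fdiToFineId(q * 10L + j)
  wrongId <- fdiToFineId(q * 10L + j - 1L)
  n3 <- prod(shape)
  p33 <- array(0.1 / 32, c(shape, 33L)); p33[, , , 1L] <- 0.9
  p5 <- array((1 - conf5) / 4, c(shape, 5L)); p5[, , , 1L] <- conf5
  for (pos in 1:4) {
    vox <- which(lab == truth[pos])
    p33[vox] <- 0.02
    if (planted && pos == j) {
      p33[vox + n3 * wrongId] <- 0.55
      p33[vox + n3 * trueId] <- 0.40
    } else {
      p33[vox + n3 * truth[pos]] <- 0.9
    }
    par <- unname(parityGroup(fineIdToFdi(truth[pos])))
    p5[vox] <- (1 - conf5) / 4
    p5[vox + n3 * par] <- conf5
  }
  norm4 <- function(a) {
    s <- rowSums(matrix(a, n3, dim(a)[4L]))
    a / array(s, dim(a))
  }
  list(p33 = newProbabilityMap(norm4(p33), "fine"),
       p5 = newProbabilityMap(norm4(p5), "parity"),
       truth = lab, trueId = trueId, wrongId = wrongId,
       quadrant = q, position = j)
}
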