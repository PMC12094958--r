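# AdaBoost-weighted soft-voting ensemble fusion: per-model vote weights are
# learned on a calibration set by a sequential boosting pass, and the three
# cascades' probability maps are fused as a convex combination.

#' AdaBoost vote weight from an error rate
#'
#' \code{alpha = 0.5 * log((1 - eps) / eps)}: zero at chance (eps = 0.5),
#' strictly decreasing in eps. The error rate must lie strictly inside
#' (0, 1); clipping into the configured range is the caller's documented
#' policy (see \code{calibrateWeights}).
#'
#' @param eps error rate(s), strictly inside (0, 1)
#' @return vote weight(s) alpha
#' @examples
#' adaboostWeight(0.5)            # 0
#' adaboostWeight(1 / (1 + exp(2)))  # 1
#' @export
adaboostWeight <- function(eps) {
  if (any(!is.finite(eps)) || any(eps <= 0) || any(eps >= 1))
    .stopWith("domainError",
              "error rate must lie strictly inside (0, 1); got %s",
              paste(signif(eps[!(eps > 0 & eps < 1)], 4), collapse = ", "))
  0.5 * log((1 - eps) / eps)
}

# evaluate one "model" on one sample, returning the predicted label map.
# Accepted model forms: a function(sample) -> LabelMap/ProbabilityMap,
# a Segmenter (coarse stage), or list(coarse=, fine=) cascade pair.
.modelPredict <- function(model, sample, stage, config) {
  out <- if (is.function(model)) {
    model(sample)
  } else if (is(model, "Segmenter")) {
    segmentCoarse(model, sample@volume)$labels
  } else if (is.list(model) && !is.null(model$coarse)) {
    res <- runCascade(model$coarse, model$fine, sample@volume, config)
    if (stage == "fine") res@fine else res@coarse
  } else {
    .stopWith("contractError", "unrecognized model form for calibration")
  }
  if (is(out, "ProbabilityMap"))
    out <- newLabelMap(.argmaxClasses(out@data), out@scheme,
                       out@spacing, out@transform)
  out
}

# mean foreground Dice of a predicted vs ground-truth label map
.meanForegroundDice <- function(pred, gt) {
  tab <- perClassMetrics(pred, gt)
  mean(tab$dice, na.rm = TRUE)
}

#' Calibrate ensemble vote weights by sequential boosting
#'
#' Runs each model over the calibration samples and scores it by mean
#' foreground Dice per sample. Models are then processed in a fixed,
#' documented order (descending unweighted mean Dice). Sample weights start
#' uniform; for model t, a sample counts as misclassified when its mean
#' foreground Dice falls below the threshold D* (\code{diceThreshold});
#' \code{eps_t} is the weighted misclassified fraction clipped into
#' \code{epsClip}; \code{alpha_t} follows the AdaBoost closed form; sample
#' weights are multiplied by \code{exp(alpha_t)} on misclassified samples
#' and renormalized. Deterministic given models and samples.
#'
#' @param models list of models (cascade pairs \code{list(coarse=, fine=)},
#'   \linkS4class{Segmenter}s, or prediction functions)
#' @param calibration list of at least 2 \linkS4class{PhantomSample}s
#' @param diceThreshold per-sample misclassification threshold D*
#' @param epsClip error-rate clip bounds (alpha >= 0 at the upper bound 0.5,
#'   so a worse-than-chance model gets zero vote)
#' @param stage "coarse" or "fine": which ground truth to score against
#' @param config pipeline configuration passed to cascade models
#' @return an \linkS4class{EnsembleWeights}
#' @export
calibrateWeights <- function(models, calibration, diceThreshold = 0.95,
                             epsClip = c(1e-4, 0.5),
                             stage = c("coarse", "fine"),
                             config = loadPipelineConfig()) {
  stage <- match.arg(stage)
  if (length(calibration) < 2L)
    .stopWith("calibrationError", "need at least 2 calibration samples")
  nM <- length(models)
  nS <- length(calibration)
  dice <- matrix(NA_real_, nS, nM)
  for (t in seq_len(nM)) for (i in seq_len(nS)) {
    s <- calibration[[i]]
    gt <- if (stage == "fine") s@fine else s@coarse
    pred <- .modelPredict(models[[t]], s, stage, config)
    dice[i, t] <- .meanForegroundDice(pred, gt)
  }
  ord <- order(-colMeans(dice))
  w <- rep(1 / nS, nS)
  eps <- numeric(nM)
  alpha <- numeric(nM)
  for (t in ord) {
    mis <- dice[, t] < diceThreshold
    e <- sum(w[mis]) / sum(w)
    e <- min(max(e, epsClip[1L]), epsClip[2L])
    a <- adaboostWeight(e)
    eps[t] <- e
    alpha[t] <- a
    if (any(mis)) {
      w[mis] <- w[mis] * exp(a)
      w <- w / sum(w)
    }
  }
  wNorm <- if (sum(alpha) > 0) alpha / sum(alpha) else rep(1 / nM, nM)
  ids <- vapply(seq_len(nS), function(i)
    sprintf("sample-%02d", i), character(1L))
  new("EnsembleWeights", epsilon = eps, alpha = alpha, w = wNorm,
      order = as.integer(ord), sampleIds = ids, sampleWeights = w,
      rule = list(diceThreshold = diceThreshold, epsClip = epsClip,
                  stage = stage, perSampleDice = dice))
}

#' Fuse probability maps by weighted soft voting
#'
#' \code{fused(v, c) = sum_t w_t * p_t(v, c)}: a convex combination, so the
#' fused map stays on the simplex. Labels are the fused argmax with the
#' lowest-id tie-break. One-hot weights reproduce the selected model
#' exactly, and permuting models and weights together leaves the result
#' unchanged.
#'
#' @param probMaps list of \linkS4class{ProbabilityMap}s on one grid and
#'   scheme
#' @param weights an \linkS4class{EnsembleWeights} or a numeric weight
#'   vector (normalized internally)
#' @return \code{list(labels = LabelMap, prob = ProbabilityMap)}
#' @export
fuseProbabilityMaps <- function(probMaps, weights) {
  stopifnot(length(probMaps) >= 2L)
  w <- if (is(weights, "EnsembleWeights")) weights@w else as.numeric(weights)
  if (length(w) != length(probMaps))
    .stopWith("contractError", "need one weight per probability map")
  if (any(w < 0)) .stopWith("contractError", "weights must be nonnegative")
  w <- w / sum(w)
  ref <- probMaps[[1L]]
  for (pm in probMaps[-1L]) {
    if (!all(dim(pm@data) == dim(ref@data)))
      .stopWith("contractError", "probability maps must share one grid")
    if (pm@scheme@name != ref@scheme@name)
      .stopWith("contractError", "probability maps must share one scheme")
  }
  fused <- ref@data * w[1L]
  for (t in seq_along(probMaps)[-1L])
    fused <- fused + probMaps[[t]]@data * w[t]
  prob <- newProbabilityMap(fused, ref@scheme, ref@spacing, ref@transform)
  labels <- newLabelMap(.argmaxClasses(fused), ref@scheme, ref@spacing,
                        ref@transform)
  list(labels = labels, prob = prob)
}

#' Run the fused ensemble cascade
#'
#' Runs each cascade's coarse stage, fuses the coarse probability maps on
#' the full grid, extracts each cascade's dentition ROI and takes the union
#' box, resamples the union ROI once to a common grid, fuses the three fine
#' dual-head predictions there, applies the adjacent-tooth correction to
#' the fused maps, and pastes back. When no cascade finds a dentition the
#' fused coarse map is returned and the fine stage is skipped (flagged).
#'
#' @param models list of 3 cascade pairs \code{list(coarse=, fine=)}
#' @param weights \linkS4class{EnsembleWeights} (or numeric) for the coarse
#'   fusion
#' @param volume a \linkS4class{CTVolume}
#' @param config a \linkS4class{PipelineConfig}
#' @param fineWeights optional separate weight set for the fine-stage
#'   fusion (defaults to \code{weights})
#' @return a \linkS4class{CascadeResult}
#' @export
runELSeg <- function(models, weights, volume, config = loadPipelineConfig(),
                     fineWeights = weights) {
  stopifnot(is(volume, "CTVolume"))
  sh <- dim(volume@data)
  coarseProbs <- vector("list", length(models))
  boxes <- vector("list", length(models))
  for (t in seq_along(models)) {
    cs <- tryCatch(segmentCoarse(models[[t]]$coarse, volume),
                   cmfelsegError = function(e) {
                     e$message <- sprintf("[model %d] %s", t,
                                          conditionMessage(e))
                     stop(e)
                   })
    coarseProbs[[t]] <- cs$prob
    boxes[[t]] <- tryCatch(extractTeethROI(cs$labels, config@roiMargin),
                           emptyForegroundError = function(e) NULL)
  }
  fusedCoarse <- fuseProbabilityMaps(coarseProbs, weights)
  found <- !vapply(boxes, is.null, logical(1L))
  if (!any(found)) {
    return(new("CascadeResult", coarse = fusedCoarse$labels,
               fine = newLabelMap(array(0L, sh), labelScheme("fine"),
                                  volume@spacing, volume@transform),
               roi = new("ROIBox", lower = c(0L, 0L, 0L),
                         upper = as.integer(sh),
                         sourceShape = as.integer(sh),
                         targetShape = as.integer(sh)),
               coarseProb = NULL, fineProb = NULL, disagreement = 0,
               roiFallback = TRUE))
  }
  lower <- do.call(pmin, lapply(boxes[found], function(b) b@lower))
  upper <- do.call(pmax, lapply(boxes[found], function(b) b@upper))
  box <- new("ROIBox", lower = as.integer(lower), upper = as.integer(upper),
             sourceShape = as.integer(sh),
             targetShape = rep(config@fineTargetShape, 3L))
  roi <- cropResample(volume, NULL, box)
  p33s <- vector("list", length(models))
  p5s <- vector("list", length(models))
  for (t in seq_along(models)) {
    fine <- segmentFine(models[[t]]$fine, roi$volume)
    p33s[[t]] <- fine$p33
    p5s[[t]] <- fine$p5
  }
  fused33 <- fuseProbabilityMaps(p33s, fineWeights)
  fused5 <- fuseProbabilityMaps(p5s, fineWeights)
  corrected <- combinationCorrect(fused33$prob, fused5$prob, config@tau)
  fineFull <- pasteBack(corrected, box, sh, volume@spacing,
                        volume@transform)
  toothVox <- fineFull@data > 0L
  disagreement <- if (any(toothVox)) {
    mean(!(fusedCoarse$labels@data[toothVox] %in%
             c(.COARSE_UPPER_TEETH, .COARSE_LOWER_TEETH)))
  } else 0
  new("CascadeResult", coarse = fusedCoarse$labels, fine = fineFull,
      roi = box, coarseProb = NULL, fineProb = NULL,
      disagreement = disagreement, roiFallback = !all(found))
}
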