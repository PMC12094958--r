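# Soft Dice loss, the combined dual-head fine-stage loss, cross-validation
# splitting and the seeded SGD training loop.

#' Configure the dual-head fine-stage loss
#'
#' @param lambda1 weight of the 33-class Dice term (default 0.5)
#' @param lambda2 weight of the 5-class Dice term (default 0.5)
#' @param smooth smoothing constant of the soft Dice ratio (default 1e-5)
#' @return a \linkS4class{FineLossConfig}
#' @export
fineLossConfig <- function(lambda1 = 0.5, lambda2 = 0.5, smooth = 1e-5) {
  obj <- new("FineLossConfig", lambda1 = as.numeric(lambda1),
             lambda2 = as.numeric(lambda2), smooth = as.numeric(smooth))
  validObject(obj)
  obj
}

#' Configure the training loop
#'
#' @param epochs,batchSize,lr,momentum,optimizer,patchSize,patchesPerSample
#'   see \linkS4class{TrainConfig}
#' @param ceWeight weight of the auxiliary cross-entropy term in the
#'   training objective (Dice + CE is the conventional combination for
#'   optimizing volumetric U-Nets; set 0 for pure Dice training)
#' @param balancedSampling centre half of the patches on random foreground
#'   voxels so small structures are seen often
#' @param augment random x-flip augmentation
#' @param seed training seed (controls patch sampling and sample order)
#' @param fold cross-validation fold index (bookkeeping)
#' @return a \linkS4class{TrainConfig}
#' @export
trainConfig <- function(epochs = 4L, batchSize = 1L, lr = 0.003,
                        momentum = 0.9, optimizer = "adam", patchSize = 32L,
                        patchesPerSample = 4L, ceWeight = 1.0,
                        balancedSampling = FALSE, augment = FALSE,
                        seed = 1L, fold = 0L) {
  obj <- new("TrainConfig", epochs = as.integer(epochs),
             batchSize = as.integer(batchSize), lr = as.numeric(lr),
             momentum = as.numeric(momentum), optimizer = optimizer,
             patchSize = as.integer(patchSize),
             patchesPerSample = as.integer(patchesPerSample),
             ceWeight = as.numeric(ceWeight),
             balancedSampling = isTRUE(balancedSampling),
             augment = isTRUE(augment), seed = as.integer(seed),
             fold = as.integer(fold))
  validObject(obj)
  obj
}

# soft Dice on raw arrays: probs (x,y,z,K), onehot (x,y,z,K).
# Foreground-class mean by default; returns the loss and optionally the
# gradient w.r.t. probs.
.softDice <- function(probs, onehot, smooth, excludeBackground = TRUE,
                      grad = FALSE) {
  d <- dim(probs)
  K <- d[4L]
  n <- prod(d[1:3])
  pm <- matrix(probs, n, K)
  gm <- matrix(onehot, n, K)
  cls <- if (excludeBackground) seq_len(K)[-1L] else seq_len(K)
  inter <- colSums(pm[, cls, drop = FALSE] * gm[, cls, drop = FALSE])
  psum <- colSums(pm[, cls, drop = FALSE])
  gsum <- colSums(gm[, cls, drop = FALSE])
  denom <- psum + gsum + smooth
  dice <- (2 * inter + smooth) / denom
  loss <- 1 - mean(dice)
  if (!grad) return(list(loss = loss))
  gp <- matrix(0, n, K)
  nc <- length(cls)
  for (j in seq_along(cls)) {
    c <- cls[j]
    gp[, c] <- -(2 * gm[, c] * denom[j] - (2 * inter[j] + smooth)) /
      (nc * denom[j]^2)
  }
  list(loss = loss, gprobs = array(gp, d))
}

#' Soft Dice loss between a probability map and a label map
#'
#' Computes \code{1 - mean_c (2*sum(p_c*g_c) + s) / (sum(p_c) + sum(g_c) + s)}
#' with one-hot ground truth g, averaged over the scheme's foreground
#' classes (the background class is excluded by default). Lies in [0, 1]
#' and approaches 0 for a perfect prediction as s goes to 0.
#'
#' @param probs a \linkS4class{ProbabilityMap}
#' @param target a \linkS4class{LabelMap} on the same grid and scheme
#' @param smooth smoothing constant s (> 0)
#' @param excludeBackground drop the background class from the mean
#' @return scalar loss in [0, 1]
#' @export
softDiceLoss <- function(probs, target, smooth = 1e-5,
                         excludeBackground = TRUE) {
  stopifnot(is(probs, "ProbabilityMap"), is(target, "LabelMap"))
  if (probs@scheme@name != target@scheme@name)
    .stopWith("contractError", "probs and target must share one scheme")
  .checkSameGrid(probs, target, "probs and target")
  K <- nClasses(probs@scheme)
  .softDice(probs@data, .oneHot(target@data, K), smooth,
            excludeBackground)$loss
}

#' Combined loss of the dual-head fine stage
#'
#' \code{lambda1 * Ldice(p33, G33) + lambda2 * Ldice(p5, G5)}: the 33-class
#' head is supervised by individual FDI teeth, the 5-class head by the
#' jaw/parity groups, and the total is linear in (lambda1, lambda2).
#'
#' @param p33 fine-scheme \linkS4class{ProbabilityMap}
#' @param G33 fine-scheme \linkS4class{LabelMap}
#' @param p5 parity-scheme \linkS4class{ProbabilityMap}
#' @param G5 parity-scheme \linkS4class{LabelMap}
#' @param cfg a \linkS4class{FineLossConfig}
#' @return scalar loss
#' @export
fineLoss <- function(p33, G33, p5, G5, cfg = fineLossConfig()) {
  if (p33@scheme@name != "fine" || G33@scheme@name != "fine")
    .stopWith("contractError", "p33/G33 must be on the fine scheme")
  if (p5@scheme@name != "parity" || G5@scheme@name != "parity")
    .stopWith("contractError", "p5/G5 must be on the parity scheme")
  cfg@lambda1 * softDiceLoss(p33, G33, cfg@smooth) +
    cfg@lambda2 * softDiceLoss(p5, G5, cfg@smooth)
}

#' Deterministic k-fold cross-validation split
#'
#' Validation sets partition the ids with sizes differing by at most 1.
#'
#' @param sampleIds vector of sample identifiers
#' @param k number of folds (>= 2)
#' @param seed shuffle seed
#' @return list of k elements, each \code{list(train = , validation = )}
#' @export
kfoldSplit <- function(sampleIds, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) .stopWith("splitError", "k must be >= 2")
  if (length(sampleIds) < k)
    .stopWith("splitError", "need at least k = %d sample ids, got %d",
              k, length(sampleIds))
  shuffled <- .withSeed(seed, sample(sampleIds))
  fold <- rep(seq_len(k), length.out = length(shuffled))
  lapply(seq_len(k), function(i)
    list(train = shuffled[fold != i], validation = shuffled[fold == i]))
}

# normalize heterogeneous training samples to list(volume=, labels=) pairs
.asTrainingPair <- function(s, stage) {
  if (is(s, "PhantomSample")) {
    if (stage == "coarse") return(list(volume = s@volume, labels = s@coarse))
    return(list(volume = s@volume, labels = s@fine))
  }
  if (is.list(s) && !is.null(s$volume)) {
    lab <- s$labels %||% s$fine %||% s$coarse
    return(list(volume = s$volume, labels = lab))
  }
  .stopWith("contractError",
            "samples must be PhantomSamples or list(volume=, labels=) pairs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a segmenter with seeded stochastic gradient descent
#'
#' Draws random patches from each sample per epoch, optimizes the soft Dice
#' loss (coarse stage) or the combined dual-head loss (fine stage) with
#' SGD + momentum, and records the per-epoch mean training loss. Two runs
#' with identical seeds and configs produce identical histories.
#'
#' @param model a \linkS4class{Segmenter}; 1 head with 10 classes for the
#'   coarse stage, heads c(33, 5) for the fine stage
#' @param samples list of \linkS4class{PhantomSample}s, or of
#'   \code{list(volume = , labels = )} pairs. Fine-stage samples must be
#'   ROI-cropped pairs with fine-scheme labels; the 5-class parity target
#'   is derived from them.
#' @param stage "coarse" or "fine"
#' @param cfg a \linkS4class{TrainConfig}
#' @param lossCfg a \linkS4class{FineLossConfig} (loss weights and
#'   smoothing; the coarse stage uses only the smoothing constant)
#' @return \code{list(model = trained Segmenter, history = data.frame)}
#' @export
trainSegmenter <- function(model, samples, stage = c("coarse", "fine"),
                           cfg = trainConfig(), lossCfg = fineLossConfig()) {
  stage <- match.arg(stage)
  stopifnot(is(model, "Segmenter"))
  if (!length(samples))
    .stopWith("contractError", "samples must be nonempty")
  nH <- length(model@config@nClasses)
  if (stage == "coarse" && nH != 1L)
    .stopWith("contractError", "coarse stage expects a single-head model")
  if (stage == "fine" &&
      !(nH == 2L && all(model@config@nClasses == c(33L, 5L))))
    .stopWith("contractError",
              "fine stage expects a dual-head model with classes c(33, 5)")
  pairs <- lapply(samples, .asTrainingPair, stage = stage)
  K1 <- model@config@nClasses[1L]
  for (p in pairs) {
    if (max(p$labels@data) >= K1)
      .stopWith("contractError",
                "label ids exceed the model's %d classes", K1)
  }
  # foreground voxel index lists per sample for class-balanced patch
  # sampling (half the patches are centred on a random foreground voxel of
  # a randomly chosen present class, so small structures are seen often)
  fgIndex <- lapply(pairs, function(p) {
    lab <- p$labels@data
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    stats::setNames(lapply(ids, function(id) which(lab == id)),
                    as.character(ids))
  })
  m <- .gridMultiple(model@config)
  params <- model@params
  vel <- .paramZeros(params)        # SGD momentum / Adam first moment
  vel2 <- .paramZeros(params)       # Adam second moment
  stepN <- 0L
  history <- data.frame(epoch = integer(), loss = numeric())
  lut5 <- c(0L, unname(.parityOfFineId()))

  run <- function() {
    for (ep in seq_len(cfg@epochs)) {
      losses <- c()
      order_ <- sample(length(pairs))
      for (si in order_) {
        vol <- pairs[[si]]$volume@data
        lab <- pairs[[si]]$labels@data
        sh <- dim(vol)
        ps <- min(cfg@patchSize, min(sh))
        ps <- (ps %/% m) * m
        if (ps < m)
          .stopWith("contractError", "sample smaller than one grid cell")
        mu <- mean(vol); sigma <- max(sd(vol), 1e-8)
        for (rep_ in seq_len(cfg@patchesPerSample)) {
          fg <- fgIndex[[si]]
          if (cfg@balancedSampling && length(fg) &&
              stats::runif(1) < 0.5) {
            cls <- fg[[sample.int(length(fg), 1L)]]
            centre <- arrayInd(cls[sample.int(length(cls), 1L)], sh) - 1L
            org <- vapply(1:3, function(i)
              as.integer(max(0, min(sh[i] - ps, centre[i] - ps %/% 2L))),
              integer(1L))
          } else {
            org <- vapply(1:3, function(i)
              if (sh[i] > ps) sample.int(sh[i] - ps + 1L, 1L) - 1L else 0L,
              integer(1L))
          }
          ix <- org[1L] + seq_len(ps); iy <- org[2L] + seq_len(ps)
          iz <- org[3L] + seq_len(ps)
          pvol <- vol[ix, iy, iz, drop = FALSE]; dim(pvol) <- c(ps, ps, ps)
          plab <- lab[ix, iy, iz, drop = FALSE]; dim(plab) <- c(ps, ps, ps)
          if (cfg@augment && sample(c(TRUE, FALSE), 1L)) {
            pvol <- pvol[ps:1, , , drop = FALSE]
            plab <- plab[ps:1, , , drop = FALSE]
            dim(pvol) <- dim(plab) <- c(ps, ps, ps)
          }
          fw <- .segForward(model, pvol, mu, sigma, sh, org,
                            keepCache = TRUE)
          if (stage == "coarse") {
            oh <- .oneHot(plab, K1)
            hd <- .headObjective(fw$probs[[1L]], plab, oh, lossCfg@smooth,
                                 cfg@ceWeight)
            loss <- hd$loss
            gheads <- list(hd$glogits)
          } else {
            oh33 <- .oneHot(plab, 33L)
            plab5 <- plab; plab5[] <- lut5[plab + 1L]
            oh5 <- .oneHot(plab5, 5L)
            h33 <- .headObjective(fw$probs[[1L]], plab, oh33,
                                  lossCfg@smooth, cfg@ceWeight)
            h5 <- .headObjective(fw$probs[[2L]], plab5, oh5,
                                 lossCfg@smooth, cfg@ceWeight)
            loss <- lossCfg@lambda1 * h33$loss + lossCfg@lambda2 * h5$loss
            gheads <- list(lossCfg@lambda1 * h33$glogits,
                           lossCfg@lambda2 * h5$glogits)
          }
          if (!is.finite(loss))
            .stopWith("trainingDivergenceError",
                      "non-finite loss at epoch %d", ep)
          gp <- .unetBwd(model@config, params, fw$cache, gheads)
          if (cfg@optimizer == "adam") {
            stepN <<- stepN + 1L
            b1 <- 0.9; b2 <- 0.999
            vel <<- .paramMap2(function(m_, g) b1 * m_ + (1 - b1) * g,
                               vel, gp)
            vel2 <<- .paramMap2(function(v_, g) b2 * v_ + (1 - b2) * g^2,
                                vel2, gp)
            corr <- cfg@lr * sqrt(1 - b2^stepN) / (1 - b1^stepN)
            params <<- .paramMap3(function(p, m_, v_)
              p - corr * m_ / (sqrt(v_) + 1e-8), params, vel, vel2)
          } else {
            vel <<- .paramMap2(function(v, g) cfg@momentum * v - cfg@lr * g,
                               vel, gp)
            params <<- .paramMap2(`+`, params, vel)
          }
          model@params <- params
          losses <- c(losses, loss)
        }
      }
      history[nrow(history) + 1L, ] <- list(ep, mean(losses))
    }
    history
  }
  history <- .withSeed(cfg@seed, run())
  model@params <- params
  model@trained <- TRUE
  list(model = model, history = history)
}

# one head's training objective: soft Dice plus an optional class-balanced
# voxel-wise cross-entropy term, with the gradient w.r.t. the head's
# logits. The CE term uses median-frequency balancing (weight of class c
# proportional to median class frequency / frequency of c, clipped) so
# small structures contribute gradients comparable to large ones.
.headObjective <- function(probs, lab, onehot, smooth, ceWeight) {
  sd_ <- .softDice(probs, onehot, smooth, grad = TRUE)
  glogits <- .softmaxBwd(probs, sd_$gprobs)
  loss <- sd_$loss
  if (ceWeight > 0) {
    K <- dim(probs)[4L]
    n <- length(lab)
    counts <- tabulate(as.vector(lab) + 1L, nbins = K)
    present <- counts > 0L
    wclass <- numeric(K)
    wclass[present] <- pmin(stats::median(counts[present]) /
                              counts[present], 20)
    wvox <- wclass[as.vector(lab) + 1L]
    wsum <- sum(wvox)
    ptrue <- probs[seq_len(n) + n * as.numeric(lab)]
    loss <- loss - ceWeight * sum(wvox * log(pmax(ptrue, 1e-12))) / wsum
    glogits <- glogits + (ceWeight / wsum) *
      array(wvox, dim(probs)) * (probs - onehot)
  }
  list(loss = loss, glogits = glogits)
}

# chain rule through the per-voxel softmax: given dL/dp, return dL/dz
.softmaxBwd <- function(probs, gprobs) {
  d <- dim(probs)
  n <- prod(d[1:3])
  pm <- matrix(probs, n, d[4L])
  gm <- matrix(gprobs, n, d[4L])
  dot <- rowSums(pm * gm)
  array(pm * (gm - dot), d)
}
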