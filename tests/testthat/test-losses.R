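test_that("soft Dice loss reproduces the closed-form limit cases", {
  sh <- c(4, 4, 4)
  set.seed(1)
  lab <- array(sample(0:4, prod(sh), replace = TRUE), sh)
  lab[1:5] <- 0:4                       # every parity class present
  target <- newLabelMap(lab, "parity")
  onehot <- cmfelseg:::.oneHot(lab, 5L)
  perfect <- newProbabilityMap(onehot, "parity")
  expect_lt(softDiceLoss(perfect, target, smooth = 1e-5), 1e-4)

  # fully disjoint: every voxel predicted as a cyclically shifted class,
  # so predictions and ground truth never intersect on any class
  wrong <- (lab %% 4L) + 1L
  disjoint <- newProbabilityMap(cmfelseg:::.oneHot(wrong, 5L), "parity")
  expect_gt(softDiceLoss(disjoint, target, smooth = 1e-12), 1 - 1e-6)
})

test_that("the 2-voxel hand-computed Dice case gives 0.5", {
  # 2 voxels, 2 classes; p(fg) = (0.5, 0.5); target = (fg, bg); s -> 0
  # per the formula: 1 - (2 * 0.5) / (1.0 + 1.0) = 0.5
  p <- array(c(0.5, 0.5,        # background channel
               0.5, 0.5), c(2, 1, 1, 2))
  lab <- array(c(1L, 0L), c(2, 1, 1))
  oh <- cmfelseg:::.oneHot(lab, 2L)
  res <- cmfelseg:::.softDice(p, oh, smooth = 0)
  expect_equal(res$loss, 0.5, tolerance = 1e-12)
})

test_that("soft Dice lies in [0,1] and improves when mass moves to the true class", {
  set.seed(3)
  sh <- c(6, 6, 6)
  lab <- array(sample(0:4, prod(sh), replace = TRUE), sh)
  oh <- cmfelseg:::.oneHot(lab, 5L)
  for (rep_ in 1:20) {
    p <- randomProbArray(sh, 5L, seed = rep_)
    l0 <- cmfelseg:::.softDice(p, oh, 1e-5)$loss
    expect_gte(l0, 0); expect_lte(l0, 1)
    # move 10% of each voxel's off-class mass onto the true class
    p2 <- p * 0.9 + oh * (0.1 * rowSums(matrix(p, prod(sh), 5L)))
    s <- rowSums(matrix(p2, prod(sh), 5L))
    p2 <- p2 / array(s, dim(p2))
    l1 <- cmfelseg:::.softDice(p2, oh, 1e-5)$loss
    expect_lt(l1, l0)
  }
})

test_that("the fine loss equals the weighted sum of its head losses", {
  set.seed(4)
  sh <- c(6, 6, 6)
  lab <- array(sample(c(0:5, 20:25), prod(sh), replace = TRUE), sh)
  G33 <- newLabelMap(lab, "fine")
  G5 <- deriveParityLabels(G33)
  p33 <- randomProbMap(sh, "fine", seed = 10)
  p5 <- randomProbMap(sh, "parity", seed = 11)

  d33 <- softDiceLoss(p33, G33)
  d5 <- softDiceLoss(p5, G5)
  expect_equal(fineLoss(p33, G33, p5, G5, fineLossConfig(1, 0)), d33)
  expect_equal(fineLoss(p33, G33, p5, G5, fineLossConfig(0.5, 0.5)),
               0.5 * d33 + 0.5 * d5)

  # perfect both heads -> 0 in the small-smooth limit
  perfect33 <- newProbabilityMap(cmfelseg:::.oneHot(lab, 33L), "fine")
  perfect5 <- newProbabilityMap(cmfelseg:::.oneHot(voxels(G5), 5L), "parity")
  expect_lt(fineLoss(perfect33, G33, perfect5, G5), 1e-3)
})

test_that("the fine loss is linear in (lambda1, lambda2)", {
  set.seed(5)
  sh <- c(4, 4, 4)
  lab <- array(sample(0:32, prod(sh), replace = TRUE), sh)
  G33 <- newLabelMap(lab, "fine")
  G5 <- deriveParityLabels(G33)
  p33 <- randomProbMap(sh, "fine", seed = 20)
  p5 <- randomProbMap(sh, "parity", seed = 21)
  base <- c(l1 = 0.7, l2 = 0.3)
  L0 <- fineLoss(p33, G33, p5, G5, fineLossConfig(base["l1"], base["l2"]))
  for (a in c(0.25, 1.5, 3)) {
    La <- fineLoss(p33, G33, p5, G5,
                   fineLossConfig(a * base["l1"], a * base["l2"]))
    expect_equal(La, a * L0, tolerance = 1e-12)
  }
})

test_that("scheme and grid mismatches are contract errors", {
  p <- randomProbMap(c(4, 4, 4), "fine", seed = 1)
  t5 <- newLabelMap(array(0L, c(4, 4, 4)), "parity")
  expect_error(softDiceLoss(p, t5), class = "contractError")
  tBig <- newLabelMap(array(0L, c(6, 6, 6)), "fine")
  expect_error(softDiceLoss(p, tBig), class = "contractError")
})

test_that("k-fold splits partition the ids deterministically", {
  ids <- sprintf("s%02d", 1:10)
  folds <- kfoldSplit(ids, k = 5, seed = 3)
  expect_length(folds, 5L)
  vals <- lapply(folds, `[[`, "validation")
  expect_true(all(lengths(vals) == 2L))
  expect_setequal(unlist(vals), ids)
  for (f in folds)
    expect_length(intersect(f$train, f$validation), 0L)
  expect_identical(folds, kfoldSplit(ids, k = 5, seed = 3))
  expect_error(kfoldSplit(ids[1:3], k = 5), class = "splitError")
})

test_that("validation folds stay disjoint and covering over many seeds", {
  ids <- sprintf("x%03d", 1:23)
  for (seed in 1:100) {
    folds <- kfoldSplit(ids, k = 4, seed = seed)
    vals <- lapply(folds, `[[`, "validation")
    expect_setequal(unlist(vals), ids)
    expect_equal(sum(lengths(vals)), length(ids))   # pairwise disjoint
    expect_lte(diff(range(lengths(vals))), 1L)
  }
})

test_that("a short training run is seeded, finite and recorded", {
  p <- cachedPhantom(seed = 1, shape = 32L)
  seg <- buildSegmenter(backboneConfig("dynamic_unet", 10, depth = 2,
                                       baseWidth = 4), seed = 2)
  cfg <- trainConfig(epochs = 1, patchSize = 16, patchesPerSample = 1,
                     seed = 5)
  r <- trainSegmenter(seg, list(p), "coarse", cfg)
  expect_equal(nrow(r$history), 1L)
  expect_true(is.finite(r$history$loss))
  expect_true(r$model@trained)
  # determinism: identical seeds give identical histories and weights
  r2 <- trainSegmenter(seg, list(p), "coarse", cfg)
  expect_identical(r$history, r2$history)
  expect_identical(r$model@params$stem$c$w, r2$model@params$stem$c$w)
})

test_that("training reduces the loss on an easy two-structure task", {
  # two structures, no noise: a bright ball inside a dim background
  sh <- c(16, 16, 16)
  co <- (sh - 1) / 2
  X <- array(rep(seq_len(sh[1]) - 1, prod(sh[2:3])), sh)
  Y <- array(rep(rep(seq_len(sh[2]) - 1, each = sh[1]), sh[3]), sh)
  Z <- array(rep(seq_len(sh[3]) - 1, each = prod(sh[1:2])), sh)
  ball <- (X - co[1])^2 + (Y - co[2])^2 + (Z - co[3])^2 <= 25
  lab <- array(0L, sh); lab[ball] <- 1L
  vol <- array(0, sh); vol[ball] <- 1000
  samples <- list(list(volume = newVolume(vol),
                       labels = newLabelMap(lab, "coarse")))
  seg <- buildSegmenter(backboneConfig("dynamic_unet", 10, depth = 2,
                                       baseWidth = 4), seed = 3)
  cfg <- trainConfig(epochs = 20, patchSize = 16, patchesPerSample = 1,
                     lr = 0.003, seed = 7)
  r <- trainSegmenter(seg, samples, "coarse", cfg)
  expect_lt(r$history$loss[20], r$history$loss[1])
})

test_that("stage/model mismatches are contract errors", {
  p <- cachedPhantom(seed = 1, shape = 32L)
  dual <- buildSegmenter(backboneConfig("dynamic_unet", c(33, 5),
                                        depth = 2, baseWidth = 4), seed = 1)
  expect_error(trainSegmenter(dual, list(p), "coarse"),
               class = "contractError")
  single <- buildSegmenter(backboneConfig("dynamic_unet", 10, depth = 2,
                                          baseWidth = 4), seed = 1)
  expect_error(trainSegmenter(single, list(p), "fine"),
               class = "contractError")
  expect_error(trainSegmenter(single, list(), "coarse"),
               class = "contractError")
})

test_that("the parity head's loss weight changes fine-stage training", {
  # parity-confusable fixture: two adjacent-position teeth per jaw
  sh <- c(16, 16, 16)
  lab <- array(0L, sh)
  lab[4:6, 4:6, 9:11] <- fdiToFineId(11)
  lab[10:12, 4:6, 9:11] <- fdiToFineId(12)
  lab[4:6, 10:12, 5:7] <- fdiToFineId(41)
  lab[10:12, 10:12, 5:7] <- fdiToFineId(42)
  vol <- array(40, sh); vol[lab > 0L] <- 1200
  pairs <- list(list(volume = newVolume(vol),
                     labels = newLabelMap(lab, "fine")))
  seg <- buildSegmenter(backboneConfig("dynamic_unet", c(33, 5), depth = 2,
                                       baseWidth = 4), seed = 9)
  cfg <- trainConfig(epochs = 3, patchSize = 16, patchesPerSample = 2,
                     seed = 21)
  rA <- trainSegmenter(seg, pairs, "fine", cfg, fineLossConfig(1, 0))
  rB <- trainSegmenter(seg, pairs, "fine", cfg, fineLossConfig(0.5, 0.5))
  expect_true(all(is.finite(rA$history$loss)))
  expect_true(all(is.finite(rB$history$loss)))
  # the 5-class term couples into the objective: the curves differ
  expect_false(isTRUE(all.equal(rA$history$loss, rB$history$loss)))
})
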