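test_that("the dentition ROI is the margin-dilated half-open bounding box", {
  lab <- array(0L, c(40, 40, 40))
  lab[11:21, 11:21, 11:21] <- 8L          # teeth at 0-based 10..20 inclusive
  box <- extractTeethROI(newLabelMap(lab, "coarse"), margin = 2)
  expect_identical(box@lower, c(8L, 8L, 8L))
  expect_identical(box@upper, c(23L, 23L, 23L))
})

test_that("the ROI box clips at the grid boundary", {
  lab <- array(0L, c(30, 30, 30))
  lab[1:4, 28:30, 1:4] <- 9L
  box <- extractTeethROI(newLabelMap(lab, "coarse"), margin = 5)
  expect_identical(box@lower, c(0L, 22L, 0L))
  expect_identical(box@upper, c(9L, 30L, 9L))
})

test_that("every tooth voxel lies inside the extracted box (exhaustive)", {
  set.seed(41)
  for (rep_ in 1:10) {
    lab <- array(0L, c(24, 24, 24))
    vox <- sample(24^3, 50)
    lab[vox] <- sample(c(8L, 9L), 50, replace = TRUE)
    box <- extractTeethROI(newLabelMap(lab, "coarse"), margin = 0)
    co <- arrayInd(which(lab %in% c(8L, 9L)), dim(lab)) - 1L
    for (ax in 1:3) {
      expect_true(all(co[, ax] >= box@lower[ax]))
      expect_true(all(co[, ax] < box@upper[ax]))
    }
  }
})

test_that("an empty dentition raises the empty-foreground error", {
  lab <- array(0L, c(16, 16, 16)); lab[5, 5, 5] <- 3L
  expect_error(extractTeethROI(newLabelMap(lab, "coarse")),
               class = "emptyForegroundError")
})

test_that("crop with target equal to box shape is bit-identical", {
  p <- cachedPhantom(seed = 1, shape = 48L)
  box <- extractTeethROI(p@coarse, margin = 3)
  out <- cropResample(p@volume, p@fine, box)
  ext <- box@upper - box@lower
  expect_equal(dim(voxels(out$volume)), unname(ext))
  manual <- voxels(p@volume)[box@lower[1] + seq_len(ext[1]),
                             box@lower[2] + seq_len(ext[2]),
                             box@lower[3] + seq_len(ext[3])]
  expect_identical(voxels(out$volume), manual)
  manualLab <- voxels(p@fine)[box@lower[1] + seq_len(ext[1]),
                              box@lower[2] + seq_len(ext[2]),
                              box@lower[3] + seq_len(ext[3])]
  expect_identical(voxels(out$labels), manualLab)
})

test_that("nearest-neighbour downscaling never invents label ids", {
  checker <- array(0L, c(16, 16, 16))
  checker[] <- as.integer((outer(1:16, 1:16, `+`) %% 2))  # ids {0,1}
  lm <- newLabelMap(checker, "coarse")
  box <- new("ROIBox", lower = c(0L, 0L, 0L), upper = c(16L, 16L, 16L),
             sourceShape = c(16L, 16L, 16L), targetShape = c(8L, 8L, 8L))
  out <- cropResample(NULL, lm, box)
  expect_true(all(voxels(out$labels) %in% unique(as.vector(checker))))
  expect_error(cropResample(NULL, lm, box, target = c(0, 4, 4)),
               class = "sizeError")
})

test_that("world coordinates stay correct through crop and resample", {
  aff <- rbind(c(0.5, 0, 0, -20), c(0, 0.5, 0, 10), c(0, 0, 0.8, 5),
               c(0, 0, 0, 1))
  v <- newVolume(array(rnorm(20^3), c(20, 20, 20)),
                 spacing = c(0.5, 0.5, 0.8), transform = aff)
  box <- new("ROIBox", lower = c(4L, 6L, 8L), upper = c(12L, 14L, 16L),
             sourceShape = c(20L, 20L, 20L), targetShape = c(8L, 8L, 8L))
  out <- cropResample(v, NULL, box)
  # pure crop: world of output (0,0,0) equals world of input lower corner
  expect_equal(voxelToWorld(worldTransform(out$volume), c(0, 0, 0)),
               voxelToWorld(aff, c(4, 6, 8)))
  # downscale by 2: output voxel centres sit between input centres
  out2 <- cropResample(v, NULL, box, target = c(4, 4, 4))
  expect_equal(voxelToWorld(worldTransform(out2$volume), c(0, 0, 0)),
               voxelToWorld(aff, c(4.5, 6.5, 8.5)))
})

test_that("paste after crop restores the labels inside the box", {
  p <- cachedPhantom(seed = 2, shape = 48L)
  box <- extractTeethROI(p@coarse, margin = 2)
  roi <- cropResample(NULL, p@fine, box)
  back <- pasteBack(roi$labels, box, dim(voxels(p@fine)))
  ext <- box@upper - box@lower
  inBox <- voxels(back)[box@lower[1] + seq_len(ext[1]),
                        box@lower[2] + seq_len(ext[2]),
                        box@lower[3] + seq_len(ext[3])]
  orig <- voxels(p@fine)[box@lower[1] + seq_len(ext[1]),
                         box@lower[2] + seq_len(ext[2]),
                         box@lower[3] + seq_len(ext[3])]
  expect_identical(inBox, orig)
  outside <- voxels(back)
  outside[box@lower[1] + seq_len(ext[1]), box@lower[2] + seq_len(ext[2]),
          box@lower[3] + seq_len(ext[3])] <- 0L
  expect_true(all(outside == 0L))

  # all-background ROI pastes to an all-background map
  bg <- newLabelMap(array(0L, unname(ext)), "fine")
  expect_true(all(voxels(pasteBack(bg, box, c(48, 48, 48))) == 0L))

  # downscale-then-paste: label-set closure
  box2 <- box
  box2@targetShape <- as.integer(pmax(ext %/% 2L, 1L))
  roi2 <- cropResample(NULL, p@fine, box2)
  back2 <- pasteBack(roi2$labels, box2, c(48, 48, 48))
  expect_true(all(unique(as.vector(voxels(back2))) %in%
                    c(0L, unique(as.vector(voxels(roi2$labels))))))
})

test_that("coarse argmax respects the lowest-id tie-break", {
  sh <- c(3, 3, 3)
  p <- array(0, c(sh, 10))
  p[, , , 3] <- 0.4; p[, , , 4] <- 0.4   # exact tie classes 2 and 3
  p[, , , 1] <- 0.2
  expect_true(all(cmfelseg:::.argmaxClasses(p) == 2L))
})

test_that("the parity correction fixes a planted misidentification", {
  fx <- mkParityFixture(seed = 1)
  corrected <- combinationCorrect(fx$p33, fx$p5, tau = 0.6)
  # the planted component must carry its true id again
  plantedVox <- which(voxels(fx$truthMap) == fx$trueId)
  expect_true(all(voxels(corrected)[plantedVox] == fx$trueId))
  # all other teeth keep their ids
  for (id in setdiff(unique(as.vector(voxels(fx$truthMap))), c(0L, fx$trueId)))
    expect_true(all(voxels(corrected)[voxels(fx$truthMap) == id] == id))
})

test_that("the correction is gated by the confidence threshold", {
  fx <- mkParityFixture(seed = 2)
  untouched <- combinationCorrect(fx$p33, fx$p5, tau = 1.0)
  expect_identical(voxels(untouched),
                   cmfelseg:::.argmaxClasses(voxels(fx$p33)))
})

test_that("parity-consistent components are never changed (idempotence)", {
  fx <- mkParityFixture(seed = 3, planted = FALSE)
  once <- combinationCorrect(fx$p33, fx$p5, tau = 0.6)
  expect_identical(voxels(once), cmfelseg:::.argmaxClasses(voxels(fx$p33)))
  # applying the correction to an already-consistent result changes nothing
  fx2 <- mkParityFixture(seed = 4)
  corrected <- combinationCorrect(fx2$p33, fx2$p5, tau = 0.6)
  pCorr <- probFromLabels(voxels(corrected), 33L, conf = 0.9)
  again <- combinationCorrect(pCorr, fx2$p5, tau = 0.6)
  expect_identical(voxels(again), voxels(corrected))
})

test_that("the cascade equals its manual stage composition", {
  p <- cachedPhantom(seed = 1, shape = 48L)
  cfg <- loadPipelineConfig()
  coarseSeg <- buildSegmenter(backboneConfig("dynamic_unet", 10, depth = 2,
                                             baseWidth = 4), seed = 1)
  fineSeg <- buildSegmenter(backboneConfig("dynamic_unet", c(33, 5),
                                           depth = 2, baseWidth = 4),
                            seed = 2)
  res <- runCascade(coarseSeg, fineSeg, p@volume, cfg)

  cs <- segmentCoarse(coarseSeg, p@volume)
  box <- tryCatch(extractTeethROI(cs$labels, cfg@roiMargin),
                  emptyForegroundError = function(e) NULL)
  if (is.null(box)) {
    expect_true(res@roiFallback)
  } else {
    box@targetShape <- rep(cfg@fineTargetShape, 3L)
    roi <- cropResample(p@volume, NULL, box)
    fine <- segmentFine(fineSeg, roi$volume)
    corrected <- combinationCorrect(fine$p33, fine$p5, cfg@tau)
    manual <- pasteBack(corrected, box, dim(voxels(p@volume)),
                        spacing(p@volume), worldTransform(p@volume))
    expect_identical(voxels(res@coarse), voxels(cs$labels))
    expect_identical(voxels(res@fine), voxels(manual))
    expect_identical(res@roi@lower, box@lower)
  }
})

test_that("an empty dentition volume takes the flagged whole-volume fallback", {
  flat <- newVolume(array(rnorm(32^3, 0, 1), c(32, 32, 32)))
  coarseSeg <- buildSegmenter(backboneConfig("dynamic_unet", 10, depth = 2,
                                             baseWidth = 4), seed = 5)
  # zero weights -> uniform probabilities -> argmax all background
  coarseSeg@params <- cmfelseg:::.paramZeros(coarseSeg@params)
  fineSeg <- buildSegmenter(backboneConfig("dynamic_unet", c(33, 5),
                                           depth = 2, baseWidth = 4),
                            seed = 6)
  cfg <- loadPipelineConfig()
  res <- runCascade(coarseSeg, fineSeg, flat, cfg)
  expect_true(res@roiFallback)
  expect_true(all(voxels(res@coarse) == 0L))
  expect_identical(res@roi@lower, c(0L, 0L, 0L))
})

test_that("model contract violations carry their stage tag", {
  p <- cachedPhantom(seed = 1, shape = 32L)
  wrongCoarse <- buildSegmenter(backboneConfig("dynamic_unet", c(33, 5),
                                               depth = 2, baseWidth = 4),
                                seed = 1)
  err <- tryCatch(runCascade(wrongCoarse, wrongCoarse, p@volume),
                  cmfelsegError = identity)
  expect_match(conditionMessage(err), "stage coarse")
})

test_that("the dual heads share a decoder: perturbing input moves both", {
  seg <- buildSegmenter(backboneConfig("dynamic_unet", c(33, 5), depth = 2,
                                       baseWidth = 4), seed = 3)
  v <- newVolume(array(rnorm(16^3, 700, 200), c(16, 16, 16)))
  base <- segmentFine(seg, v)
  bumped <- v
  bumped@data[8, 8, 8] <- bumped@data[8, 8, 8] + 500
  pert <- segmentFine(seg, bumped)
  expect_gt(max(abs(voxels(pert$p33) - voxels(base$p33))), 0)
  expect_gt(max(abs(voxels(pert$p5) - voxels(base$p5))), 0)
  # both maps share the ROI grid and the simplex invariant
  for (pm in list(pert$p33, pert$p5)) {
    expect_equal(dim(voxels(pm))[1:3], c(16, 16, 16))
    s <- rowSums(matrix(voxels(pm), 16^3, dim(voxels(pm))[4]))
    expect_lt(max(abs(s - 1)), 1e-6)
  }
})
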