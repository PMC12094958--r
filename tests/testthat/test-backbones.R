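test_that("all families satisfy the output-shape and simplex contract", {
  v <- newVolume(array(rnorm(16^3, 700, 100), c(16, 16, 16)))
  for (fam in c("residual_unet", "dynamic_unet", "large_kernel_unet")) {
    seg <- buildSegmenter(backboneConfig(fam, 10, depth = 2, baseWidth = 4),
                          seed = 1)
    pm <- slidingWindowPredict(seg, v)
    expect_s4_class(pm, "ProbabilityMap")
    expect_equal(dim(voxels(pm)), c(16, 16, 16, 10))
    s <- rowSums(matrix(voxels(pm), 16^3, 10))
    expect_lt(max(abs(s - 1)), 1e-6)     # even untrained
  }
})

test_that("initialization is deterministic per seed", {
  cfg <- backboneConfig("residual_unet", 10, depth = 2, baseWidth = 4)
  a <- buildSegmenter(cfg, seed = 9)
  b <- buildSegmenter(cfg, seed = 9)
  expect_identical(a@params, b@params)
  c_ <- buildSegmenter(cfg, seed = 10)
  expect_false(identical(a@params$stem$c$w, c_@params$stem$c$w))
})

test_that("unknown family and invalid configs are configuration errors", {
  expect_error(backboneConfig("foo", 10), class = "configurationError")
  expect_error(backboneConfig("dynamic_unet", 10, depth = 1),
               class = "configurationError")
  expect_error(backboneConfig("large_kernel_unet", 10, kernelSize = 4),
               class = "configurationError")
})

test_that("depthwise spatial mixing uses C*k^3 parameters, dense uses C^2*k^3", {
  k <- 7L
  seg <- buildSegmenter(backboneConfig("large_kernel_unet", 10, depth = 2,
                                       baseWidth = 8, kernelSize = k),
                        seed = 1)
  for (l in 1:2) {
    dw <- seg@params$enc[[l]]$dw
    C <- length(dw$b)
    expect_equal(length(dw$w), C * k^3)          # depthwise weights
    expect_lt(length(dw$w), C^2 * k^3)           # strictly below dense
  }
})

test_that("inference is deterministic for fixed weights and input", {
  v <- newVolume(array(rnorm(16^3), c(16, 16, 16)))
  seg <- buildSegmenter(backboneConfig("dynamic_unet", 10, depth = 2,
                                       baseWidth = 4), seed = 2)
  a <- slidingWindowPredict(seg, v)
  b <- slidingWindowPredict(seg, v)
  expect_identical(voxels(a), voxels(b))
})

test_that("volumes smaller than the patch are padded and cropped back", {
  v <- newVolume(array(rnorm(10 * 12 * 9), c(10, 12, 9)))
  seg <- buildSegmenter(backboneConfig("dynamic_unet", 10, depth = 2,
                                       baseWidth = 4), seed = 3)
  pm <- slidingWindowPredict(seg, v, patch = 16)
  expect_equal(dim(voxels(pm))[1:3], c(10, 12, 9))
})

test_that("sliding-window blending weights normalize to 1 everywhere", {
  w <- slidingWindowWeights(c(48, 48, 48), patch = 32, overlap = 0.5)
  expect_lt(max(abs(w - 1)), 1e-6)
  w2 <- slidingWindowWeights(c(40, 48, 56), patch = 16, overlap = 0.25)
  expect_lt(max(abs(w2 - 1)), 1e-6)
})

test_that("blending preserves a constant model's uniform output", {
  # a segmenter whose weights are all zero emits the uniform distribution
  seg <- buildSegmenter(backboneConfig("dynamic_unet", 10, depth = 2,
                                       baseWidth = 4, normalization = "none"),
                        seed = 1)
  seg@params <- cmfelseg:::.paramZeros(seg@params)
  v <- newVolume(array(rnorm(24^3), c(24, 24, 24)))
  pm <- slidingWindowPredict(seg, v, patch = 16, overlap = 0.5)
  expect_lt(max(abs(voxels(pm) - 0.1)), 1e-9)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(6)
  cfg <- backboneConfig("residual_unet", 3, depth = 2, baseWidth = 4)
  seg <- buildSegmenter(cfg, seed = 7)
  x <- array(rnorm(8^3 * 4), c(8, 8, 8, 4))
  lab <- array(sample(0:2, 8^3, TRUE), c(8, 8, 8))
  oh <- cmfelseg:::.oneHot(lab, 3L)
  lossOf <- function(params) {
    fw <- cmfelseg:::.unetFwd(cfg, params, x)
    p <- cmfelseg:::.softmax4(fw$logits[[1]])
    cmfelseg:::.softDice(p, oh, 1e-5)$loss
  }
  fw <- cmfelseg:::.unetFwd(cfg, seg@params, x, keepCache = TRUE)
  p <- cmfelseg:::.softmax4(fw$logits[[1]])
  sd1 <- cmfelseg:::.softDice(p, oh, 1e-5, grad = TRUE)
  gp <- cmfelseg:::.unetBwd(cfg, seg@params, fw$cache,
                            list(cmfelseg:::.softmaxBwd(p, sd1$gprobs)))
  bump <- function(params, path, i, d) {
    rec <- function(lst, pth) {
      if (length(pth) == 1L) {
        lst[[pth[[1L]]]][i] <- lst[[pth[[1L]]]][i] + d
        return(lst)
      }
      lst[[pth[[1L]]]] <- rec(lst[[pth[[1L]]]], pth[-1L])
      lst
    }
    rec(params, path)
  }
  paths <- list(list("stem", "c", "w"), list("enc", 1L, "u1", "c", "w"),
                list("down", 1L, "c", "w"), list("dec", 1L, "up", "c", "w"),
                list("heads", 1L, "w"), list("stem", "n", "g"))
  for (pa in paths) {
    garr <- gp
    for (s in pa) garr <- garr[[s]]
    i <- max(1L, length(garr) %/% 2L)
    eps <- 1e-5
    num <- (lossOf(bump(seg@params, pa, i, eps)) -
              lossOf(bump(seg@params, pa, i, -eps))) / (2 * eps)
    expect_equal(garr[i], num, tolerance = 1e-4)
  }
})

test_that("the three families are substitutable behind one contract", {
  p <- cachedPhantom(seed = 1, shape = 32L)
  for (fam in c("residual_unet", "dynamic_unet", "large_kernel_unet")) {
    seg <- buildSegmenter(backboneConfig(fam, 10, depth = 2, baseWidth = 4),
                          seed = 1)
    cs <- segmentCoarse(seg, p@volume)
    expect_s4_class(cs$labels, "LabelMap")
    expect_equal(scheme(cs$labels)@name, "coarse")
    expect_true(validObject(cs$labels, test = TRUE))
  }
})

test_that("checkpoints round-trip through save and load", {
  seg <- buildSegmenter(backboneConfig("large_kernel_unet", c(33, 5),
                                       depth = 2, baseWidth = 4), seed = 4)
  f <- withr::local_tempfile(fileext = ".rds")
  saveSegmenter(seg, f)
  back <- loadSegmenter(f)
  expect_identical(back@params, seg@params)
  expect_identical(back@config@family, "large_kernel_unet")
})
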