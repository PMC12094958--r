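# Shared fixtures, generated in code at test time.

# small, fast phantom spec used across tests
testSpec <- function(shape = 64L, ...) {
  args <- modifyList(list(shape = shape, missingProb = 0, noiseSigma = 30),
                     list(...))
  do.call(phantomSpec, args)
}

# cache phantoms across tests within one run
.phantomCache <- new.env(parent = emptyenv())
cachedPhantom <- function(seed = 1L, shape = 64L, ...) {
  key <- paste0(seed, "-", shape, "-", paste(c(...), collapse = "_"))
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- generatePhantom(testSpec(shape, ...), seed = seed)
  .phantomCache[[key]]
}

# a simplex-valid random probability array (x, y, z, K)
randomProbArray <- function(shape, K, seed = 1L) {
  set.seed(seed)
  a <- array(stats::rexp(prod(shape) * K), c(shape, K))
  s <- rowSums(matrix(a, prod(shape), K))
  a / array(s, dim(a))
}

randomProbMap <- function(shape, scheme, seed = 1L) {
  K <- length(labelScheme(scheme)@ids)
  newProbabilityMap(randomProbArray(shape, K, seed), scheme)
}

# probability map that puts mass `conf` on the labelled class per voxel and
# spreads the rest uniformly
probFromLabels <- function(lab, K, conf = 0.9) {
  oh <- cmfelseg:::.oneHot(lab, K)
  p <- oh * conf + (1 - conf) / K
  s <- rowSums(matrix(p, length(lab), K))
  newProbabilityMap(p / array(s, dim(p)),
                    switch(as.character(K), "33" = "fine", "5" = "parity",
                           "10" = "coarse"))
}

# noisy-oracle segmenter: corrupts ground-truth labels at a voxel error
# rate, assigning a random wrong class, and emits soft probabilities
noisyOracleLabels <- function(gt, errorRate, seed) {
  set.seed(seed)
  lab <- gt@data
  K <- nClasses(gt@scheme)
  n <- length(lab)
  flip <- which(stats::runif(n) < errorRate)
  if (length(flip)) {
    shift <- sample.int(K - 1L, length(flip), replace = TRUE)
    lab[flip] <- (lab[flip] + shift) %% K
  }
  lab
}

noisyOracleModel <- function(errorRate, seedBase, conf = 0.9,
                             stage = "coarse") {
  force(errorRate); force(seedBase); force(conf); force(stage)
  function(sample) {
    gt <- if (stage == "fine") sample@fine else sample@coarse
    lab <- noisyOracleLabels(gt, errorRate, seedBase + sample@seed)
    newLabelMap(lab, gt@scheme, gt@spacing, gt@transform)
  }
}

# --- parity-correction fixtures ---------------------------------------------
# delegate to the package-internal fixture builder so tests and the
# acceptance studies exercise identical constructions
mkParityFixture <- function(seed = 1L, planted = TRUE, conf5 = 0.95,
                            shape = c(20L, 20L, 20L)) {
  fx <- cmfelseg:::.parityFixture(seed = seed, planted = planted,
                                  conf5 = conf5, shape = shape)
  fx$truthMap <- newLabelMap(fx$truth, "fine")
  fx
}
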