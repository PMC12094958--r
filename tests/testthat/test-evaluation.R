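test_that("Dice and IoU reproduce set-overlap arithmetic", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2, 1, 1] <- TRUE                 # |A| = 2
  b[2:3, 1, 1] <- TRUE                 # |B| = 2, |A&B| = 1
  expect_equal(diceScore(a, b), 0.5)
  expect_equal(iouScore(a, b), 1 / 3)

  expect_equal(diceScore(a, a), 1)
  expect_equal(iouScore(a, a), 1)

  d <- array(FALSE, c(4, 4, 4)); d[4, 4, 4] <- TRUE
  expect_equal(diceScore(a, d), 0)
  expect_equal(iouScore(a, d), 0)

  # both empty: not applicable, never a silent 0 or 1
  e <- array(FALSE, c(4, 4, 4))
  expect_true(is.na(diceScore(e, e)))
  expect_true(is.na(iouScore(e, e)))

  # symmetry
  expect_equal(diceScore(a, b), diceScore(b, a))
  expect_error(diceScore(a, array(FALSE, c(3, 3, 3))),
               class = "contractError")
})

test_that("per-class metrics match a brute-force counting oracle", {
  # independent oracle: explicit per-voxel triple loop counts
  bruteForce <- function(pred, gt, id) {
    np <- 0L; ng <- 0L; ni <- 0L
    d <- dim(pred)
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        p <- pred[i, j, k] == id
        g <- gt[i, j, k] == id
        np <- np + p; ng <- ng + g; ni <- ni + (p && g)
      }
    if (np + ng == 0) return(c(dice = NA_real_, iou = NA_real_))
    c(dice = 2 * ni / (np + ng), iou = ni / (np + ng - ni))
  }
  set.seed(21)
  for (rep_ in 1:5) {
    pred <- array(sample(0:32, 8^3, replace = TRUE), c(8, 8, 8))
    gt <- array(sample(0:32, 8^3, replace = TRUE), c(8, 8, 8))
    tab <- perClassMetrics(newLabelMap(pred, "fine"),
                           newLabelMap(gt, "fine"))
    expect_equal(nrow(tab), 32L)
    for (row in sample(nrow(tab), 6L)) {
      expected <- bruteForce(pred, gt, tab$classId[row])
      expect_equal(tab$dice[row], unname(expected["dice"]),
                   tolerance = 1e-12)
      expect_equal(tab$iou[row], unname(expected["iou"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("Dice and IoU satisfy their functional relation row-wise", {
  set.seed(22)
  pred <- array(sample(0:9, 10^3, replace = TRUE), c(10, 10, 10))
  gt <- array(sample(0:9, 10^3, replace = TRUE), c(10, 10, 10))
  tab <- perClassMetrics(newLabelMap(pred, "coarse"),
                         newLabelMap(gt, "coarse"))
  ok <- tab$applicable
  expect_true(all(abs(tab$dice[ok] - 2 * tab$iou[ok] / (1 + tab$iou[ok]))
                  < 1e-12))
})

test_that("identical maps score 1 and one-sided absences score 0 with flags", {
  p <- cachedPhantom(seed = 1, shape = 48L)
  tab <- perClassMetrics(p@coarse, p@coarse)
  expect_true(all(tab$dice[tab$applicable] == 1))
  expect_true(all(tab$iou[tab$applicable] == 1))

  empty <- newLabelMap(array(0L, dim(voxels(p@coarse))), "coarse")
  tab2 <- perClassMetrics(empty, p@coarse)
  present <- tab2$presentGT
  expect_true(all(tab2$dice[present] == 0))
  expect_false(any(tab2$presentPred))
  # absent from both: flagged not-applicable, excluded from aggregation
  expect_true(all(is.na(tab2$dice[!tab2$applicable])))
  agg <- aggregateMetrics(tab2)
  expect_false(any(is.na(agg$meanDice)))
})

test_that("surface deviation matches the shifted-cube closed form", {
  cube <- array(FALSE, c(9, 9, 9))
  cube[3:7, 3:7, 3:7] <- TRUE
  same <- surfaceDeviation(cube, cube)
  expect_equal(same$mean, 0)
  expect_equal(same$max, 0)

  shifted <- array(FALSE, c(9, 9, 9))
  shifted[3:7, 3:7, 4:8] <- TRUE       # +1 voxel along z
  dev <- surfaceDeviation(cube, shifted, spacing = c(1, 1, 1))
  expect_equal(dev$max, 1.0)

  # units linearity: doubling the spacing doubles the distances
  dev2 <- surfaceDeviation(cube, shifted, spacing = c(2, 2, 2))
  expect_equal(dev2$max, 2 * dev$max)
  expect_equal(dev2$mean, 2 * dev$mean)

  # brute-force all-pairs oracle on the toy cubes
  surf <- function(m) {
    s <- cmfelseg:::.surfaceVoxels(m)
    arrayInd(which(s), dim(m)) - 1L
  }
  A <- surf(cube); B <- surf(shifted)
  dAB <- apply(A, 1, function(a)
    min(sqrt(rowSums(sweep(B, 2, a)^2))))
  dBA <- apply(B, 1, function(b)
    min(sqrt(rowSums(sweep(A, 2, b)^2))))
  expect_equal(dev$max, max(dAB, dBA))
  expect_equal(dev$mean, mean(c(dAB, dBA)))

  emp <- surfaceDeviation(array(FALSE, c(4, 4, 4)), cube[1:4, 1:4, 1:4])
  expect_true(is.na(emp$mean))
  expect_match(emp$reason, "empty")
})

test_that("group comparison picks the documented test and direction", {
  set.seed(31)
  a <- rnorm(20, 0.9, 0.01)
  b <- rnorm(20, 0.5, 0.01)
  r <- compareGroups(a, b)
  expect_true(r$test %in% c("t-test", "Mann-Whitney U"))
  expect_lt(r$p.value, 0.05)

  # identical values, shuffled: no significance
  x <- c(0.1, 0.5, 0.9, 0.3, 0.7, 0.2, 0.8, 0.6, 0.4, 0.55)
  r2 <- compareGroups(x, sample(x))
  expect_gt(r2$p.value, 0.05)

  # zero-variance degenerate input falls back to the rank test
  r3 <- compareGroups(rep(0.9, 5), c(0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(r3$test, "Mann-Whitney U")

  expect_error(compareGroups(c(1, 2), c(1, 2, 3)),
               class = "sampleSizeError")
})

test_that("the grade rubric applies the worst-grade and all-A rules", {
  th <- c(A = 0.95, B = 0.90, C = 0.80)
  r <- gradeReport(c(skull = 1.0, mandible = 0.99, teeth = 0.97), th)
  expect_true(all(r@grades == "A"))
  expect_equal(r@overall, "A")

  r2 <- gradeReport(c(skull = 1.0, mandible = 0.92, teeth = 0.99), th)
  expect_equal(unname(r2@grades["mandible"]), "B")
  expect_equal(r2@overall, "B")

  r3 <- gradeReport(c(skull = 1.0, mandible = 0.92, teeth = 0.5), th)
  expect_equal(r3@overall, "D")

  # exhaustive: all 4^4 grade combinations of a 4-category fixture
  levelsDice <- c(A = 0.97, B = 0.92, C = 0.85, D = 0.4)
  for (i in names(levelsDice)) for (j in names(levelsDice))
    for (k in names(levelsDice)) for (l in names(levelsDice)) {
      gr <- gradeReport(c(a = levelsDice[[i]], b = levelsDice[[j]],
                          c = levelsDice[[k]], d = levelsDice[[l]]), th)
      grades <- c(i, j, k, l)
      expectedOverall <- if (all(grades == "A")) "A" else
        c("A", "B", "C", "D")[max(match(grades, c("A", "B", "C", "D")))]
      expect_identical(unname(gr@grades), grades)
      expect_identical(gr@overall, expectedOverall)
    }

  expect_error(gradeReport(c(x = 1), c(A = 0.9, B = 0.9, C = 0.8)),
               class = "configurationError")
})
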