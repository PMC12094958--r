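# Evaluation surface: per-class Dice and IoU, symmetric surface distances,
# two-group comparison tests and the four-grade quality rubric.

.binCounts <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    .stopWith("contractError", "masks must share one shape")
  p <- as.logical(pred)
  g <- as.logical(gt)
  c(np = sum(p), ng = sum(g), ni = sum(p & g))
}

#' Dice coefficient and IoU of two binary masks
#'
#' \code{Dice = 2|A&B| / (|A| + |B|)}, \code{IoU = |A&B| / |A|B|union|};
#' when both masks are empty there is nothing to score and \code{NA}
#' (not-applicable) is returned rather than a silent 0 or 1.
#'
#' @param pred,gt binary masks (logical or 0/1 arrays) of equal shape
#' @return scalar in [0, 1], or NA when both masks are empty
#' @export
diceScore <- function(pred, gt) {
  n <- .binCounts(pred, gt)
  if (n["np"] + n["ng"] == 0) return(NA_real_)
  unname(2 * n["ni"] / (n["np"] + n["ng"]))
}

#' @rdname diceScore
#' @export
iouScore <- function(pred, gt) {
  n <- .binCounts(pred, gt)
  u <- n["np"] + n["ng"] - n["ni"]
  if (u == 0) return(NA_real_)
  unname(n["ni"] / u)
}

#' Per-class Dice and IoU between two label maps
#'
#' One row per foreground class of the scheme. Classes absent from both
#' maps get NA scores and \code{applicable = FALSE}; they are excluded from
#' aggregation rather than silently counted as perfect. Row-wise,
#' \code{dice == 2*iou/(1+iou)} to 1e-12.
#'
#' @param pred,gt \linkS4class{LabelMap}s on the same grid and scheme
#' @param sampleId optional sample identifier recorded per row
#' @return a data.frame with columns sampleId, scheme, classId, classLabel,
#'   dice, iou, presentGT, presentPred, applicable
#' @export
perClassMetrics <- function(pred, gt, sampleId = NA_character_) {
  stopifnot(is(pred, "LabelMap"), is(gt, "LabelMap"))
  if (pred@scheme@name != gt@scheme@name)
    .stopWith("contractError", "pred and gt must share one scheme")
  .checkSameGrid(pred, gt, "pred and gt")
  ids <- pred@scheme@ids
  K <- length(ids)
  pv <- as.vector(pred@data)
  gv <- as.vector(gt@data)
  # joint tabulation: one pass over the voxels
  np <- tabulate(pv + 1L, nbins = K)
  ng <- tabulate(gv + 1L, nbins = K)
  ni <- tabulate(pv[pv == gv] + 1L, nbins = K)
  fg <- seq_len(K)[-1L]
  denom <- np[fg] + ng[fg]
  union_ <- denom - ni[fg]
  dice <- ifelse(denom > 0, 2 * ni[fg] / denom, NA_real_)
  iou <- ifelse(union_ > 0, ni[fg] / union_, NA_real_)
  data.frame(sampleId = sampleId, scheme = pred@scheme@name,
             classId = ids[fg], classLabel = pred@scheme@labels[fg],
             dice = dice, iou = iou,
             presentGT = ng[fg] > 0L, presentPred = np[fg] > 0L,
             applicable = denom > 0L,
             stringsAsFactors = FALSE)
}

#' Aggregate a metric table to per-class mean and standard deviation
#'
#' Not-applicable rows (class absent from both maps) are excluded.
#'
#' @param metrics a data.frame from \code{perClassMetrics} (rows from
#'   several samples may be concatenated)
#' @return a data.frame with per-class n, meanDice, sdDice, meanIoU, sdIoU
#' @export
aggregateMetrics <- function(metrics) {
  app <- metrics[metrics$applicable, , drop = FALSE]
  if (!nrow(app))
    return(data.frame(classId = integer(), classLabel = character(),
                      n = integer(), meanDice = numeric(),
                      sdDice = numeric(), meanIoU = numeric(),
                      sdIoU = numeric()))
  sp <- split(app, app$classId)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(classId = d$classId[1L], classLabel = d$classLabel[1L],
               n = nrow(d), meanDice = mean(d$dice), sdDice = sd(d$dice),
               meanIoU = mean(d$iou), sdIoU = sd(d$iou))))
  rownames(out) <- NULL
  out[order(out$classId), , drop = FALSE]
}

# surface voxels: mask minus its 6-neighbourhood erosion (outside counts as
# background, so boundary voxels of the grid are surface)
.surfaceVoxels <- function(mask) {
  sh <- dim(mask)
  m <- array(as.logical(mask), sh)
  shifted <- function(dx, dy, dz) {
    out <- array(FALSE, sh)
    xs <- seq_len(sh[1L]); ys <- seq_len(sh[2L]); zs <- seq_len(sh[3L])
    sx <- xs + dx; sy <- ys + dy; sz <- zs + dz
    okx <- sx >= 1L & sx <= sh[1L]
    oky <- sy >= 1L & sy <= sh[2L]
    okz <- sz >= 1L & sz <= sh[3L]
    out[xs[okx], ys[oky], zs[okz]] <- m[sx[okx], sy[oky], sz[okz]]
    out
  }
  inner <- m
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    inner <- inner & shifted(d[1L], d[2L], d[3L])
  m & !inner
}

#' Symmetric surface distance between two binary masks
#'
#' Surface voxels are each mask minus its 6-neighbourhood erosion;
#' distances are computed in both directions between the two surface sets,
#' in mm via the voxel spacing, and summarized. Distances scale linearly
#' with spacing.
#'
#' @param pred,gt nonempty binary masks of equal shape
#' @param spacing voxel spacing in mm
#' @return \code{list(mean = , max = , n = )}: mean and maximum symmetric
#'   surface distance (mm) and the number of surface voxel pairs scored;
#'   an empty mask yields \code{list(mean = NA, max = NA, reason = ...)}
#' @export
surfaceDeviation <- function(pred, gt, spacing = c(1, 1, 1)) {
  if (!all(dim(pred) == dim(gt)))
    .stopWith("contractError", "masks must share one shape")
  if (!any(as.logical(pred)) || !any(as.logical(gt)))
    return(list(mean = NA_real_, max = NA_real_,
                reason = "empty mask: surface distance not applicable"))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  coordsOf <- function(mask) {
    s <- .surfaceVoxels(mask)
    co <- arrayInd(which(s), dim(mask)) - 1L
    sweep(co, 2L, spacing, `*`)
  }
  a <- coordsOf(pred)
  b <- coordsOf(gt)
  dab <- min_distances_cpp(a, b)
  dba <- min_distances_cpp(b, a)
  list(mean = mean(c(dab, dba)), max = max(dab, dba),
       n = length(dab) + length(dba))
}

#' Compare two groups of continuous values
#'
#' Normality is assessed per group with the Shapiro-Wilk test at 0.05;
#' when both groups pass, a two-sample t-test is used, otherwise the
#' Mann-Whitney U (Wilcoxon rank-sum) test. Zero-variance degenerate input
#' falls back to the rank test.
#'
#' @param a,b numeric vectors with at least 3 values each
#' @param alpha significance level reported alongside (default 0.05)
#' @return \code{list(test = "t-test" | "Mann-Whitney U", statistic = ,
#'   p.value = , significant = )}
#' @export
compareGroups <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    .stopWith("sampleSizeError", "both groups need at least 3 values")
  degenerate <- sd(a) == 0 || sd(b) == 0
  normal <- !degenerate &&
    shapiro.test(a)$p.value > 0.05 && shapiro.test(b)$p.value > 0.05
  if (normal) {
    ht <- t.test(a, b)
    test <- "t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b))
    test <- "Mann-Whitney U"
  }
  list(test = test, statistic = unname(ht$statistic),
       p.value = ht$p.value, significant = ht$p.value < alpha)
}

#' Four-grade quality rubric from per-category Dice
#'
#' Per-category grades by Dice cut-off (defaults: A >= 0.95, B >= 0.90,
#' C >= 0.80, else D) — an automated proxy for human grading, and labeled
#' as such. The overall grade is "A" only if every category is "A";
#' otherwise it is the worst category grade.
#'
#' @param metrics a data.frame from \code{perClassMetrics} (possibly
#'   several samples), or a named numeric vector of per-category Dice
#' @param thresholds strictly decreasing named cut-offs c(A=, B=, C=)
#' @return a \linkS4class{GradeReport}
#' @export
gradeReport <- function(metrics, thresholds = c(A = 0.95, B = 0.90,
                                                C = 0.80)) {
  if (!all(c("A", "B", "C") %in% names(thresholds)) ||
      !(thresholds["A"] > thresholds["B"] &&
          thresholds["B"] > thresholds["C"]))
    .stopWith("configurationError",
              "thresholds must be strictly decreasing A > B > C")
  if (is.data.frame(metrics)) {
    agg <- aggregateMetrics(metrics)
    dice <- stats::setNames(agg$meanDice, agg$classLabel)
  } else {
    dice <- metrics
    if (is.null(names(dice)))
      names(dice) <- sprintf("category-%d", seq_along(dice))
  }
  gradeOf <- function(d) {
    if (d >= thresholds["A"]) "A"
    else if (d >= thresholds["B"]) "B"
    else if (d >= thresholds["C"]) "C"
    else "D"
  }
  grades <- vapply(dice, gradeOf, character(1L))
  overall <- if (all(grades == "A")) "A" else
    c("D", "C", "B")[min(match(grades, c("D", "C", "B"), nomatch = 4L))]
  new("GradeReport", grades = grades, overall = overall,
      thresholds = thresholds)
}
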