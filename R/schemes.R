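# Label taxonomies. The coarse scheme follows the fixed structure listing
# (background, facial soft tissue, upper skull, mandible, cervical vertebra,
# hyoid, pharyngeal cavity, inferior alveolar nerve, upper teeth, lower
# teeth). The fine scheme maps FDI codes sorted ascending to ids 1..32.

.COARSE_LABELS <- c("background", "facial soft tissue", "upper skull",
                    "mandible", "cervical vertebra", "hyoid",
                    "pharyngeal cavity", "inferior alveolar nerve",
                    "upper teeth", "lower teeth")
.PARITY_LABELS <- c("background", "upper-odd", "upper-even",
                    "lower-odd", "lower-even")

# coarse ids for the dentition foreground
.COARSE_UPPER_TEETH <- 8L
.COARSE_LOWER_TEETH <- 9L

#' All 32 FDI tooth codes in ascending order
#'
#' Two-digit FDI codes: quadrant digit 1-4 (1 upper right, 2 upper left,
#' 3 lower left, 4 lower right) and position digit 1-8 (central incisor to
#' third molar). Ascending FDI order defines fine-scheme ids 1..32.
#'
#' @return integer vector of the 32 codes
#' @export
fdiCodes <- function() {
  as.integer(outer(1:8, c(10L, 20L, 30L, 40L), `+`))
}

#' Convert between FDI codes and fine-scheme class ids
#'
#' @param id fine-scheme class ids in 1..32
#' @param code FDI codes (11..18, 21..28, 31..38, 41..48)
#' @return the corresponding codes or ids
#' @export
fineIdToFdi <- function(id) {
  id <- as.integer(id)
  if (any(is.na(id)) || any(id < 1L | id > 32L))
    stop("fine tooth ids must lie in 1..32")
  fdiCodes()[id]
}

#' @rdname fineIdToFdi
#' @export
fdiToFineId <- function(code) {
  code <- as.integer(code)
  m <- match(code, fdiCodes())
  if (any(is.na(m)))
    stop("invalid FDI code(s): ", paste(code[is.na(m)], collapse = ", "))
  m
}

#' Construct a canonical label scheme
#'
#' @param name "coarse" (10 classes), "fine" (33 classes) or "parity"
#'   (5 classes)
#' @return a \linkS4class{LabelScheme}
#' @examples
#' labelScheme("parity")
#' @export
labelScheme <- function(name = c("coarse", "fine", "parity")) {
  name <- match.arg(name)
  switch(name,
    coarse = new("LabelScheme", name = "coarse", ids = 0:9,
                 labels = .COARSE_LABELS),
    fine = new("LabelScheme", name = "fine", ids = 0:32,
               labels = c("background", paste0("FDI ", fdiCodes()))),
    parity = new("LabelScheme", name = "parity", ids = 0:4,
                 labels = .PARITY_LABELS))
}

#' Jaw/parity group of an FDI tooth code
#'
#' Teeth fall into four groups by jaw (quadrants 1-2 upper, 3-4 lower) and
#' the parity of the FDI position digit: upper-odd (1), upper-even (2),
#' lower-odd (3), lower-even (4). The mapping depends only on the jaw and
#' the last-digit parity.
#'
#' @param fdi vector of FDI codes
#' @return integer parity-scheme class ids (1..4), named by group label
#' @examples
#' parityGroup(c(11, 28, 47))
#' @export
parityGroup <- function(fdi) {
  fdi <- as.integer(fdi)
  quadrant <- fdi %/% 10L
  pos <- fdi %% 10L
  bad <- is.na(fdi) | quadrant < 1L | quadrant > 4L | pos < 1L | pos > 8L
  if (any(bad))
    stop("invalid FDI code(s): ", paste(unique(fdi[bad]), collapse = ", "))
  upper <- quadrant <= 2L
  odd <- pos %% 2L == 1L
  out <- ifelse(upper, ifelse(odd, 1L, 2L), ifelse(odd, 3L, 4L))
  names(out) <- .PARITY_LABELS[out + 1L]
  out
}

# parity id of every fine-scheme id 1..32 (lookup table)
.parityOfFineId <- function() parityGroup(fdiCodes())

#' Derive the 5-class parity label map from a fine label map
#'
#' Applies the jaw/parity grouping voxel-wise: background stays background,
#' each FDI tooth id maps to its upper/lower odd/even group. This is how the
#' 5-class ground truth of the dual-head fine stage is constructed from the
#' 33-class ground truth.
#'
#' @param fine a \linkS4class{LabelMap} on the fine scheme
#' @return a \linkS4class{LabelMap} on the parity scheme
#' @export
deriveParityLabels <- function(fine) {
  stopifnot(is(fine, "LabelMap"))
  if (fine@scheme@name != "fine")
    stop("deriveParityLabels expects a fine-scheme label map")
  lut <- c(0L, unname(.parityOfFineId()))   # index by fine id + 1
  out <- fine@data
  out[] <- lut[fine@data + 1L]
  newLabelMap(out, labelScheme("parity"), fine@spacing, fine@transform)
}
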