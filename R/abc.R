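## Deterministic modified ABC sinus-augmentation classification.
## Five surgical approaches keyed on residual bone height (RBH, the
## crest-to-sinus-floor distance) and on the presence of a horizontal or
## vertical ridge defect:
##   A  : RBH greater than 10 mm            -> implant placement alone
##   B  : RBH 6-9 mm                        -> osteotome (transcrestal) elevation
##   B' : RBH 6-9 mm with ridge defect      -> osteotome + GBR
##   C  : RBH 5 mm or less                  -> lateral wall sinus elevation
##   C' : RBH 5 mm or less with defect      -> lateral wall sinus elevation + GBR
## The published anchors leave (5,6) and (9,10] mm unassigned; the package
## completes them monotonically as C: (0,5], B: (5,10], A: (10,Inf), the only
## completion consistent with the anchors; boundaries are configurable.

.PROCEDURES <- c(
  "A"  = "Implant placement",
  "B"  = "Osteotome",
  "B'" = "Osteotome + GBR",
  "C"  = "Lateral wall sinus elevation",
  "C'" = "Lateral wall sinus elevation + GBR")

#' Recommended surgical procedure for a class
#'
#' @param class one of `"A"`, `"B"`, `"B'"`, `"C"`, `"C'"`.
#' @return The recommended procedure string.
#' @examples
#' procedureFor("B'")
#' @export
procedureFor <- function(class) {
  if (!all(class %in% SURGICAL_CLASSES))
    .err("unknown surgical class", "sinusplan_bad_class")
  unname(.PROCEDURES[class])
}

#' Classify residual bone height into a surgical class
#'
#' Maps an RBH measurement and a defect flag to one of the five surgical
#' classes.  Class A ignores the defect flag (abundant bone needs no
#' adjunct grafting in this scheme).
#'
#' @param rbh residual bone height in mm (positive, finite); vectorised.
#' @param defect logical; is a horizontal or vertical ridge defect present?
#' @param boundaries numeric(2), the C/B and B/A change points in mm
#'   (default `c(5, 10)`): class C for `rbh <= boundaries[1]`, B for
#'   `boundaries[1] < rbh <= boundaries[2]`, A above.
#' @return Character vector of classes in `{A, B, B', C, C'}` with the
#'   recommended procedure(s) attached as attribute `"procedure"`.
#' @examples
#' classifyRBH(11, FALSE)  # "A"
#' classifyRBH(7, TRUE)    # "B'"
#' @export
classifyRBH <- function(rbh, defect = FALSE, boundaries = c(5, 10)) {
  if (any(!is.finite(rbh)) || any(rbh <= 0))
    .err("rbh must be positive and finite (mm)", "sinusplan_bad_rbh")
  n <- max(length(rbh), length(defect))
  rbh <- rep_len(rbh, n); defect <- rep_len(as.logical(defect), n)
  cls <- ifelse(rbh > boundaries[2], "A",
         ifelse(rbh > boundaries[1], ifelse(defect, "B'", "B"),
                                     ifelse(defect, "C'", "C")))
  attr(cls, "procedure") <- procedureFor(cls)
  cls
}

#' Assess horizontal/vertical ridge defects from landmarks
#'
#' A horizontal defect is a ridge width |MH-LH| below `thresholds@minWidth`;
#' a vertical defect is a crest step |AC-CEJ| above `thresholds@maxStep`.
#'
#' @param landmarks a [LandmarkSet-class] containing MH, LH, AC and CEJ.
#' @param thresholds a [DefectThresholds-class].
#' @return Logical flag with attribute `"kind"` in
#'   `c("none", "horizontal", "vertical", "combined")`.
#' @export
assessDefect <- function(landmarks, thresholds = defectThresholds()) {
  cc <- landmarks@coords
  need <- c("MH", "LH", "AC", "CEJ")
  if (!all(need %in% rownames(cc)))
    .err(paste0("missing landmark(s): ",
                paste(setdiff(need, rownames(cc)), collapse = ", ")),
         "sinusplan_missing_landmark")
  width <- sqrt(sum((cc["MH", ] - cc["LH", ])^2))
  step  <- sqrt(sum((cc["AC", ] - cc["CEJ", ])^2))
  h <- width < thresholds@minWidth
  v <- step > thresholds@maxStep
  out <- h || v
  attr(out, "kind") <- if (h && v) "combined" else if (h) "horizontal" else
                       if (v) "vertical" else "none"
  attr(out, "width_mm") <- width
  attr(out, "step_mm") <- step
  out
}

#' Surgical plan from a full landmark set
#'
#' Composes the two rules: RBH is the straight-line |AC-SF| distance in mm
#' (matching the classifier's absolute-distance priors), the defect status
#' comes from [assessDefect()], and the class from [classifyRBH()].  A
#' vertical-component RBH (the |AC-SF| difference along the z axis only) is
#' available for comparison with perpendicular clinical measurements.
#'
#' @param landmarks a [LandmarkSet-class] with all five landmarks.
#' @param thresholds a [DefectThresholds-class].
#' @param rbhMode `"euclidean"` (default) or `"vertical"`.
#' @param boundaries passed to [classifyRBH()].
#' @return A list with elements `class`, `procedure`, `rbh_mm`, `defect`,
#'   `defect_kind` and `priors` (a [DistancePriors-class]).
#' @examples
#' lm <- landmarkSet(list(AC = c(12, 12, 8), SF = c(12, 12, 20),
#'                        MH = c(8, 12, 8), LH = c(16, 12, 8),
#'                        CEJ = c(12, 12, 8)))
#' planFromLandmarks(lm)$class  # "A"
#' @export
planFromLandmarks <- function(landmarks, thresholds = defectThresholds(),
                              rbhMode = c("euclidean", "vertical"),
                              boundaries = c(5, 10)) {
  rbhMode <- match.arg(rbhMode)
  cc <- landmarks@coords
  if (!all(LANDMARK_NAMES %in% rownames(cc)))
    .err(paste0("missing landmark(s): ",
                paste(setdiff(LANDMARK_NAMES, rownames(cc)), collapse = ", ")),
         "sinusplan_missing_landmark")
  priors <- computeDistancePriors(landmarks)
  rbh <- if (rbhMode == "euclidean") priors@dAcSf else
    abs(cc["AC", 3] - cc["SF", 3])
  defect <- assessDefect(landmarks, thresholds)
  cls <- classifyRBH(rbh, as.logical(defect), boundaries = boundaries)
  list(class = as.character(cls), procedure = procedureFor(as.character(cls)),
       rbh_mm = unname(rbh), defect = as.logical(defect),
       defect_kind = attr(defect, "kind"), priors = priors)
}
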