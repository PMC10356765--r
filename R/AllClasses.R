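#' @import methods
#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib sinusplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## The five anatomical landmarks of the posterior maxilla used throughout:
## alveolar bone crest (AC), maxillary sinus floor (SF), medial and lateral
## points of the horizontal bone width (MH, LH), and the adjacent
## cementoenamel junction (CEJ).
LANDMARK_NAMES <- c("AC", "SF", "MH", "LH", "CEJ")

## Fixed class order of the modified ABC sinus-augmentation classification.
SURGICAL_CLASSES <- c("A", "B", "B'", "C", "C'")

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sinusplan_error", "error")))
}

#' CBCTVolume: a 3D intensity grid with voxel geometry
#'
#' Container for a CBCT-like scalar volume.  The voxel grid is axis-aligned:
#' the world-mm position of 0-based voxel index \eqn{i} is
#' \eqn{origin + i \cdot spacing}, component-wise.  Oblique acquisitions are
#' not represented (no direction matrix).
#'
#' @slot grid 3D numeric array of intensities.
#' @slot spacing numeric(3), per-axis voxel size in mm (all > 0).
#' @slot origin numeric(3), world-mm position of voxel index (0,0,0).
#' @slot dtypeBits integer(1), nominal intensity bit depth of the source.
#'
#' @exportClass CBCTVolume
setClass("CBCTVolume",
  representation(grid = "array", spacing = "numeric", origin = "numeric",
                 dtypeBits = "integer"),
  prototype(spacing = c(0.3, 0.3, 0.3), origin = c(0, 0, 0),
            dtypeBits = 16L))

setValidity("CBCTVolume", function(object) {
  if (length(dim(object@grid)) != 3L) return("grid must have exactly three axes")
  if (any(dim(object@grid) < 1L)) return("each grid axis must have length >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be three positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite values (mm)")
  if (any(!is.finite(object@grid))) return("intensities must all be finite")
  TRUE
})

#' Construct a CBCTVolume
#'
#' @param grid 3D numeric array of intensities.
#' @param spacing per-axis voxel size in mm, recycled to length 3.
#' @param origin world-mm coordinate of voxel (0,0,0).
#' @param dtypeBits nominal bit depth tag (metadata only).
#' @return A validated [CBCTVolume-class] object.
#' @examples
#' v <- cbctVolume(array(0, c(8, 8, 8)), spacing = 0.3)
#' spacing(v)
#' @export
cbctVolume <- function(grid, spacing = c(0.3, 0.3, 0.3), origin = c(0, 0, 0),
                       dtypeBits = 16L) {
  new("CBCTVolume", grid = grid, spacing = rep(as.numeric(spacing), length.out = 3L),
      origin = rep(as.numeric(origin), length.out = 3L),
      dtypeBits = as.integer(dtypeBits))
}

#' LandmarkSet: named anatomical points in world mm
#'
#' Holds up to one 3D world-mm point for each of the five landmark names
#' AC, SF, MH, LH, CEJ, with a provenance tag recording whether the points
#' were annotated by a rater or predicted by the detection cascade.
#'
#' @slot coords numeric matrix, one row per stored landmark (rownames are the
#'   landmark names, columns x/y/z in mm).
#' @slot provenance character(1), `"annotated"` or `"predicted"`.
#'
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(coords = "matrix", provenance = "character"),
  prototype(provenance = "annotated"))

setValidity("LandmarkSet", function(object) {
  cc <- object@coords
  if (ncol(cc) != 3L) return("coords must have three columns (x, y, z in mm)")
  nm <- rownames(cc)
  if (nrow(cc) > 0L) {
    if (is.null(nm)) return("coords rows must be named by landmark")
    bad <- setdiff(nm, LANDMARK_NAMES)
    if (length(bad)) return(paste0("unknown landmark name(s): ", paste(bad, collapse = ", ")))
    if (anyDuplicated(nm)) return("at most one point per landmark name")
    if (any(!is.finite(cc))) return("all landmark coordinates must be finite")
  }
  if (!object@provenance %in% c("annotated", "predicted"))
    return("provenance must be 'annotated' or 'predicted'")
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param points a named list of numeric(3) world-mm points, or a numeric
#'   matrix with landmark rownames and three columns.  Names must come from
#'   AC, SF, MH, LH, CEJ.
#' @param provenance `"annotated"` (rater ground truth) or `"predicted"`.
#' @return A validated [LandmarkSet-class].
#' @examples
#' lm <- landmarkSet(list(AC = c(0, 0, 0), SF = c(0, 0, 7)))
#' landmarkCoords(lm)
#' @export
landmarkSet <- function(points, provenance = "annotated") {
  if (is.list(points)) {
    if (length(points) && is.null(names(points)))
      .err("landmark points must be named", "sinusplan_unknown_landmark")
    m <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
    rownames(m) <- names(points)
    if (is.null(m)) m <- matrix(numeric(0), 0, 3)
    points <- m
  }
  points <- as.matrix(points)
  if (nrow(points)) {
    nm <- rownames(points)
    bad <- setdiff(nm, LANDMARK_NAMES)
    if (length(bad))
      .err(paste0("unknown landmark name(s): ", paste(bad, collapse = ", ")),
           "sinusplan_unknown_landmark")
    if (anyDuplicated(nm))
      .err("duplicate landmark name", "sinusplan_duplicate_landmark")
    if (any(!is.finite(points)))
      .err("malformed (non-finite) landmark coordinate", "sinusplan_bad_coordinate")
  }
  colnames(points) <- c("x", "y", "z")
  ## keep canonical AC, SF, MH, LH, CEJ ordering for the names present
  points <- points[intersect(LANDMARK_NAMES, rownames(points)), , drop = FALSE]
  new("LandmarkSet", coords = points, provenance = provenance)
}

#' HeatmapStack: per-landmark 3D Gaussian heatmaps
#'
#' One channel per landmark, each a grid of values in \[0,1\] produced by
#' `encodeHeatmap()` or predicted by the detection network.  When the stack
#' covers a sub-volume (a VOI patch), `patchOffset` records the 0-based
#' corner voxel of the patch in the parent grid.
#'
#' @slot data 4D numeric array (x, y, z, channel).
#' @slot sigma numeric(1), Gaussian width used for encoding, in voxels.
#' @slot landmarkNames character, channel names.
#' @slot patchOffset integer(3), 0-based corner of the stack in its parent grid.
#' @slot refDim integer(3), dimensions of the parent grid.
#'
#' @exportClass HeatmapStack
setClass("HeatmapStack",
  representation(data = "array", sigma = "numeric", landmarkNames = "character",
                 patchOffset = "integer", refDim = "integer"))

setValidity("HeatmapStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (x, y, z, channel)")
  if (length(object@landmarkNames) != d[4L])
    return("one landmark name per channel required")
  rng <- range(object@data)
  if (!all(is.finite(rng)) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("heatmap values must lie in [0, 1]")
  if (any(object@patchOffset < 0L)) return("patchOffset must be non-negative")
  if (any(object@patchOffset + d[1:3] > object@refDim))
    return("patch must lie within the parent grid")
  TRUE
})

#' Construct a HeatmapStack
#'
#' @param data 4D array (x, y, z, channel) of values in \[0,1\].
#' @param sigma Gaussian width used for encoding, in voxels.
#' @param landmarkNames one name per channel.
#' @param patchOffset 0-based corner of the stack in its parent grid.
#' @param refDim parent grid dimensions.
#' @return A validated [HeatmapStack-class].
#' @export
heatmapStack <- function(data, sigma, landmarkNames,
                         patchOffset = c(0L, 0L, 0L), refDim = dim(data)[1:3]) {
  new("HeatmapStack", data = data, sigma = as.numeric(sigma),
      landmarkNames = landmarkNames, patchOffset = as.integer(patchOffset),
      refDim = as.integer(refDim))
}

#' DistancePriors: the three inter-landmark distances guiding classification
#'
#' Absolute Euclidean distances in mm between AC and SF (the residual bone
#' height), MH and LH (the horizontal bone width), and AC and CEJ (the
#' vertical step to the adjacent tooth).
#'
#' @slot dAcSf numeric(1), |AC - SF| in mm.
#' @slot dMhLh numeric(1), |MH - LH| in mm.
#' @slot dAcCej numeric(1), |AC - CEJ| in mm.
#'
#' @exportClass DistancePriors
setClass("DistancePriors",
  representation(dAcSf = "numeric", dMhLh = "numeric", dAcCej = "numeric"))

setValidity("DistancePriors", function(object) {
  v <- c(object@dAcSf, object@dMhLh, object@dAcCej)
  if (length(v) != 3L || any(!is.finite(v)) || any(v < 0))
    return("all three distances must be finite and >= 0")
  TRUE
})

distancePriors <- function(dAcSf, dMhLh, dAcCej) {
  new("DistancePriors", dAcSf = as.numeric(dAcSf), dMhLh = as.numeric(dMhLh),
      dAcCej = as.numeric(dAcCej))
}

#' PhantomSpec: parameters of a synthetic posterior-maxilla phantom
#'
#' Describes one synthetic CBCT-like volume: the residual bone height from
#' alveolar crest to sinus floor, the medial-to-lateral ridge width, the
#' vertical step between crest and the adjacent tooth's cementoenamel
#' junction, grid geometry, tissue intensity levels, noise and a smooth
#' interface-deformation amplitude.
#'
#' @slot rbh numeric(1), crest-to-sinus-floor height in mm (> 0).
#' @slot ridgeWidth numeric(1), MH-to-LH width in mm (> 0).
#' @slot verticalStep numeric(1), apical offset of AC relative to CEJ in mm (>= 0).
#' @slot spacing numeric(3), voxel size in mm.
#' @slot shape integer(3), grid dimensions (each >= 16).
#' @slot tissueLevels numeric(3) named air/bone/tooth mean intensities in \[0,1\].
#' @slot noiseSd numeric(1), additive Gaussian intensity noise SD (>= 0).
#' @slot deformAmp numeric(1), amplitude (mm) of the smooth sinus-floor undulation.
#' @slot seed integer(1), RNG seed making the phantom deterministic.
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(rbh = "numeric", ridgeWidth = "numeric", verticalStep = "numeric",
                 spacing = "numeric", shape = "integer", tissueLevels = "numeric",
                 noiseSd = "numeric", deformAmp = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@rbh <= 0 || !is.finite(object@rbh)) return("rbh must be > 0 mm")
  if (object@ridgeWidth <= 0 || !is.finite(object@ridgeWidth))
    return("ridgeWidth must be > 0 mm")
  if (object@verticalStep < 0 || !is.finite(object@verticalStep))
    return("verticalStep must be >= 0 mm")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values (mm)")
  if (length(object@shape) != 3L || any(object@shape < 16L))
    return("all grid dimensions must be >= 16")
  if (length(object@tissueLevels) != 3L ||
      !identical(names(object@tissueLevels), c("air", "bone", "tooth")))
    return("tissueLevels must be named air, bone, tooth")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@deformAmp < 0) return("deformAmp must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe the package's desk-scale study conditions: a 64-cubed
#' grid at 0.4 mm isotropic spacing (25.6 mm field of view over the
#' posterior maxilla).  CBCT scanner variation can be emulated with
#' spacings such as 0.15, 0.25 or 0.3 mm.
#'
#' @param rbh residual bone height |AC-SF| in mm.
#' @param ridgeWidth horizontal bone width |MH-LH| in mm.
#' @param verticalStep vertical crest defect |AC-CEJ| in mm.
#' @param spacing voxel size (mm), recycled to 3.
#' @param shape grid dimensions, recycled to 3.
#' @param tissueLevels named mean intensities for air, bone, tooth.
#' @param noiseSd additive intensity noise SD.
#' @param deformAmp smooth sinus-floor undulation amplitude (mm).
#' @param seed RNG seed.
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(rbh = 7, ridgeWidth = 8, verticalStep = 0,
                        spacing = 0.4, shape = 64L,
                        tissueLevels = c(air = 0.05, bone = 0.6, tooth = 0.9),
                        noiseSd = 0.03, deformAmp = 0.4, seed = 1L) {
  new("PhantomSpec", rbh = as.numeric(rbh), ridgeWidth = as.numeric(ridgeWidth),
      verticalStep = as.numeric(verticalStep),
      spacing = rep(as.numeric(spacing), length.out = 3L),
      shape = rep(as.integer(shape), length.out = 3L),
      tissueLevels = tissueLevels, noiseSd = as.numeric(noiseSd),
      deformAmp = as.numeric(deformAmp), seed = as.integer(seed))
}

#' PhantomSample: one generated phantom with ground truth
#'
#' @slot volume the generated [CBCTVolume-class].
#' @slot landmarks ground-truth [LandmarkSet-class] (world mm).
#' @slot label surgical class, one of A, B, B', C, C'; always equal to the
#'   modified-ABC rules applied to the phantom geometry.
#' @slot spec the [PhantomSpec-class] that produced the sample.
#'
#' @exportClass PhantomSample
setClass("PhantomSample",
  representation(volume = "CBCTVolume", landmarks = "LandmarkSet",
                 label = "character", spec = "PhantomSpec"))

setValidity("PhantomSample", function(object) {
  if (!object@label %in% SURGICAL_CLASSES)
    return("label must be one of A, B, B', C, C'")
  if (nrow(object@landmarks@coords) != 5L)
    return("all five landmarks must be present")
  TRUE
})

#' DefectThresholds: numeric criteria for horizontal/vertical ridge defects
#'
#' The modified ABC classification sub-divides classes B and C into B'/C'
#' when a horizontal or vertical ridge defect is present; the clinical
#' definition is qualitative, so the package exposes numeric thresholds:
#' a horizontal defect is a ridge width |MH-LH| below `minWidth` and a
#' vertical defect a crest step |AC-CEJ| above `maxStep`.
#'
#' @slot minWidth numeric(1), mm; default 6.
#' @slot maxStep numeric(1), mm; default 3.
#'
#' @exportClass DefectThresholds
setClass("DefectThresholds",
  representation(minWidth = "numeric", maxStep = "numeric"),
  prototype(minWidth = 6, maxStep = 3))

setValidity("DefectThresholds", function(object) {
  if (object@minWidth <= 0 || object@maxStep <= 0)
    return("both thresholds must be > 0 mm")
  TRUE
})

#' @param minWidth horizontal-defect threshold on |MH-LH| (mm).
#' @param maxStep vertical-defect threshold on |AC-CEJ| (mm).
#' @rdname DefectThresholds-class
#' @export
defectThresholds <- function(minWidth = 6, maxStep = 3) {
  new("DefectThresholds", minWidth = as.numeric(minWidth),
      maxStep = as.numeric(maxStep))
}

## ---- show methods -----------------------------------------------------

setMethod("show", "CBCTVolume", function(object) {
  d <- dim(object@grid)
  cat(sprintf("CBCTVolume %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm, intensity range [%.3g, %.3g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@grid), max(object@grid)))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet (%s) with %d of 5 landmarks\n",
              object@provenance, nrow(object@coords)))
  if (nrow(object@coords)) print(round(object@coords, 4))
})

setMethod("show", "HeatmapStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("HeatmapStack %d x %d x %d, %d channel(s) [%s], sigma = %.3g voxels\n",
              d[1], d[2], d[3], d[4], paste(object@landmarkNames, collapse = ", "),
              object@sigma))
  if (any(object@patchOffset != 0L) || any(d[1:3] != object@refDim))
    cat(sprintf("  sub-volume at offset (%d, %d, %d) of a %d x %d x %d parent\n",
                object@patchOffset[1], object@patchOffset[2], object@patchOffset[3],
                object@refDim[1], object@refDim[2], object@refDim[3]))
})

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf("PhantomSample, class %s (RBH %.2f mm, width %.2f mm, step %.2f mm)\n",
              object@label, object@spec@rbh, object@spec@ridgeWidth,
              object@spec@verticalStep))
})

setMethod("show", "DistancePriors", function(object) {
  cat(sprintf("DistancePriors: |AC-SF| %.3f mm, |MH-LH| %.3f mm, |AC-CEJ| %.3f mm\n",
              object@dAcSf, object@dMhLh, object@dAcCej))
})

## ---- accessors --------------------------------------------------------

#' @rdname CBCTVolume-class
#' @param object,x a CBCTVolume (or other sinusplan object).
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname CBCTVolume-class
#' @export
setMethod("spacing", "CBCTVolume", function(x) x@spacing)

#' @rdname CBCTVolume-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname CBCTVolume-class
#' @export
setMethod("origin", "CBCTVolume", function(x) x@origin)

#' @rdname CBCTVolume-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname CBCTVolume-class
#' @export
setMethod("intensities", "CBCTVolume", function(x) x@grid)

#' @rdname CBCTVolume-class
#' @export
setMethod("dim", "CBCTVolume", function(x) dim(x@grid))

#' @rdname LandmarkSet-class
#' @param x a LandmarkSet.
#' @export
setGeneric("landmarkCoords", function(x) standardGeneric("landmarkCoords"))
#' @rdname LandmarkSet-class
#' @export
setMethod("landmarkCoords", "LandmarkSet", function(x) x@coords)

#' @rdname LandmarkSet-class
#' @export
setGeneric("landmarkNames", function(x) standardGeneric("landmarkNames"))
#' @rdname LandmarkSet-class
#' @export
setMethod("landmarkNames", "LandmarkSet", function(x) rownames(x@coords))
#' @rdname HeatmapStack-class
#' @export
setMethod("landmarkNames", "HeatmapStack", function(x) x@landmarkNames)

#' @rdname LandmarkSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname LandmarkSet-class
#' @export
setMethod("provenance", "LandmarkSet", function(x) x@provenance)

#' @rdname HeatmapStack-class
#' @param x a HeatmapStack.
#' @export
setGeneric("heatmapData", function(x) standardGeneric("heatmapData"))
#' @rdname HeatmapStack-class
#' @export
setMethod("heatmapData", "HeatmapStack", function(x) x@data)

#' @rdname HeatmapStack-class
#' @export
setGeneric("patchOffset", function(x) standardGeneric("patchOffset"))
#' @rdname HeatmapStack-class
#' @export
setMethod("patchOffset", "HeatmapStack", function(x) x@patchOffset)

#' @rdname DistancePriors-class
#' @param x a DistancePriors.
#' @export
setGeneric("priorValues", function(x) standardGeneric("priorValues"))
#' @rdname DistancePriors-class
#' @export
setMethod("priorValues", "DistancePriors",
          function(x) c(dAcSf = x@dAcSf, dMhLh = x@dMhLh, dAcCej = x@dAcCej))

#' @rdname PhantomSample-class
#' @param x a PhantomSample.
#' @export
setGeneric("sampleVolume", function(x) standardGeneric("sampleVolume"))
#' @rdname PhantomSample-class
#' @export
setMethod("sampleVolume", "PhantomSample", function(x) x@volume)

#' @rdname PhantomSample-class
#' @export
setGeneric("sampleLandmarks", function(x) standardGeneric("sampleLandmarks"))
#' @rdname PhantomSample-class
#' @export
setMethod("sampleLandmarks", "PhantomSample", function(x) x@landmarks)

#' @rdname PhantomSample-class
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))
#' @rdname PhantomSample-class
#' @export
setMethod("sampleLabel", "PhantomSample", function(x) x@label)

#' @rdname PhantomSample-class
#' @export
setGeneric("sampleSpec", function(x) standardGeneric("sampleSpec"))
#' @rdname PhantomSample-class
#' @export
setMethod("sampleSpec", "PhantomSample", function(x) x@spec)
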