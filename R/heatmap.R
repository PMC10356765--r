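## Gaussian heatmap codec and VOI cropping.
## A landmark at (possibly sub-voxel) position x is encoded as
## H = exp(-D^2 / (2 sigma^2)) evaluated at every voxel, D being the
## Euclidean distance to x in voxel units (optionally in mm for anisotropic
## grids).  The heatmap is a soft segmentation label: values in [0, 1],
## monotone non-increasing in D.

#' VOIPatch: a cropped sub-volume with offset bookkeeping
#'
#' @slot grid cropped intensity array.
#' @slot offset integer(3), 0-based corner voxel index in the parent grid.
#' @slot parentDim integer(3), parent grid dimensions.
#' @exportClass VOIPatch
setClass("VOIPatch",
  representation(grid = "array", offset = "integer", parentDim = "integer"))

setValidity("VOIPatch", function(object) {
  if (any(object@offset < 0L)) return("offset must be non-negative")
  if (any(object@offset + dim(object@grid) > object@parentDim))
    return("patch must fit inside the parent grid")
  TRUE
})

setMethod("show", "VOIPatch", function(object) {
  d <- dim(object@grid)
  cat(sprintf("VOIPatch %d x %d x %d at offset (%d, %d, %d)\n",
              d[1], d[2], d[3], object@offset[1], object@offset[2], object@offset[3]))
})

#' Encode a landmark as a 3D Gaussian heatmap
#'
#' @param landmarkVoxel continuous 0-based voxel index of the landmark
#'   (length 3); must lie inside the grid.
#' @param shape grid dimensions (length 3).
#' @param sigma Gaussian width; voxels by default, mm when `spacing` is given.
#' @param spacing optional per-axis voxel size in mm; when supplied the
#'   distance D is computed in world mm (anisotropic grids).
#' @return 3D numeric array of heatmap values in \[0, 1\].
#' @examples
#' h <- encodeHeatmap(c(8, 8, 8), c(16, 16, 16), sigma = 2)
#' h[9, 9, 9]  # 1 at the landmark voxel (0-based index 8)
#' @export
encodeHeatmap <- function(landmarkVoxel, shape, sigma, spacing = NULL) {
  if (sigma <= 0) .err("sigma must be > 0", "sinusplan_bad_sigma")
  shape <- as.integer(shape)
  if (any(landmarkVoxel < 0) || any(landmarkVoxel > shape - 1L))
    .err("landmark lies outside the grid", "sinusplan_outside_grid")
  sp <- if (is.null(spacing)) c(1, 1, 1) else rep(as.numeric(spacing), length.out = 3L)
  dx2 <- ((seq_len(shape[1]) - 1 - landmarkVoxel[1]) * sp[1])^2
  dy2 <- ((seq_len(shape[2]) - 1 - landmarkVoxel[2]) * sp[2])^2
  dz2 <- ((seq_len(shape[3]) - 1 - landmarkVoxel[3]) * sp[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  exp(-d2 / (2 * sigma^2))
}

#' Encode a full landmark set as a heatmap stack
#'
#' @param landmarks a [LandmarkSet-class] in world mm.
#' @param volume the [CBCTVolume-class] the stack is registered to.
#' @param sigma Gaussian width in voxels.
#' @return A [HeatmapStack-class] with one channel per landmark.
#' @export
encodeLandmarkStack <- function(landmarks, volume, sigma) {
  d <- dim(volume@grid)
  nm <- rownames(landmarks@coords)
  arr <- array(0, c(d, length(nm)))
  for (i in seq_along(nm)) {
    v <- worldToVoxel(landmarks@coords[nm[i], ], volume)
    arr[, , , i] <- encodeHeatmap(as.numeric(v), d, sigma)
  }
  heatmapStack(arr, sigma = sigma, landmarkNames = nm)
}

#' Decode a heatmap channel to a continuous voxel index
#'
#' Peak extraction: the global argmax seeds the peak (ties broken by lowest
#' linear index), the voxels carrying the top fraction `p` of the total
#' heatmap mass are selected, restricted to an 11-cubed neighbourhood of
#' the argmax, and their intensity-weighted centroid is returned, giving
#' sub-voxel accuracy beyond the bare argmax.
#'
#' @param channel 3D numeric array (finite, non-constant).
#' @param p top mass fraction used for the centroid (default 0.05).
#' @return Continuous 0-based voxel index (length 3).
#' @export
decodeHeatmap <- function(channel, p = 0.05) {
  if (any(!is.finite(channel)))
    .err("heatmap channel contains non-finite values", "sinusplan_degenerate_channel")
  r <- range(channel)
  if (r[2] - r[1] <= 0)
    .err("constant heatmap channel: no peak to decode", "sinusplan_degenerate_channel")
  d <- dim(channel)
  i0 <- which.max(channel)            # lowest linear index on ties
  a0 <- arrayInd(i0, d)
  ## smallest value set holding the top p of total mass
  v <- as.numeric(channel)
  tot <- sum(v)
  sv <- sort(v, decreasing = TRUE)
  k <- which(cumsum(sv) >= p * tot)[1L]
  ## relative tolerance keeps numerically tied voxels in the set, so the
  ## selection stays symmetric around symmetric peaks
  thr <- sv[k] * (1 - 1e-9)
  sel <- which(channel >= thr)
  ai <- arrayInd(sel, d)
  near <- abs(ai[, 1] - a0[1]) <= 5L & abs(ai[, 2] - a0[2]) <= 5L &
          abs(ai[, 3] - a0[3]) <= 5L
  ai <- ai[near, , drop = FALSE]
  w <- channel[sel[near]]
  colSums(ai * w) / sum(w) - 1       # back to 0-based
}

#' Crop a volume-of-interest patch around a coarse prediction
#'
#' The patch is centred on the rounded centre index; when it would exceed a
#' boundary it is shifted to fit (clamped), never zero-padded, so every
#' patch voxel holds a genuine parent intensity.  The recorded offset maps
#' patch coordinates back to parent coordinates exactly:
#' `parent index = patch index + offset`.
#'
#' @param volume a [CBCTVolume-class] (or plain 3D array).
#' @param center continuous 0-based voxel index of the patch centre.
#' @param size patch dimensions, recycled to length 3; must not exceed the
#'   volume on any axis.
#' @return A [VOIPatch-class].
#' @export
cropVOI <- function(volume, center, size) {
  g <- if (is(volume, "CBCTVolume")) volume@grid else volume
  d <- dim(g)
  size <- rep(as.integer(size), length.out = 3L)
  if (any(size > d))
    .err("patch size exceeds the volume extent", "sinusplan_bad_geometry")
  corner <- round(center) - size %/% 2L
  corner <- pmin(pmax(corner, 0L), d - size)
  corner <- as.integer(corner)
  patch <- g[corner[1] + seq_len(size[1]),
             corner[2] + seq_len(size[2]),
             corner[3] + seq_len(size[3]), drop = FALSE]
  new("VOIPatch", grid = patch, offset = corner, parentDim = as.integer(d))
}

#' Map a patch-local voxel index to its parent volume
#'
#' @param index continuous 0-based index within the patch.
#' @param patch a [VOIPatch-class] (or a [HeatmapStack-class] carrying a
#'   patch offset).
#' @return The 0-based index in the parent grid.
#' @export
patchToParent <- function(index, patch) {
  off <- if (is(patch, "HeatmapStack")) patch@patchOffset else patch@offset
  as.numeric(index) + as.numeric(off)
}
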