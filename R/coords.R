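## Voxel <-> world coordinate contract shared by every module.
## Voxel indices are 0-based and continuous; world mm = origin + index * spacing,
## component-wise (axis-aligned volumes, no rotation).  All distances reported
## anywhere in the package are world-mm distances, never raw voxel counts.

.as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), nrow = 1L)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) .err("points must have three coordinates", "sinusplan_bad_coordinate")
  p
}

#' Convert world-mm points to continuous 0-based voxel indices
#'
#' The affine map is `index = (point - origin) / spacing` per axis; its exact
#' inverse is [voxelToWorld()].  Out-of-grid indices are returned as-is and
#' flagged through the `"inside"` attribute rather than raised as errors.
#'
#' @param points numeric(3) or an n x 3 matrix of world-mm points.
#' @param volume a [CBCTVolume-class].
#' @return Continuous 0-based voxel indices, same shape as the input, with a
#'   logical attribute `"inside"` marking points that fall within the grid
#'   (index in `[0, dim - 1]` on every axis).
#' @examples
#' v <- cbctVolume(array(0, c(16, 16, 16)), spacing = 0.3)
#' worldToVoxel(c(3, 0, 0), v)   # index (10, 0, 0)
#' @export
worldToVoxel <- function(points, volume) {
  vec <- is.null(dim(points))
  p <- .as_points(points)
  idx <- sweep(sweep(p, 2L, volume@origin, "-"), 2L, volume@spacing, "/")
  d <- dim(volume@grid)
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
            idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
            idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  if (vec) { out <- idx[1L, ]; attr(out, "inside") <- inside[1L] }
  else { out <- idx; attr(out, "inside") <- inside }
  out
}

#' Convert continuous 0-based voxel indices to world-mm points
#'
#' @param indices numeric(3) or an n x 3 matrix of 0-based voxel indices.
#' @param volume a [CBCTVolume-class].
#' @return World-mm coordinates, same shape as the input.
#' @export
voxelToWorld <- function(indices, volume) {
  vec <- is.null(dim(indices))
  p <- .as_points(indices)
  w <- sweep(sweep(p, 2L, volume@spacing, "*"), 2L, volume@origin, "+")
  if (vec) w[1L, ] else w
}

## Min-max rescale of intensities to [0, 1]; constant volumes map to 0.
normalizeIntensity <- function(grid) {
  r <- range(grid)
  if (r[2] - r[1] <= 0) return(array(0, dim(grid)))
  (grid - r[1]) / (r[2] - r[1])
}

## Block-average downsample of a volume by integer factor k, with geometry
## carried along: the downsampled voxel j covers full-resolution voxels
## k*j .. k*j+k-1, so its centre sits at full index k*j + (k-1)/2 and the
## downsampled origin shifts by spacing*(k-1)/2.
downsampleVolume <- function(volume, k) {
  k <- as.integer(k)
  if (k == 1L) return(volume)
  d <- dim(volume@grid)
  if (any(d %% k != 0L))
    .err("grid dimensions must be divisible by the downsample factor",
         "sinusplan_bad_geometry")
  x <- matrix(as.numeric(volume@grid), nrow = 1L)
  y <- cpp_avgpool(x, 1L, d[1], d[2], d[3], 1L, k)
  cbctVolume(array(as.numeric(y), d %/% k), spacing = volume@spacing * k,
             origin = volume@origin + volume@spacing * (k - 1) / 2,
             dtypeBits = volume@dtypeBits)
}
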