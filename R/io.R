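## Volume and landmark file I/O.
## Volumes: NIfTI (.nii / .nii.gz) with spacing in the pixdim header and the
## world origin in the sform/qform translation.  Landmarks: a fiducial-CSV
## dialect (name,x,y,z in world mm) or JSON with the same fields.

#' Read a volumetric image
#'
#' Reads a NIfTI volume and returns it as a [CBCTVolume-class]; spacing and
#' origin are taken from the file header.  Only axis-aligned volumes are
#' supported (the rotational part of the NIfTI affine is ignored).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [CBCTVolume-class].
#' @seealso [writeVolume()], [readLandmarks()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    .err(paste0("volume file not found: ", path), "sinusplan_missing_file")
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    .err(paste0("unsupported volume format (expected .nii/.nii.gz): ", path),
         "sinusplan_unsupported_format")
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    .err(paste0("unsupported or corrupt volume file: ", path,
                " (", conditionMessage(e), ")"), "sinusplan_unsupported_format"))
  ## NIfTI stores pixdim as float32; round to its 7 significant digits so a
  ## 0.3 mm spacing survives the round-trip exactly
  sp <- signif(as.numeric(RNifti::pixdim(img))[1:3], 7)
  if (any(!is.finite(sp)) || any(sp <= 0))
    .err("non-positive voxel spacing in file header", "sinusplan_bad_spacing")
  xf <- RNifti::xform(img)
  org <- signif(as.numeric(xf[1:3, 4]), 7)
  bits <- attr(img, "bitpix")
  g <- as.array(img)
  if (length(dim(g)) == 4L && dim(g)[4] == 1L) g <- g[, , , 1L]
  g <- array(as.numeric(g), dim(g))
  cbctVolume(g, spacing = sp, origin = org,
             dtypeBits = if (is.null(bits)) 16L else as.integer(bits))
}

#' Write a volumetric image
#'
#' @param volume a [CBCTVolume-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CBCTVolume"))
  img <- RNifti::asNifti(volume@grid)
  RNifti::pixdim(img) <- volume@spacing
  m <- diag(c(volume@spacing, 1))
  m[1:3, 4] <- volume@origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a landmark set
#'
#' Accepts the fiducial-CSV dialect (`name,x,y,z`, coordinates in world mm,
#' header optional) or a JSON file with a `landmarks` object mapping names to
#' 3-vectors.  Only the five landmark names AC, SF, MH, LH, CEJ are accepted;
#' unknown names, duplicated names and malformed coordinates are distinct
#' errors.
#'
#' @param path path to a `.csv`, `.fcsv` or `.json` landmark file.
#' @return A [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path))
    .err(paste0("landmark file not found: ", path), "sinusplan_missing_file")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    lms <- obj$landmarks
    if (is.null(lms)) .err("JSON landmark file must contain a 'landmarks' object",
                           "sinusplan_unsupported_format")
    if (is.data.frame(lms)) lms <- as.list(as.data.frame(t(lms)))
    nm <- names(lms)
    if (anyDuplicated(nm)) .err("duplicate landmark name", "sinusplan_duplicate_landmark")
    pts <- lapply(lms, function(p) {
      p <- suppressWarnings(as.numeric(unlist(p)))
      if (length(p) != 3L || any(!is.finite(p)))
        .err("malformed landmark coordinate", "sinusplan_bad_coordinate")
      p
    })
    names(pts) <- nm
    prov <- if (!is.null(obj$provenance)) obj$provenance else "annotated"
    return(landmarkSet(pts, provenance = prov))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && grepl("^\\s*name\\s*,", lines[1], ignore.case = TRUE))
    lines <- lines[-1L]
  if (!length(lines)) return(landmarkSet(list()))
  parts <- strsplit(lines, ",")
  nm <- vapply(parts, function(p) trimws(p[[1L]]), "")
  if (anyDuplicated(nm)) .err("duplicate landmark name", "sinusplan_duplicate_landmark")
  pts <- lapply(parts, function(p) {
    if (length(p) != 4L) .err("malformed landmark row (expected name,x,y,z)",
                              "sinusplan_bad_coordinate")
    v <- suppressWarnings(as.numeric(trimws(p[2:4])))
    if (any(!is.finite(v))) .err("malformed landmark coordinate",
                                 "sinusplan_bad_coordinate")
    v
  })
  names(pts) <- nm
  landmarkSet(pts)
}

#' Write a landmark set
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path output path; `.json` selects the JSON format, anything else
#'   the fiducial-CSV dialect.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  cc <- landmarks@coords
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(landmarks = setNames(lapply(seq_len(nrow(cc)),
                                            function(i) unname(cc[i, ])),
                                     rownames(cc)),
                provenance = landmarks@provenance)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(name = rownames(cc), x = cc[, 1], y = cc[, 2], z = cc[, 3])
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export a heatmap stack as NIfTI files for inspection
#'
#' Writes one NIfTI file per landmark channel, named `<prefix>_<name>.nii.gz`.
#'
#' @param stack a [HeatmapStack-class].
#' @param prefix output path prefix.
#' @param volume optional parent [CBCTVolume-class] supplying voxel geometry.
#' @return The written paths, invisibly.
#' @export
writeHeatmaps <- function(stack, prefix, volume = NULL) {
  stopifnot(is(stack, "HeatmapStack"))
  sp <- if (is.null(volume)) c(1, 1, 1) else volume@spacing
  org <- if (is.null(volume)) c(0, 0, 0) else volume@origin
  paths <- character(0)
  for (i in seq_along(stack@landmarkNames)) {
    v <- cbctVolume(stack@data[, , , i], spacing = sp,
                    origin = org + sp * stack@patchOffset, dtypeBits = 32L)
    p <- sprintf("%s_%s.nii.gz", prefix, stack@landmarkNames[i])
    writeVolume(v, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
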