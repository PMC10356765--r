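## Synthetic CBCT phantom of the posterior maxilla.
##
## Minimal analytic geometry that makes all five landmarks well-defined:
##   - the alveolar ridge is a bone slab of configurable width whose crest
##     plane sits at height zc; outside the width the crest surface rises
##     steeply, so the two crest corners are the medial/lateral ridge points
##     MH and LH;
##   - the sinus floor is a smooth curved (paraboloid) air-bone interface
##     whose apex sits a controllable residual bone height above the crest;
##     a smooth radial undulation (deformAmp) perturbs the floor away from
##     the apex without moving it;
##   - an adjacent tooth is a high-intensity cylinder whose crown bulges
##     below the cementoenamel junction; the CEJ landmark is the mesial
##     cervical point, placed directly inferior to AC so that |AC-CEJ|
##     equals the vertical step exactly.
## Landmarks are exact analytic world-mm points, so the rule-derived label
## stored with each sample is reproduced exactly by planFromLandmarks().

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.ramp <- function(t) pmin(pmax(t + 0.5, 0), 1)

#' Generate one synthetic posterior-maxilla phantom
#'
#' Deterministic given `spec@seed`: the same spec generates bit-identical
#' volumes and identical landmarks.  The ground-truth inter-landmark
#' distances equal the spec quantities exactly (|AC-SF| = `rbh`,
#' |MH-LH| = `ridgeWidth`, |AC-CEJ| = `verticalStep`), and the stored label
#' is the modified-ABC class derived from the same geometry.
#'
#' @param spec a [PhantomSpec-class].
#' @param thresholds defect thresholds used to derive the stored label.
#' @return A [PhantomSample-class].
#' @examples
#' s <- generatePhantom(phantomSpec(rbh = 12, ridgeWidth = 8, seed = 7))
#' sampleLabel(s)  # "A"
#' @export
generatePhantom <- function(spec, thresholds = defectThresholds()) {
  validObject(spec)
  fov <- spec@shape * spec@spacing
  .with_seed(spec@seed, {
    e <- 0.7 * max(spec@spacing)            # soft interface width (mm)
    cx <- fov[1] / 2 + runif(1, -1.5, 1.5)
    ym <- fov[2] / 2 + runif(1, -1.5, 1.5)  # measurement plane / tooth mesial plane
    zc <- max(0.22 * fov[3], spec@verticalStep + 2.0) + runif(1, -1, 1)
    zs <- zc + spec@rbh                     # sinus floor apex
    zcej <- zc - spec@verticalStep
    if (zs + 1.5 > fov[3])
      .err("rbh does not fit the field of view", "sinusplan_bad_geometry")
    if (zcej < 0.8 || cx + spec@ridgeWidth / 2 + 1 > fov[1] ||
        cx - spec@ridgeWidth / 2 - 1 < 0)
      .err("phantom geometry does not fit the grid", "sinusplan_bad_geometry")

    curv <- runif(1, 0.02, 0.05)            # sinus floor curvature (1/mm)
    wallSlope <- runif(1, 2.5, 3.5)         # crest rise outside the ridge width
    rt <- runif(1, 2.3, 3.2)                # tooth root radius (mm)
    bumpR <- runif(1, 5, 7)                 # deformation wavelength (mm)
    levels <- spec@tissueLevels * runif(3, 0.95, 1.05)

    d <- spec@shape
    xv <- (seq_len(d[1]) - 1) * spec@spacing[1]
    yv <- (seq_len(d[2]) - 1) * spec@spacing[2]
    zv <- (seq_len(d[3]) - 1) * spec@spacing[3]
    X <- rep(xv, times = d[2] * d[3])
    Y <- rep(rep(yv, each = d[1]), times = d[3])
    Z <- rep(zv, each = d[1] * d[2])

    ## crest surface: flat at zc across the ridge width, rising outside it
    zcrest <- zc + pmax(0, abs(X - cx) - spec@ridgeWidth / 2) * wallSlope
    ## sinus floor: paraboloid about (cx, ym) plus a non-negative undulation
    ## that vanishes at the apex (the SF landmark stays the floor minimum)
    r2 <- (X - cx)^2 + (Y - ym)^2
    bump <- spec@deformAmp * (1 - cos(2 * pi * pmin(sqrt(r2), bumpR) / bumpR)) / 2
    zfloor <- zs + curv * r2 + bump

    boneFrac <- .ramp((Z - zcrest) / e) * .ramp((zfloor - Z) / e)
    vol <- levels["air"] + (levels["bone"] - levels["air"]) * boneFrac

    ## adjacent tooth: cylinder with mesial surface at y = ym; crown bulge
    ## below the CEJ level
    zbot <- max(zcej - 3.5, 0.4)
    ztop <- min(zcej + 6, zs - 0.8)
    rxy <- sqrt((X - cx)^2 + (Y - (ym + rt))^2)
    rprof <- rt + 0.7 * .ramp((zcej - Z) / e)
    toothFrac <- .ramp((rprof - rxy) / e) * .ramp((Z - zbot) / e) *
      .ramp((ztop - Z) / e)
    vol <- vol * (1 - toothFrac) + levels["tooth"] * toothFrac

    if (spec@noiseSd > 0)
      vol <- vol + rnorm(length(vol), 0, spec@noiseSd)

    volume <- cbctVolume(array(vol, d), spacing = spec@spacing,
                         origin = c(0, 0, 0), dtypeBits = 16L)
    lms <- landmarkSet(list(
      AC  = c(cx, ym, zc),
      SF  = c(cx, ym, zs),
      MH  = c(cx - spec@ridgeWidth / 2, ym, zc),
      LH  = c(cx + spec@ridgeWidth / 2, ym, zc),
      CEJ = c(cx, ym, zcej)), provenance = "annotated")
    v <- worldToVoxel(lms@coords, volume)
    if (!all(attr(v, "inside")))
      .err("phantom landmarks fall outside the grid", "sinusplan_bad_geometry")

    plan <- planFromLandmarks(lms, thresholds)
    new("PhantomSample", volume = volume, landmarks = lms,
        label = plan$class, spec = spec)
  })
}

## RBH sampling intervals per class (mm): spans the published anchors and
## fills their gaps consistently with the rule boundaries at 5 and 10 mm.
.RBH_INTERVALS <- list("A" = c(10, 15), "B" = c(5, 10), "B'" = c(5, 10),
                       "C" = c(1, 5), "C'" = c(1, 5))

## Largest-remainder apportionment of n among proportions p.
.largest_remainder <- function(n, p) {
  q <- n * p
  counts <- floor(q)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(q - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  as.integer(counts)
}

#' Generate a phantom dataset with controlled class mix
#'
#' Per-class counts follow the requested proportions exactly after
#' largest-remainder rounding.  Within each class, RBH is drawn uniformly
#' from that class's interval (C/C' in (1,5], B/B' in (5,10], A in (10,15]);
#' defect classes draw a horizontal, vertical or combined ridge defect with
#' a 0.5 mm margin from the defect thresholds so the geometry-derived label
#' is unambiguous.
#'
#' @param n number of phantoms.
#' @param classMix named proportions over A, B, B', C, C'; must sum to 1.
#' @param baseSpec a [PhantomSpec-class] supplying grid geometry, tissue
#'   levels, noise and deformation defaults.
#' @param seed RNG seed for the whole dataset.
#' @param dir optional output directory; when given, each volume is written
#'   as NIfTI, each landmark set as fiducial CSV, and a `manifest.csv` is
#'   written alongside.
#' @param thresholds defect thresholds used for labels.
#' @return List with `samples` (list of [PhantomSample-class]) and
#'   `manifest` (data.frame with file, label, rbh_mm, width_mm, step_mm,
#'   seed per sample).
#' @export
generateDataset <- function(n, classMix = NULL, baseSpec = phantomSpec(),
                            seed = 1L, dir = NULL,
                            thresholds = defectThresholds()) {
  if (n < 1) .err("n must be >= 1", "sinusplan_bad_mix")
  if (is.null(classMix))
    classMix <- setNames(rep(0.2, 5), SURGICAL_CLASSES)
  if (!setequal(names(classMix), SURGICAL_CLASSES))
    .err("classMix must be named with the five classes A, B, B', C, C'",
         "sinusplan_bad_mix")
  classMix <- classMix[SURGICAL_CLASSES]
  if (abs(sum(classMix) - 1) > 1e-9)
    .err("class proportions must sum to 1", "sinusplan_bad_mix")
  counts <- .largest_remainder(n, as.numeric(classMix))
  labels <- rep(SURGICAL_CLASSES, counts)

  .with_seed(seed, {
    labels <- sample(labels)                 # shuffle class order
    childSeeds <- sample.int(.Machine$integer.max - 1L, n)
    params <- lapply(seq_len(n), function(i) {
      cl <- labels[i]
      iv <- .RBH_INTERVALS[[cl]]
      rbh <- runif(1, iv[1] + 1e-3, iv[2])
      if (cl %in% c("B'", "C'")) {
        kind <- sample(c("horizontal", "vertical", "combined"), 1)
        width <- if (kind %in% c("horizontal", "combined"))
          runif(1, thresholds@minWidth - 2.5, thresholds@minWidth - 0.5) else
          runif(1, thresholds@minWidth + 0.5, thresholds@minWidth + 3.5)
        step <- if (kind %in% c("vertical", "combined"))
          runif(1, thresholds@maxStep + 0.5, thresholds@maxStep + 2.5) else
          runif(1, 0, thresholds@maxStep - 0.5)
      } else {
        width <- runif(1, thresholds@minWidth + 0.5, thresholds@minWidth + 3.5)
        step <- runif(1, 0, thresholds@maxStep - 0.5)
      }
      list(class = cl, rbh = rbh, width = width, step = step)
    })
  })

  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params[[i]]
    spec <- phantomSpec(rbh = p$rbh, ridgeWidth = p$width,
                        verticalStep = p$step, spacing = baseSpec@spacing,
                        shape = baseSpec@shape,
                        tissueLevels = baseSpec@tissueLevels,
                        noiseSd = baseSpec@noiseSd,
                        deformAmp = baseSpec@deformAmp,
                        seed = childSeeds[i])
    s <- generatePhantom(spec, thresholds)
    stopifnot(s@label == p$class)           # label-geometry consistency
    fn <- sprintf("phantom_%03d.nii.gz", i)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeVolume(s@volume, file.path(dir, fn))
      writeLandmarks(s@landmarks,
                     file.path(dir, sprintf("phantom_%03d_landmarks.csv", i)))
    }
    samples[[i]] <- s
    rows[[i]] <- data.frame(file = fn, label = s@label, rbh_mm = p$rbh,
                            width_mm = p$width, step_mm = p$step,
                            seed = childSeeds[i])
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(samples = samples, manifest = manifest)
}
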