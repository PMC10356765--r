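# Synthetic phantom generator: determinism, geometric fidelity,
# label consistency, class balance.

test_that("the same spec and seed generate bit-identical phantoms", {
  s1 <- generatePhantom(tinySpec(seed = 42L))
  s2 <- generatePhantom(tinySpec(seed = 42L))
  expect_identical(intensities(sampleVolume(s1)), intensities(sampleVolume(s2)))
  expect_identical(landmarkCoords(sampleLandmarks(s1)),
                   landmarkCoords(sampleLandmarks(s2)))
  s3 <- generatePhantom(tinySpec(seed = 43L))
  expect_false(identical(intensities(sampleVolume(s1)),
                         intensities(sampleVolume(s3))))
})

test_that("ground-truth inter-landmark distances equal the spec quantities", {
  s <- generatePhantom(phantomSpec(rbh = 7, ridgeWidth = 8, verticalStep = 0,
                                   spacing = 0.4, shape = 64L, seed = 5L))
  pv <- priorValues(computeDistancePriors(sampleLandmarks(s)))
  expect_gte(pv["dAcSf"], 6.6); expect_lte(pv["dAcSf"], 7.4)
  expect_equal(unname(pv), c(7, 8, 0), tolerance = 0.5 * 0.4)

  s2 <- generatePhantom(phantomSpec(rbh = 11.5, ridgeWidth = 4.2,
                                    verticalStep = 4.0, spacing = 0.4,
                                    shape = 64L, seed = 6L))
  pv2 <- priorValues(computeDistancePriors(sampleLandmarks(s2)))
  expect_equal(unname(pv2), c(11.5, 4.2, 4.0), tolerance = 0.5 * 0.4)
})

test_that("geometry that cannot fit the grid is rejected", {
  expect_error(generatePhantom(phantomSpec(rbh = 30, spacing = 0.4, shape = 64L)),
               class = "sinusplan_bad_geometry")
})

test_that("tissue contrast exceeds three noise standard deviations", {
  sp <- tinySpec(seed = 9L, noise = 0.05)
  s <- generatePhantom(sp)
  g <- intensities(sampleVolume(s))
  lm <- landmarkCoords(sampleLandmarks(s))
  v <- sampleVolume(s)
  ## sample bone just above the crest midline and sinus air above the floor
  acVox <- round(as.numeric(worldToVoxel(lm["AC", ], v))) + 1
  sfVox <- round(as.numeric(worldToVoxel(lm["SF", ], v))) + 1
  bone <- g[acVox[1], acVox[2], acVox[3] + 3]
  air <- g[sfVox[1], sfVox[2], min(dim(g)[3], sfVox[3] + 4)]
  expect_gt(bone - air, 3 * sp@noiseSd)
})

test_that("stored labels equal the rules applied to the ground-truth landmarks", {
  ds <- generateDataset(25, baseSpec = tinySpec(), seed = 13L)
  for (s in ds$samples) {
    expect_identical(planFromLandmarks(sampleLandmarks(s))$class, sampleLabel(s))
  }
  ## manifest rows re-derive to the stored label through the rule engine
  m <- ds$manifest
  for (i in seq_len(nrow(m))) {
    defect <- m$width_mm[i] < 6 || m$step_mm[i] > 3
    expect_identical(as.character(classifyRBH(m$rbh_mm[i], defect)), m$label[i])
  }
})

test_that("class balance follows largest-remainder rounding", {
  ds <- generateDataset(10, baseSpec = tinySpec(), seed = 3L)
  expect_equal(unname(table(ds$manifest$label)[c("A", "B", "B'", "C", "C'")]),
               rep(2L, 5), ignore_attr = TRUE)
  mix <- c(A = 0.5, B = 0.3, "B'" = 0.1, C = 0.06, "C'" = 0.04)
  ds2 <- generateDataset(17, classMix = mix, baseSpec = tinySpec(), seed = 4L)
  tab <- table(factor(ds2$manifest$label, levels = names(mix)))
  expect_equal(sum(tab), 17L)
  ## floors 8,5,1,1,0 leave 2; the largest remainders (B' 0.7, C' 0.68) round up
  expect_equal(as.integer(tab[c("A", "B", "B'", "C", "C'")]), c(8L, 5L, 2L, 1L, 1L))
  expect_error(generateDataset(10, classMix = mix * 0.9, baseSpec = tinySpec()),
               class = "sinusplan_bad_mix")
})

test_that("RBH samples stay inside each class's interval", {
  ds <- generateDataset(30, baseSpec = tinySpec(), seed = 17L)
  m <- ds$manifest
  iv <- list("A" = c(10, 15), "B" = c(5, 10), "B'" = c(5, 10),
             "C" = c(1, 5), "C'" = c(1, 5))
  for (i in seq_len(nrow(m))) {
    r <- iv[[m$label[i]]]
    expect_gt(m$rbh_mm[i], r[1]); expect_lte(m$rbh_mm[i], r[2])
  }
})

test_that("mm distances are resolution invariant between 0.15 and 0.3 mm", {
  mk <- function(sp) generatePhantom(phantomSpec(rbh = 6, ridgeWidth = 7,
    verticalStep = 2, spacing = sp, shape = if (sp < 0.2) 96L else 48L,
    seed = 77L))
  d1 <- priorValues(computeDistancePriors(sampleLandmarks(mk(0.3))))
  d2 <- priorValues(computeDistancePriors(sampleLandmarks(mk(0.15))))
  expect_lt(max(abs(d1 - d2)), 0.5)
})

test_that("dataset directories contain volumes, landmarks and a manifest", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(3, baseSpec = tinySpec(), seed = 2L, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "\\.nii\\.gz$"), 3L)
  expect_length(list.files(dir, pattern = "_landmarks\\.csv$"), 3L)
  lm <- readLandmarks(file.path(dir, "phantom_001_landmarks.csv"))
  expect_lt(max(abs(landmarkCoords(lm) -
                    landmarkCoords(sampleLandmarks(ds$samples[[1]])))), 1e-6)
})
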