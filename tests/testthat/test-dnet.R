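# Detection-network construction, training and cascade inference contracts.
# Training runs here are tiny smoke tests; parameter-recovery quality is
# exercised in the acceptance suite.

test_that("default architecture doubles channel widths from 8 to 64", {
  expect_equal(sinusplan:::.dnet_channels(dnetConfig()), c(8L, 16L, 32L, 64L))
  expect_equal(sinusplan:::.dnet_channels(dnetConfig(baseChannels = 4L)),
               c(4L, 8L, 16L, 32L))
})

test_that("deep supervision emits exactly three side outputs at four levels", {
  cfg <- dnetConfig(levels = 4, baseChannels = 2, inputSize = 8, outChannels = 2)
  net <- buildDNet(cfg, seed = 1)
  fwd <- sinusplan:::.dnetFwd(net@weights, net@bnStats,
                              matrix(rnorm(8^3), 1), cfg, 1L)
  expect_length(fwd$sides, 3L)
  ## every side output is sigmoid-valued at full resolution
  for (P in fwd$sides) {
    expect_equal(ncol(P), 512L)
    expect_true(all(P > 0 & P < 1))
  }
  cfgNoDs <- dnetConfig(levels = 4, baseChannels = 2, inputSize = 8,
                        outChannels = 2, useDS = FALSE)
  netNoDs <- buildDNet(cfgNoDs, seed = 1)
  fwd2 <- sinusplan:::.dnetFwd(netNoDs@weights, netNoDs@bnStats,
                               matrix(rnorm(8^3), 1), cfgNoDs, 1L)
  expect_length(fwd2$sides, 1L)
})

test_that("input sizes not divisible by 2^(levels-1) are rejected", {
  expect_error(buildDNet(dnetConfig(levels = 4, inputSize = 60)),
               class = "sinusplan_bad_config")
  expect_silent(invisible(buildDNet(dnetConfig(levels = 3, baseChannels = 2,
                                               inputSize = 60, outChannels = 1))))
})

make_tiny_dataset <- function(n, seed) {
  generateDataset(n, baseSpec = tinySpec(), seed = seed)$samples
}

tiny_dcfg <- function(...)
  dnetConfig(levels = 3L, baseChannels = 2L, inputSize = 16L,
             coarseDownsample = 2L, finePatchSize = 8L,
             sigmaCoarse = 2, sigmaFine = 2, ...)

test_that("a two-epoch smoke run records finite losses and history", {
  samples <- make_tiny_dataset(5, seed = 71L)
  tcfg <- trainConfig(epochs = 2L, batchSize = 2L, seed = 5L)
  m <- trainDNet("coarse", samples[1:4], samples[5], tiny_dcfg(), tcfg)
  h <- trainingHistory(m)
  expect_equal(nrow(h), 2L)
  expect_true(all(is.finite(h$train)))
  expect_true(all(is.finite(h$val)))
  ## fine stage accepts the same dataset
  mf <- trainDNet("fine", samples[1:4], samples[5], tiny_dcfg(), tcfg)
  expect_equal(nrow(trainingHistory(mf)), 2L)
  expect_true(all(is.finite(trainingHistory(mf)$train)))
})

test_that("training is reproducible given the seed", {
  samples <- make_tiny_dataset(4, seed = 72L)
  tcfg <- trainConfig(epochs = 2L, batchSize = 2L, seed = 77L)
  m1 <- trainDNet("coarse", samples[1:3], samples[4], tiny_dcfg(), tcfg)
  m2 <- trainDNet("coarse", samples[1:3], samples[4], tiny_dcfg(), tcfg)
  expect_identical(trainingHistory(m1)$train, trainingHistory(m2)$train)
  expect_identical(m1@weights$enc[[1]]$Wa, m2@weights$enc[[1]]$Wa)
})

test_that("training error contracts: empty data and missing validation", {
  expect_error(trainDNet("coarse", list(), NULL, tiny_dcfg(), trainConfig()),
               class = "sinusplan_empty_dataset")
  samples <- make_tiny_dataset(2, seed = 73L)
  expect_error(trainDNet("coarse", samples, NULL, tiny_dcfg(),
                         trainConfig(epochs = 1L)),
               class = "sinusplan_no_validation")
  ## plateau disabled allows a validation-free run
  m <- trainDNet("coarse", samples, NULL, tiny_dcfg(),
                 trainConfig(epochs = 1L, batchSize = 2L), plateau = FALSE)
  expect_equal(nrow(trainingHistory(m)), 1L)
})

test_that("oracle-stub cascade returns ground truth exactly", {
  ## landmarks placed on exact voxel centres so sub-voxel decoding is exact
  v <- cbctVolume(array(rnorm(32^3), c(32, 32, 32)), spacing = 0.8)
  vox <- rbind(AC = c(14, 16, 8), SF = c(14, 16, 17), MH = c(9, 16, 8),
               LH = c(19, 16, 8), CEJ = c(14, 16, 6))
  lm <- landmarkSet(voxelToWorld(vox, v))
  coarseStub <- function(volume) encodeLandmarkStack(lm, volume, sigma = 2)
  fineOracle <- local({
    vol <- v
    function(patchGrid, name) {
      cv <- as.numeric(worldToVoxel(landmarkCoords(lm)[name, ], vol))
      patch <- cropVOI(vol, cv, dim(patchGrid))
      encodeHeatmap(cv - patch@offset, dim(patchGrid), sigma = 2)
    }
  })
  det <- detectLandmarks(coarseStub, fineOracle, v)
  expect_lt(max(abs(landmarkCoords(det$landmarks) - landmarkCoords(lm))), 1e-6)
  expect_identical(provenance(det$landmarks), "predicted")
  expect_length(attr(det$landmarks, "undetected"), 0L)
})

test_that("a degenerate coarse channel flags that landmark as undetected", {
  s <- generatePhantom(tinySpec(seed = 75L))
  v <- sampleVolume(s); lm <- sampleLandmarks(s)
  coarseStub <- function(volume) {
    st <- encodeLandmarkStack(lm, volume, sigma = 2)
    d <- st@data
    d[, , , 2] <- 0.3                      # SF channel constant
    heatmapStack(d, 2, landmarkNames(st))
  }
  fineOracle <- function(patchGrid, name) encodeHeatmap(dim(patchGrid) / 2,
                                                        dim(patchGrid), 2)
  det <- detectLandmarks(coarseStub, fineOracle, v)
  expect_identical(attr(det$landmarks, "undetected"), "SF")
  expect_setequal(landmarkNames(det$landmarks), c("AC", "MH", "LH", "CEJ"))
})

test_that("cascade coordinates near boundaries stay inside the volume", {
  s <- generatePhantom(tinySpec(seed = 76L))
  v <- sampleVolume(s)
  ## coarse stub that claims a peak at the very corner of the grid
  coarseStub <- function(volume)
    heatmapStack(array(encodeHeatmap(c(0, 0, 0), dim(volume@grid), 2),
                       c(dim(volume@grid), 1)), 2, "AC")
  fineOracle <- function(patchGrid, name)
    encodeHeatmap(c(1, 1, 1), dim(patchGrid), 2)
  det <- detectLandmarks(coarseStub, fineOracle, v)
  idx <- worldToVoxel(landmarkCoords(det$landmarks)["AC", ], v)
  expect_true(attr(idx, "inside"))
})

test_that("trained cascade stages interoperate end to end (smoke)", {
  samples <- make_tiny_dataset(6, seed = 78L)
  tcfg <- trainConfig(epochs = 2L, batchSize = 3L, seed = 8L)
  coarse <- trainDNet("coarse", samples[1:5], samples[6], tiny_dcfg(), tcfg)
  fine <- trainDNet("fine", samples[1:5], samples[6],
                    dnetConfig(levels = 2L, baseChannels = 2L, inputSize = 8L,
                               coarseDownsample = 2L, finePatchSize = 8L,
                               sigmaCoarse = 2, sigmaFine = 2), tcfg)
  det <- detectLandmarks(coarse, fine, sampleVolume(samples[[1]]))
  expect_s4_class(det$landmarks, "LandmarkSet")
  expect_s4_class(det$stack, "HeatmapStack")
  expect_equal(dim(det$stack@data)[1:3], dim(sampleVolume(samples[[1]])))
})
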