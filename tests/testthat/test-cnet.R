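# Distance priors and the classification network.

test_that("distance priors are the three pairwise distances in mm", {
  lm <- landmarkSet(list(AC = c(0, 0, 0), SF = c(0, 0, 7),
                         MH = c(-4, 0, 0), LH = c(4, 0, 0),
                         CEJ = c(0, 0, -1)))
  pv <- priorValues(computeDistancePriors(lm))
  expect_equal(unname(pv), c(7, 8, 1))
  expect_error(computeDistancePriors(landmarkSet(list(AC = c(0, 0, 0)))),
               class = "sinusplan_missing_landmark")
})

test_that("priors are invariant to rigid motion and consistent across units", {
  set.seed(91)
  lm <- randomLandmarkSet()
  p0 <- priorValues(computeDistancePriors(lm))
  ## translation
  lmT <- landmarkSet(landmarkCoords(lm) + rep(5, 3))
  expect_lt(max(abs(priorValues(computeDistancePriors(lmT)) - p0)), 1e-9)
  ## rotation about z
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  lmR <- landmarkSet(landmarkCoords(lm) %*% t(R))
  expect_lt(max(abs(priorValues(computeDistancePriors(lmR)) - p0)), 1e-9)
  ## voxel-then-world path equals direct world computation
  v <- cbctVolume(array(0, c(64, 64, 64)), spacing = 0.3)
  vox <- worldToVoxel(landmarkCoords(lm), v)
  back <- landmarkSet(voxelToWorld(unclass(vox), v))
  expect_lt(max(abs(priorValues(computeDistancePriors(back)) - p0)), 1e-9)
})

test_that("the concatenated feature vector length is pooled channels + 3", {
  cfg <- cnetConfig(convWidths = c(2L, 4L), inputSize = 8L, hiddenUnits = 4L)
  net <- buildCNet(cfg, seed = 3)
  expect_equal(ncol(net@weights$fc1$W), 4L + 3L)
  cfgNo <- cnetConfig(convWidths = c(2L, 4L), inputSize = 8L, hiddenUnits = 4L,
                      usePriors = FALSE)
  netNo <- buildCNet(cfgNo, seed = 3)
  expect_equal(ncol(netNo@weights$fc1$W), 4L)
})

test_that("class probabilities are a proper distribution for any input", {
  set.seed(92)
  cfg <- cnetConfig(convWidths = c(2L, 3L), inputSize = 8L, hiddenUnits = 4L)
  net <- buildCNet(cfg, seed = 4)
  for (r in 1:5) {
    xs <- matrix(rnorm(2 * 8^3 * 2, sd = 3), nrow = 2)
    pr <- matrix(runif(6, 0, 20), 3)
    fwd <- sinusplan:::.cnetFwd(net@weights, net@bnStats, xs, pr, cfg, 2L)
    expect_true(all(fwd$probs >= 0 & fwd$probs <= 1))
    expect_lt(max(abs(colSums(fwd$probs) - 1)), 1e-6)
  }
})

test_that("heatmap fusion by voxelwise maximum is channel-permutation symmetric", {
  set.seed(93)
  s <- generatePhantom(tinySpec(seed = 94L))
  v <- sampleVolume(s)
  st <- encodeLandmarkStack(sampleLandmarks(s), v, sigma = 2)
  cfg <- cnetConfig(convWidths = c(2L, 3L), inputSize = 8L, hiddenUnits = 4L)
  x1 <- prepareCNetInput(v, st, cfg)
  perm <- sample(5)
  stP <- heatmapStack(st@data[, , , perm], st@sigma, st@landmarkNames[perm])
  x2 <- prepareCNetInput(v, stP, cfg)
  expect_identical(x1, x2)
})

test_that("classifySample returns a deterministic argmax with ordered ties", {
  s <- generatePhantom(tinySpec(seed = 95L))
  v <- sampleVolume(s)
  st <- encodeLandmarkStack(sampleLandmarks(s), v, sigma = 2)
  cfg <- cnetConfig(convWidths = c(2L, 3L), inputSize = 8L, hiddenUnits = 4L)
  net <- buildCNet(cfg, seed = 5)
  pri <- computeDistancePriors(sampleLandmarks(s))
  r1 <- classifySample(net, v, st, pri)
  r2 <- classifySample(net, v, st, pri)
  expect_identical(r1$class, r2$class)
  expect_equal(sum(r1$probabilities), 1, tolerance = 1e-6)
  expect_identical(names(r1$probabilities), c("A", "B", "B'", "C", "C'"))
})

make_cnet_records <- function(n, seed, cfg) {
  ds <- generateDataset(n, baseSpec = tinySpec(), seed = seed)
  lapply(ds$samples, function(s) {
    st <- encodeLandmarkStack(sampleLandmarks(s), sampleVolume(s), sigma = 2)
    list(x = prepareCNetInput(sampleVolume(s), st, cfg),
         priors = computeDistancePriors(sampleLandmarks(s)),
         label = sampleLabel(s))
  })
}

test_that("a two-epoch training run is finite, reproducible, and accepts
           both teacher-mode and predicted heatmaps", {
  cfg <- cnetConfig(convWidths = c(2L, 3L), inputSize = 8L, hiddenUnits = 4L)
  recs <- make_cnet_records(10, seed = 96L, cfg)
  tcfg <- trainConfig(epochs = 2L, batchSize = 4L, seed = 6L)
  m1 <- trainCNet(recs[1:8], recs[9:10], cfg, tcfg)
  h <- trainingHistory(m1)
  expect_equal(nrow(h), 2L)
  expect_true(all(is.finite(h$train)))
  m2 <- trainCNet(recs[1:8], recs[9:10], cfg, tcfg)
  expect_identical(trainingHistory(m1)$train, trainingHistory(m2)$train)
  ## a class absent from training labels warns but proceeds
  sub <- Filter(function(r) r$label != "A", recs)
  expect_warning(trainCNet(sub[1:5], sub[6:length(sub)], cfg,
                           trainConfig(epochs = 1L, batchSize = 4L, seed = 6L)),
                 "absent")
})

test_that("the prior pathway is live: zeroing priors changes the logits", {
  cfg <- cnetConfig(convWidths = c(2L, 3L), inputSize = 8L, hiddenUnits = 4L)
  recs <- make_cnet_records(10, seed = 97L, cfg)
  m <- suppressWarnings(trainCNet(recs[1:8], recs[9:10], cfg,
                 trainConfig(epochs = 3L, batchSize = 4L, initialLr = 1e-3,
                             seed = 7L)))
  xs <- recs[[1]]$x
  p1 <- sinusplan:::.cnetFwd(m@weights, m@bnStats, xs,
                             matrix(priorValues(recs[[1]]$priors), 3, 1),
                             cfg, 1L)$probs
  p0 <- sinusplan:::.cnetFwd(m@weights, m@bnStats, xs,
                             matrix(0, 3, 1), cfg, 1L)$probs
  expect_gt(max(abs(p1 - p0)), 1e-8)
})
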