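# The network engine: losses against brute-force oracles, analytic
# gradients against central differences, optimiser and scheduler contracts.

ns <- asNamespace("sinusplan")

test_that("ce_loss matches the printed formula and an elementwise oracle", {
  H0 <- array(0, c(4, 4, 4)); P5 <- array(0.5, c(4, 4, 4))
  expect_equal(ceLoss(H0, P5), -log(0.5), tolerance = 1e-12)
  ## perfect prediction of a binary target is ~0 under epsilon clipping
  Hb <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
  expect_lt(ceLoss(Hb, Hb), 1e-6)
  set.seed(61)
  for (r in 1:20) {
    H <- array(runif(64), c(4, 4, 4)); P <- array(runif(64), c(4, 4, 4))
    expect_lt(abs(ceLoss(H, P) - oracle_ce(H, P)), 1e-9)
  }
  expect_error(ceLoss(array(0, c(2, 2, 2)), array(0, c(3, 3, 3))),
               class = "sinusplan_shape_mismatch")
})

test_that("ds_loss is the exact sum of three side-output cross-entropies", {
  set.seed(62)
  H <- array(runif(27), c(3, 3, 3))
  P <- array(runif(27), c(3, 3, 3))
  expect_equal(dsLoss(H, list(P, P, P)), 3 * ceLoss(H, P), tolerance = 1e-12)
  Hb <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
  P5 <- array(0.5, c(3, 3, 3))
  expect_equal(dsLoss(Hb, list(Hb, P5, P5)), 2 * (-log(0.5)), tolerance = 1e-5)
  expect_error(dsLoss(H, list(P, P)), class = "sinusplan_bad_arity")
})

test_that("the 3D convolution matches a naive seven-loop oracle", {
  set.seed(63)
  cin <- 3L; cout <- 4L; d <- c(5L, 4L, 3L); b <- 2L
  x <- matrix(rnorm(cin * prod(d) * b), cin)
  W <- matrix(rnorm(cout * 27 * cin), cout)
  y <- ns$cpp_conv3_fwd(x, W, cin, d[1], d[2], d[3], b)
  xa <- array(x, c(cin, d, b)); ya <- array(0, c(cout, d, b))
  for (s in 1:b) for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    acc <- numeric(cout)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      ii <- i + dx; jj <- j + dy; kk <- k + dz
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && kk >= 1 && kk <= d[3]) {
        o <- (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)
        acc <- acc + W[, o * cin + 1:cin, drop = FALSE] %*% xa[, ii, jj, kk, s]
      }
    }
    ya[, i, j, k, s] <- acc
  }
  expect_lt(max(abs(array(y, c(cout, d, b)) - ya)), 1e-12)
})

grad_check <- function(lossFn, weights, grads, paths, nProbe = 3, tol = 1e-4) {
  get <- function(l, p) { for (k in p) l <- l[[k]]; l }
  setv <- function(l, p, v) {
    if (length(p) == 1) { l[[p[[1]]]] <- v; return(l) }
    l[[p[[1]]]] <- setv(l[[p[[1]]]], p[-1], v); l
  }
  worst <- 0
  for (pth in paths) {
    W <- get(weights, pth); G <- get(grads, pth)
    for (r in seq_len(nProbe)) {
      i <- sample(length(W), 1); eps <- 1e-5
      Wp <- W; Wp[i] <- W[i] + eps
      Wm <- W; Wm[i] <- W[i] - eps
      num <- (lossFn(setv(weights, pth, Wp)) - lossFn(setv(weights, pth, Wm))) / (2 * eps)
      worst <- max(worst, abs(num - G[i]) / max(1e-6, abs(num) + abs(G[i])))
    }
  }
  worst
}

test_that("detection-network gradients match central differences", {
  set.seed(64)
  cfg <- dnetConfig(levels = 3, baseChannels = 2, inputSize = c(8, 8, 4),
                    outChannels = 2)
  net <- buildDNet(cfg, seed = 9)
  b <- 2L
  x <- matrix(rnorm(prod(cfg@inputSize) * b), nrow = 1)
  H <- matrix(runif(2 * prod(cfg@inputSize) * b), nrow = 2)
  lossFn <- function(wts) {
    fwd <- ns$.dnetFwd(wts, net@bnStats, x, cfg, b, train = TRUE)
    l <- 0
    for (nm in names(fwd$sides)) {
      P <- pmin(pmax(fwd$sides[[nm]], 1e-7), 1 - 1e-7)
      l <- l - mean(H * log(P) + (1 - H) * log(1 - P))
    }
    l
  }
  fwd <- ns$.dnetFwd(net@weights, net@bnStats, x, cfg, b, train = TRUE)
  dz <- lapply(fwd$sides, function(P) (P - H) / length(H))
  grads <- ns$.dnetBwd(net@weights, cfg, fwd$cache, dz, b)
  paths <- list(list("enc", 1, "Wa"), list("enc", 2, "ga"), list("enc", 3, "Wb"),
                list("lstm", "fwd", "W"), list("lstm", "bwd", "b"),
                list("lstm", "proj", "W"), list("dec", 1, "Wu"),
                list("dec", 2, "Wa"), list("dec", 1, "bb"),
                list("side", "l1", "W"), list("side", "l2", "b"))
  expect_lt(grad_check(lossFn, net@weights, grads, paths), 1e-4)
})

test_that("classification-network gradients match central differences", {
  set.seed(65)
  cfg <- cnetConfig(convWidths = c(2L, 3L), inputSize = 8L, hiddenUnits = 4L)
  net <- buildCNet(cfg, seed = 2)
  b <- 3L
  xs <- matrix(rnorm(2 * 8^3 * b), nrow = 2)
  pr <- matrix(runif(3 * b, 0, 15), 3)
  ys <- matrix(0, 5, b); for (s in 1:b) ys[sample(5, 1), s] <- 1
  lossFn <- function(wts) {
    fwd <- ns$.cnetFwd(wts, net@bnStats, xs, pr, cfg, b, train = TRUE)
    -mean(log(pmax(fwd$probs[ys > 0], 1e-12)))
  }
  fwd <- ns$.cnetFwd(net@weights, net@bnStats, xs, pr, cfg, b, train = TRUE)
  grads <- ns$.cnetBwd(net@weights, cfg, fwd$cache, (fwd$probs - ys) / b, b)
  paths <- list(list("conv", 1, "W"), list("conv", 2, "g"), list("conv", 2, "b"),
                list("fc1", "W"), list("fc1", "b"), list("fc2", "W"))
  expect_lt(grad_check(lossFn, net@weights, grads, paths), 1e-4)
})

test_that("plateau schedule halves the rate exactly once per completed plateau", {
  ## strictly improving: never reduced
  lr <- schedulePlateau(seq(1, 0.1, length.out = 30), 1e-4, 0.5, 25)
  expect_true(all(lr == 1e-4))
  ## one injected plateau of exactly `patience` non-improving epochs
  losses <- c(1, 0.9, rep(0.9, 25))
  lr <- schedulePlateau(losses, 1e-4, 0.5, 25)
  expect_equal(tail(lr, 1), 5e-5)
  expect_equal(sum(diff(lr) != 0), 1L)
  ## two plateaus halve twice
  losses2 <- c(1, rep(1, 25), rep(1, 25))
  lr2 <- schedulePlateau(losses2, 1e-4, 0.5, 25)
  expect_equal(tail(lr2, 1), 2.5e-5)
  expect_equal(sum(diff(lr2) != 0), 2L)
  ## an improvement resets the patience counter
  losses3 <- c(1, rep(1, 24), 0.5, rep(0.5, 24))
  lr3 <- schedulePlateau(losses3, 1e-4, 0.5, 25)
  expect_true(all(lr3 == 1e-4))
  expect_error(schedulePlateau(1, 1e-4, factor = 1.5), class = "sinusplan_bad_config")
})

test_that("rmsprop moves weights against the gradient with bounded steps", {
  w <- list(a = matrix(c(1, -1), 1), b = list(c = rep(0, 3)))
  g <- list(a = matrix(c(10, -10), 1), b = list(c = c(1e-3, 0, -5)))
  st <- ns$rmspropInit(w)
  out <- ns$rmspropStep(w, g, st, lr = 0.01)
  expect_lt(out$weights$a[1], 1)
  expect_gt(out$weights$a[2], -1)
  ## steps are scale-normalised: |step| <= lr / sqrt(1 - rho) approximately
  expect_lt(max(abs(out$weights$a - w$a)), 0.04)
  expect_equal(out$weights$b$c[2], 0)
})

test_that("augmentation transforms volume and landmarks consistently", {
  s <- generatePhantom(tinySpec(seed = 31L))
  v <- sampleVolume(s); lm <- sampleLandmarks(s)
  ## identity transform returns the sample bit-for-bit
  id <- augmentSample(v, lm, rotation = 0, rescale = 0, brightness = 0,
                      contrast = 1)
  expect_identical(intensities(id$volume), intensities(v))
  expect_identical(landmarkCoords(id$landmarks), landmarkCoords(lm))

  ## a 25-degree rotation moves landmarks by the same rotation matrix
  a <- augmentSample(v, lm, rotation = 25, rescale = 0, brightness = 0,
                     contrast = 1)
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ctr <- origin(v) + (dim(v) - 1) / 2 * spacing(v)
  manual <- t(R %*% (t(landmarkCoords(lm)) - ctr) + ctr)
  expect_lt(max(abs(landmarkCoords(a$landmarks) - manual)), 1e-6)

  ## rescale stretches inter-landmark distances by the scale factor
  a2 <- augmentSample(v, lm, rotation = 0, rescale = 0.2, brightness = 0,
                      contrast = 1)
  d0 <- priorValues(computeDistancePriors(lm))
  d2 <- priorValues(computeDistancePriors(a2$landmarks))
  expect_equal(unname(d2), unname(1.2 * d0), tolerance = 1e-9)

  ## determinism under a fixed RNG state
  set.seed(99); r1 <- augmentSample(v, lm)
  set.seed(99); r2 <- augmentSample(v, lm)
  expect_identical(intensities(r1$volume), intensities(r2$volume))
  expect_identical(r1$params, r2$params)
})
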