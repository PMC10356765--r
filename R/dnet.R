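## Cascaded volumetric heatmap-regression network (D-Net).
##
## Encoder-decoder with 3x3x3 conv + batch-norm + ReLU blocks, stride-2
## max-pooling, stride-2 transposed-convolution upsampling and three
## encoder-to-decoder skip connections at the default depth of four levels
## (channel widths 8, 16, 32, 64).  Optional sub-modules: multi-scale
## inputs (MSI; the input average-pooled 2x2x2 per level, concatenated at
## each encoder level), a bidirectional convolutional LSTM over axial
## slices at the bottleneck, and deep supervision (DS; a 1x1x1 conv +
## sigmoid side output at every decoder level, upsampled to full
## resolution).  The decoder's level-1 side output is the full-resolution
## head used at inference.  The same architecture serves as the coarse
## network (on a downsampled whole volume) and the fine network (on VOI
## patches at native resolution).

#' DNetConfig: detection-network architecture configuration
#'
#' @slot levels integer, encoder depth (default 4 channel stages).
#' @slot baseChannels integer, first-stage width (default 8, doubling per
#'   level to 64 at the default depth).
#' @slot useMSI,useConvLSTM,useDS logical sub-module switches.
#' @slot outChannels integer, landmark channels (default 5).
#' @slot inputSize integer(3), training grid dimensions of this network.
#' @slot coarseDownsample integer, block-average factor applied to the full
#'   volume before the coarse stage.
#' @slot finePatchSize integer(3), VOI patch dimensions for the fine stage.
#' @slot sigmaCoarse,sigmaFine numeric, Gaussian heatmap widths (voxels).
#' @exportClass DNetConfig
setClass("DNetConfig",
  representation(levels = "integer", baseChannels = "integer",
                 useMSI = "logical", useConvLSTM = "logical", useDS = "logical",
                 outChannels = "integer", inputSize = "integer",
                 coarseDownsample = "integer", finePatchSize = "integer",
                 sigmaCoarse = "numeric", sigmaFine = "numeric"))

setValidity("DNetConfig", function(object) {
  if (object@levels < 2L) return("levels must be >= 2")
  if (object@baseChannels < 1L) return("baseChannels must be >= 1")
  if (object@outChannels < 1L) return("outChannels must be >= 1")
  if (any(object@inputSize < 2L)) return("inputSize must be >= 2 per axis")
  if (object@sigmaCoarse <= 0 || object@sigmaFine <= 0)
    return("heatmap sigmas must be > 0")
  TRUE
})

#' Construct a DNetConfig
#'
#' Defaults follow the reference architecture (four levels, widths 8 to 64,
#' all three sub-modules on, five landmark channels).  `inputSize` is the
#' grid the network itself consumes: the downsampled whole volume for the
#' coarse stage, the VOI patch for the fine stage.
#'
#' @param levels encoder depth.
#' @param baseChannels first-level channel width.
#' @param useMSI,useConvLSTM,useDS sub-module switches.
#' @param outChannels number of landmark channels.
#' @param inputSize training grid dims (recycled to 3).
#' @param coarseDownsample integer downsample factor for the coarse stage.
#' @param finePatchSize fine-stage VOI patch dims (recycled to 3).
#' @param sigmaCoarse,sigmaFine heatmap Gaussian widths in voxels.
#' @return A validated [DNetConfig-class].
#' @export
dnetConfig <- function(levels = 4L, baseChannels = 8L, useMSI = TRUE,
                       useConvLSTM = TRUE, useDS = TRUE, outChannels = 5L,
                       inputSize = 16L, coarseDownsample = 4L,
                       finePatchSize = 16L, sigmaCoarse = 3, sigmaFine = 5) {
  new("DNetConfig", levels = as.integer(levels),
      baseChannels = as.integer(baseChannels), useMSI = useMSI,
      useConvLSTM = useConvLSTM, useDS = useDS,
      outChannels = as.integer(outChannels),
      inputSize = rep(as.integer(inputSize), length.out = 3L),
      coarseDownsample = as.integer(coarseDownsample),
      finePatchSize = rep(as.integer(finePatchSize), length.out = 3L),
      sigmaCoarse = sigmaCoarse, sigmaFine = sigmaFine)
}

#' TrainConfig: optimisation and augmentation configuration
#'
#' RMSprop with reduce-on-plateau scheduling and the standard augmentation
#' ranges: rotation -25 to 25 degrees about the axial axis, isotropic
#' rescaling -10 to +20 percent, and brightness/contrast intensity jitter.
#'
#' @slot epochs,batchSize integers.
#' @slot initialLr,plateauFactor numerics; plateau factor in (0,1).
#' @slot plateauPatience integer, epochs without improvement before the
#'   rate is reduced.
#' @slot rotationRange numeric(2), degrees.
#' @slot rescaleRange numeric(2), fractional (-0.1 = shrink 10 percent).
#' @slot brightnessJitter,contrastJitter numerics, jitter amplitudes.
#' @slot seed integer RNG seed.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 initialLr = "numeric", plateauFactor = "numeric",
                 plateauPatience = "integer", rotationRange = "numeric",
                 rescaleRange = "numeric", brightnessJitter = "numeric",
                 contrastJitter = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L || object@batchSize < 1L) return("epochs and batchSize must be >= 1")
  if (object@plateauFactor <= 0 || object@plateauFactor >= 1)
    return("plateauFactor must be in (0, 1)")
  if (object@plateauPatience < 1L) return("plateauPatience must be >= 1")
  if (any(!is.finite(c(object@rotationRange, object@rescaleRange,
                       object@brightnessJitter, object@contrastJitter))))
    return("augmentation ranges must be finite")
  TRUE
})

#' @param epochs,batchSize,initialLr,plateauFactor,plateauPatience optimiser
#'   settings (defaults: 300 epochs, batch 8, RMSprop at 1e-4, halve on a
#'   25-epoch validation plateau).
#' @param rotationRange,rescaleRange,brightnessJitter,contrastJitter
#'   augmentation ranges.
#' @param seed RNG seed for initialisation, shuffling and augmentation.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(epochs = 300L, batchSize = 8L, initialLr = 1e-4,
                        plateauFactor = 0.5, plateauPatience = 25L,
                        rotationRange = c(-25, 25),
                        rescaleRange = c(-0.10, 0.20),
                        brightnessJitter = 0.1, contrastJitter = 0.1,
                        seed = 1L) {
  new("TrainConfig", epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      initialLr = initialLr, plateauFactor = plateauFactor,
      plateauPatience = as.integer(plateauPatience),
      rotationRange = rotationRange, rescaleRange = rescaleRange,
      brightnessJitter = brightnessJitter, contrastJitter = contrastJitter,
      seed = as.integer(seed))
}

#' NetModel: a (possibly trained) network handle
#'
#' @slot weights nested list of parameter arrays.
#' @slot bnStats nested list of batch-norm running statistics.
#' @slot config the architecture configuration object.
#' @slot history data.frame with per-epoch train/validation loss and
#'   learning rate.
#' @slot meta list of resolution metadata (stage, downsample factor, sigma,
#'   landmark names, input spacing).
#' @exportClass NetModel
setClass("NetModel",
  representation(weights = "list", bnStats = "list", config = "ANY",
                 history = "data.frame", meta = "list"))

setMethod("show", "NetModel", function(object) {
  st <- if (!is.null(object@meta$stage)) object@meta$stage else "untrained"
  cat(sprintf("NetModel (%s), %d trained epoch(s)\n", st, nrow(object@history)))
  if (nrow(object@history))
    cat(sprintf("  final train loss %.5g, val loss %.5g\n",
                tail(object@history$train, 1), tail(object@history$val, 1)))
})

#' @rdname NetModel-class
#' @param x a NetModel.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname NetModel-class
#' @export
setMethod("trainingHistory", "NetModel", function(x) x@history)

## ---- construction -----------------------------------------------------

.dnet_channels <- function(cfg) cfg@baseChannels * 2L^(seq_len(cfg@levels) - 1L)

.check_divisible <- function(size, levels) {
  if (any(size %% (2L^(levels - 1L)) != 0L))
    .err(sprintf("input size (%s) not divisible by 2^(levels-1) = %d",
                 paste(size, collapse = "x"), 2L^(levels - 1L)),
         "sinusplan_bad_config")
}

#' Build an untrained detection network
#'
#' @param config a [DNetConfig-class].
#' @param seed RNG seed for weight initialisation (He initialisation for
#'   convolutions, zero biases, unit forget-gate bias in the convLSTM).
#' @param baseRate expected fraction of positive heatmap mass per channel;
#'   the side-output biases start at its logit so the sigmoid heads emit
#'   the prior rate from the first step instead of spending the optimiser
#'   budget on learning it.  Computed from `sigmaCoarse` and the grid by
#'   default.
#' @return An untrained [NetModel-class].
#' @export
buildDNet <- function(config, seed = 1L, baseRate = NULL) {
  validObject(config)
  .check_divisible(config@inputSize, config@levels)
  if (is.null(baseRate)) {
    mass <- (2 * pi * config@sigmaCoarse^2)^1.5
    baseRate <- min(max(mass / prod(config@inputSize), 1e-4), 0.3)
  }
  b0 <- stats::qlogis(baseRate)
  ch <- .dnet_channels(config)
  L <- config@levels
  .with_seed(seed, {
    wts <- list()
    wts$enc <- lapply(seq_len(L), function(l) {
      cin <- if (l == 1L) 1L else ch[l - 1L] + (config@useMSI) * 1L
      list(Wa = .he_init(ch[l], 27 * cin, 27 * cin),
           ga = rep(1, ch[l]), ba = rep(0, ch[l]),
           Wb = .he_init(ch[l], 27 * ch[l], 27 * ch[l]),
           gb = rep(1, ch[l]), bb = rep(0, ch[l]))
    })
    if (config@useConvLSTM)
      wts$lstm <- nnConvLstmInit(ch[L], sample.int(1e6, 1))
    wts$dec <- lapply(seq_len(L - 1L), function(l) {
      list(Wu = .he_init(8 * ch[l], ch[l + 1L], 8 * ch[l + 1L]),
           Wa = .he_init(ch[l], 27 * 2 * ch[l], 27 * 2 * ch[l]),
           ga = rep(1, ch[l]), ba = rep(0, ch[l]),
           Wb = .he_init(ch[l], 27 * ch[l], 27 * ch[l]),
           gb = rep(1, ch[l]), bb = rep(0, ch[l]))
    })
    sideLv <- if (config@useDS) seq_len(L - 1L) else 1L
    wts$side <- setNames(lapply(sideLv, function(l)
      list(W = .he_init(config@outChannels, ch[l], ch[l]),
           b = rep(b0, config@outChannels))),
      sprintf("l%d", sideLv))
    bn <- list(
      enc = lapply(seq_len(L), function(l)
        list(a = list(mean = rep(0, ch[l]), var = rep(1, ch[l])),
             b = list(mean = rep(0, ch[l]), var = rep(1, ch[l])))),
      dec = lapply(seq_len(L - 1L), function(l)
        list(a = list(mean = rep(0, ch[l]), var = rep(1, ch[l])),
             b = list(mean = rep(0, ch[l]), var = rep(1, ch[l])))))
    new("NetModel", weights = wts, bnStats = bn, config = config,
        history = data.frame(), meta = list(stage = "untrained"))
  })
}

## ---- forward / backward -----------------------------------------------

.conv_block_fwd <- function(W, g, be, x, dims, b, train, stats,
                            momentum = 0.1) {
  cv <- nnConv3Fwd(W, x, dims, b)
  f <- cpp_bnrelu_fwd(cv$y, g, be, train, stats$mean, stats$var, .BN_EPS)
  if (train) {
    stats$mean <- (1 - momentum) * stats$mean + momentum * f$mean
    stats$var <- (1 - momentum) * stats$var + momentum * f$var
  }
  list(y = f$y, cache = list(x = x, xhat = f$xhat, istd = f$istd, relu = f$y),
       stats = stats)
}

.conv_block_bwd <- function(W, g, cache, dy, dims, b, needDx = TRUE) {
  bnb <- cpp_bnrelu_bwd(g, cache$xhat, cache$istd, cache$relu, dy)
  cvb <- nnConv3Bwd(W, cache$x, bnb$dx, dims, b, needDx = needDx)
  list(dx = cvb$dx, dW = cvb$dW, dg = bnb$dgamma, db = bnb$dbeta)
}

## Forward pass on a batch.  x: 1 x (prod(inputSize) * b) matrix of
## normalised intensities.  Returns sigmoid side outputs at full resolution
## (element 1 is the inference head) and, when train = TRUE, every cache
## needed for the backward pass plus updated batch-norm statistics.
.dnetFwd <- function(wts, bn, x, cfg, b, train = FALSE) {
  L <- cfg@levels
  dimsAt <- lapply(seq_len(L), function(l) cfg@inputSize %/% (2L^(l - 1L)))
  msi <- NULL
  if (cfg@useMSI) {
    msi <- vector("list", L)
    msi[[1]] <- x
    for (l in 2:L) {
      d <- dimsAt[[l - 1L]]
      msi[[l]] <- cpp_avgpool(msi[[l - 1L]], 1L, d[1], d[2], d[3], b, 2L)
    }
  }
  encOut <- vector("list", L); encCache <- vector("list", L)
  poolArg <- vector("list", L)
  cur <- x
  for (l in seq_len(L)) {
    d <- dimsAt[[l]]
    if (l > 1L) {
      dp <- dimsAt[[l - 1L]]
      mp <- cpp_maxpool2(cur, nrow(cur), dp[1], dp[2], dp[3], b)
      poolArg[[l]] <- mp$argmax
      cur <- mp$y
      if (cfg@useMSI) cur <- rbind(cur, msi[[l]])
    }
    w <- wts$enc[[l]]
    fa <- .conv_block_fwd(w$Wa, w$ga, w$ba, cur, d, b, train, bn$enc[[l]]$a)
    bn$enc[[l]]$a <- fa$stats
    fb <- .conv_block_fwd(w$Wb, w$gb, w$bb, fa$y, d, b, train, bn$enc[[l]]$b)
    bn$enc[[l]]$b <- fb$stats
    encOut[[l]] <- fb$y
    encCache[[l]] <- list(a = fa$cache, b = fb$cache)
    cur <- fb$y
  }
  lstmCache <- NULL
  if (cfg@useConvLSTM) {
    lf <- nnConvLstmFwd(wts$lstm, cur, dimsAt[[L]], b)
    lstmCache <- lf
    cur <- lf$y
  }
  bottom <- cur
  decOut <- vector("list", L - 1L); decCache <- vector("list", L - 1L)
  for (l in rev(seq_len(L - 1L))) {
    d <- dimsAt[[l]]
    w <- wts$dec[[l]]
    deeper <- if (l == L - 1L) bottom else decOut[[l + 1L]]
    up <- nnUpconvFwd(w$Wu, deeper, dimsAt[[l + 1L]], b)
    cat2 <- rbind(up$y, encOut[[l]])
    fa <- .conv_block_fwd(w$Wa, w$ga, w$ba, cat2, d, b, train, bn$dec[[l]]$a)
    bn$dec[[l]]$a <- fa$stats
    fb <- .conv_block_fwd(w$Wb, w$gb, w$bb, fa$y, d, b, train, bn$dec[[l]]$b)
    bn$dec[[l]]$b <- fb$stats
    decOut[[l]] <- fb$y
    decCache[[l]] <- list(up = up, a = fa$cache, b = fb$cache)
  }
  sideLv <- if (cfg@useDS) seq_len(L - 1L) else 1L
  sides <- list(); sideZ <- list()
  for (l in sideLv) {
    nm <- sprintf("l%d", l)
    sw <- wts$side[[nm]]
    z <- sw$W %*% decOut[[l]] + sw$b
    f <- 2L^(l - 1L)
    if (f > 1L) {
      d <- dimsAt[[l]]
      z <- cpp_upsample_nn(z, nrow(z), d[1], d[2], d[3], b, f)
    }
    sideZ[[nm]] <- z
    sides[[nm]] <- nnSigmoid(z)
  }
  out <- list(sides = sides, bn = bn)
  if (train)
    out$cache <- list(encOut = encOut, encCache = encCache, poolArg = poolArg,
                      lstm = lstmCache, decOut = decOut, decCache = decCache,
                      dimsAt = dimsAt, msi = msi, bottom = bottom, x = x)
  out
}

## Backward pass.  dz: list (same names as sides) of gradients w.r.t. the
## pre-sigmoid side outputs at full resolution.  Returns grads mirroring
## the weight structure exactly.
.dnetBwd <- function(wts, cfg, cache, dz, b) {
  L <- cfg@levels
  dimsAt <- cache$dimsAt
  ch <- .dnet_channels(cfg)
  sideLv <- if (cfg@useDS) seq_len(L - 1L) else 1L
  gside <- list()
  dDec <- vector("list", L - 1L)
  for (l in sideLv) {
    nm <- sprintf("l%d", l)
    dzl <- dz[[nm]]
    f <- 2L^(l - 1L)
    if (f > 1L) {
      d <- dimsAt[[l]]
      ## nearest-upsample backward: sum each f^3 block
      dzl <- cpp_avgpool(dzl, nrow(dzl), d[1] * f, d[2] * f, d[3] * f, b, f) * f^3
    }
    sw <- wts$side[[nm]]
    gside[[nm]] <- list(W = dzl %*% t(cache$decOut[[l]]), b = rowSums(dzl))
    dd <- crossprod(sw$W, dzl)
    dDec[[l]] <- if (is.null(dDec[[l]])) dd else dDec[[l]] + dd
  }
  gdec <- vector("list", L - 1L)
  dBottom <- NULL
  for (l in seq_len(L - 1L)) {
    d <- dimsAt[[l]]
    w <- wts$dec[[l]]
    cc <- cache$decCache[[l]]
    dcur <- dDec[[l]]
    if (is.null(dcur)) dcur <- matrix(0, ch[l], ncol(cache$decOut[[l]]))
    gb <- .conv_block_bwd(w$Wb, w$gb, cc$b, dcur, d, b)
    ga <- .conv_block_bwd(w$Wa, w$ga, cc$a, gb$dx, d, b)
    dup <- ga$dx[seq_len(ch[l]), , drop = FALSE]
    dskip <- ga$dx[ch[l] + seq_len(ch[l]), , drop = FALSE]
    ub <- nnUpconvBwd(w$Wu, cc$up$x, dup, dimsAt[[l + 1L]], b)
    gdec[[l]] <- list(Wu = ub$dW, Wa = ga$dW, ga = ga$dg, ba = ga$db,
                      Wb = gb$dW, gb = gb$dg, bb = gb$db)
    attr(gdec[[l]], "dskip") <- dskip
    if (l == L - 1L) dBottom <- ub$dx
    else dDec[[l + 1L]] <- if (is.null(dDec[[l + 1L]])) ub$dx else dDec[[l + 1L]] + ub$dx
  }
  glstm <- NULL
  dEncTop <- dBottom
  if (cfg@useConvLSTM) {
    lb <- nnConvLstmBwd(wts$lstm, cache$lstm, cache$encOut[[L]], dimsAt[[L]], b, dBottom)
    glstm <- lb$grads
    dEncTop <- lb$dx
  }
  genc <- vector("list", L)
  dEnc <- vector("list", L)
  dEnc[[L]] <- dEncTop
  for (l in rev(seq_len(L))) {
    d <- dimsAt[[l]]
    w <- wts$enc[[l]]
    cc <- cache$encCache[[l]]
    dcur <- dEnc[[l]]
    if (l < L) {
      dsk <- attr(gdec[[l]], "dskip")
      dcur <- if (is.null(dcur)) dsk else dcur + dsk
    }
    gb <- .conv_block_bwd(w$Wb, w$gb, cc$b, dcur, d, b)
    needDx <- l > 1L
    ga <- .conv_block_bwd(w$Wa, w$ga, cc$a, gb$dx, d, b, needDx = needDx)
    genc[[l]] <- list(Wa = ga$dW, ga = ga$dg, ba = ga$db,
                      Wb = gb$dW, gb = gb$dg, bb = gb$db)
    if (needDx) {
      dx <- ga$dx
      cprev <- ch[l - 1L]
      dpool <- dx[seq_len(cprev), , drop = FALSE]  # drop MSI-channel grads
      dp <- dimsAt[[l - 1L]]
      dEnc[[l - 1L]] <- cpp_maxpool2_bwd(dpool, cache$poolArg[[l]],
                                         as.integer(prod(dp)) * b)
    }
  }
  for (l in seq_len(L - 1L)) attr(gdec[[l]], "dskip") <- NULL
  grads <- list(enc = genc)
  if (cfg@useConvLSTM) grads$lstm <- glstm
  grads$dec <- gdec
  grads$side <- gside
  grads
}

## ---- losses -----------------------------------------------------------

#' Voxel-wise cross-entropy between heatmaps
#'
#' \eqn{CE(H,P) = -(1/n) \sum_i [H_i \log P_i + (1-H_i) \log(1-P_i)]},
#' averaged over all n voxels and channels.  Predictions are clipped to
#' `[eps, 1-eps]` for numerical safety.
#'
#' @param H target heatmap values in \[0,1\] (array/matrix/HeatmapStack).
#' @param P predicted values, same shape.
#' @param eps clipping epsilon (default 1e-7).
#' @return Scalar loss (non-negative for targets in \[0,1\]).
#' @export
ceLoss <- function(H, P, eps = 1e-7) {
  if (is(H, "HeatmapStack")) H <- H@data
  if (is(P, "HeatmapStack")) P <- P@data
  if (!identical(dim(H), dim(P)) && length(H) != length(P))
    .err("H and P must have the same shape", "sinusplan_shape_mismatch")
  if (!is.null(dim(H)) && !is.null(dim(P)) && !identical(dim(H), dim(P)))
    .err("H and P must have the same shape", "sinusplan_shape_mismatch")
  P <- pmin(pmax(P, eps), 1 - eps)
  -mean(H * log(P) + (1 - H) * log(1 - P))
}

#' Deep-supervision loss: sum of three side-output cross-entropies
#'
#' \eqn{FL(H,P) = CE_1(H,P) + CE_2(H,P) + CE_3(H,P)} over the three decoder
#' side outputs (each already upsampled to full resolution).
#'
#' @param H target heatmap.
#' @param sideOutputs list of exactly three predicted stacks.
#' @param eps clipping epsilon.
#' @return Scalar loss.
#' @export
dsLoss <- function(H, sideOutputs, eps = 1e-7) {
  if (!is.list(sideOutputs) || length(sideOutputs) != 3L)
    .err("deep supervision expects exactly three side outputs",
         "sinusplan_bad_arity")
  sum(vapply(sideOutputs, function(P) ceLoss(H, P, eps), 0))
}

## ---- augmentation -----------------------------------------------------

.rotz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

.transform_points <- function(p, center, rotationDeg, scale, inverse = FALSE) {
  p <- .as_points(p)
  pc <- sweep(p, 2L, center, "-")
  if (inverse) {
    q <- (pc %*% .rotz(rotationDeg)) / scale       # R(-th) = t(R(th)) applied rowwise
  } else {
    q <- scale * (pc %*% t(.rotz(rotationDeg)))
  }
  sweep(q, 2L, center, "+")
}

.trilinear <- function(grid, pts) {
  d <- dim(grid)
  pts[, 1] <- pmin(pmax(pts[, 1], 0), d[1] - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), d[2] - 1)
  pts[, 3] <- pmin(pmax(pts[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(pts), rep(d - 2L, each = nrow(pts)))
  i0 <- pmax(i0, 0)
  f <- pts - i0
  idx <- function(dx, dy, dz)
    (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) + d[2] * (i0[, 3] + dz)) + 1
  g <- as.numeric(grid)
  v <- g[idx(0, 0, 0)] * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
       g[idx(1, 0, 0)] * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
       g[idx(0, 1, 0)] * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
       g[idx(1, 1, 0)] * f[, 1] * f[, 2] * (1 - f[, 3]) +
       g[idx(0, 0, 1)] * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
       g[idx(1, 0, 1)] * f[, 1] * (1 - f[, 2]) * f[, 3] +
       g[idx(0, 1, 1)] * (1 - f[, 1]) * f[, 2] * f[, 3] +
       g[idx(1, 1, 1)] * f[, 1] * f[, 2] * f[, 3]
  v
}

.apply_intensity <- function(g, brightness, contrast) {
  if (contrast != 1) g <- mean(g) + contrast * (g - mean(g))
  if (brightness != 0) g <- g + brightness
  g
}

#' Augment a volume and its landmarks jointly
#'
#' Applies one rigid rotation about the volume centre (axial z axis), one
#' isotropic rescale about the same centre, and brightness/contrast
#' intensity jitter to the volume; the identical spatial transform is
#' applied to the landmark coordinates.  Parameters not supplied are drawn
#' uniformly from the configured ranges using the current RNG state, so a
#' fixed seed reproduces the augmentation exactly.  The identity transform
#' (0 degrees, 0 percent, zero jitter) returns the sample unchanged.
#'
#' @param volume a [CBCTVolume-class].
#' @param landmarks a [LandmarkSet-class] in world mm (optional).
#' @param config a [TrainConfig-class] supplying ranges.
#' @param rotation,rescale,brightness,contrast explicit parameter values
#'   (rotation in degrees, rescale fractional, e.g. 0.2 = +20 percent).
#' @return List with `volume`, `landmarks` and `params`.
#' @export
augmentSample <- function(volume, landmarks = NULL, config = trainConfig(),
                          rotation = NULL, rescale = NULL, brightness = NULL,
                          contrast = NULL) {
  if (is.null(rotation)) rotation <- runif(1, config@rotationRange[1], config@rotationRange[2])
  if (is.null(rescale)) rescale <- runif(1, config@rescaleRange[1], config@rescaleRange[2])
  if (is.null(brightness)) brightness <- runif(1, -config@brightnessJitter, config@brightnessJitter)
  if (is.null(contrast)) contrast <- 1 + runif(1, -config@contrastJitter, config@contrastJitter)
  scale <- 1 + rescale
  d <- dim(volume@grid)
  center <- volume@origin + (d - 1) / 2 * volume@spacing
  g <- volume@grid
  if (rotation != 0 || scale != 1) {
    ii <- expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                      z = seq_len(d[3]) - 1)
    w <- voxelToWorld(as.matrix(ii), volume)
    src <- .transform_points(w, center, rotation, scale, inverse = TRUE)
    sv <- worldToVoxel(src, volume)
    g <- array(.trilinear(volume@grid, unclass(sv)), d)
  }
  g <- .apply_intensity(g, brightness, contrast)
  outVol <- cbctVolume(g, spacing = volume@spacing, origin = volume@origin,
                       dtypeBits = volume@dtypeBits)
  outLm <- landmarks
  if (!is.null(landmarks) && nrow(landmarks@coords)) {
    cc <- .transform_points(landmarks@coords, center, rotation, scale)
    rownames(cc) <- rownames(landmarks@coords)
    outLm <- landmarkSet(cc, provenance = landmarks@provenance)
  }
  list(volume = outVol, landmarks = outLm,
       params = list(rotation = rotation, rescale = rescale,
                     brightness = brightness, contrast = contrast))
}

## Sample a transformed VOI patch directly from the parent volume: the
## patch grid points are mapped through the inverse spatial transform and
## trilinearly interpolated, so fine-stage augmentation never resamples the
## whole volume.
.augment_patch <- function(volume, corner, size, rotation, scale, brightness,
                          contrast) {
  d <- dim(volume@grid)
  center <- volume@origin + (d - 1) / 2 * volume@spacing
  ii <- expand.grid(x = corner[1] + seq_len(size[1]) - 1,
                    y = corner[2] + seq_len(size[2]) - 1,
                    z = corner[3] + seq_len(size[3]) - 1)
  w <- voxelToWorld(as.matrix(ii), volume)
  if (rotation != 0 || scale != 1)
    w <- .transform_points(w, center, rotation, scale, inverse = TRUE)
  sv <- unclass(worldToVoxel(w, volume))
  g <- array(.trilinear(volume@grid, sv), size)
  .apply_intensity(g, brightness, contrast)
}

## ---- training ---------------------------------------------------------

.as_sample <- function(s) {
  if (is(s, "PhantomSample")) list(volume = s@volume, landmarks = s@landmarks)
  else if (is.list(s) && !is.null(s$volume)) s
  else .err("dataset elements must be PhantomSample or list(volume, landmarks)",
            "sinusplan_bad_dataset")
}

## heat-target matrix (outChannels x nvox) for landmarks at voxel coords
.heat_target <- function(voxCoords, shape, sigma, outChannels, names) {
  H <- matrix(0, outChannels, prod(shape))
  for (i in seq_len(nrow(voxCoords))) {
    ch <- match(rownames(voxCoords)[i], names)
    v <- pmin(pmax(voxCoords[i, ], 0), shape - 1)
    H[ch, ] <- as.numeric(encodeHeatmap(v, shape, sigma))
  }
  H
}

#' Train a detection-network stage
#'
#' The coarse stage consumes whole volumes block-averaged by the configured
#' downsample factor, with all-landmark heatmap targets; the fine stage
#' consumes VOI patches at native resolution centred on jittered
#' ground-truth locations (one landmark per sample per epoch, cycling
#' through the five), supervised on the target landmark's channel.
#' Optimises the deep-supervision loss (or plain cross-entropy when
#' deep supervision is off) with RMSprop; the learning rate follows
#' [schedulePlateau()] on the validation loss.  Fully reproducible given
#' `trainCfg@seed`.
#'
#' @param stage `"coarse"` or `"fine"`.
#' @param train,val lists of [PhantomSample-class] (or
#'   `list(volume=, landmarks=)`); `val` is required while plateau
#'   scheduling is enabled.
#' @param dnetCfg a [DNetConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param plateau enable reduce-on-plateau scheduling (default TRUE).
#' @param verbose print per-epoch losses.
#' @return A trained [NetModel-class] with per-epoch history.
#' @export
trainDNet <- function(stage = c("coarse", "fine"), train, val = NULL,
                      dnetCfg = dnetConfig(), trainCfg = trainConfig(),
                      plateau = TRUE, verbose = FALSE) {
  stage <- match.arg(stage)
  if (length(train) == 0L) .err("empty training dataset", "sinusplan_empty_dataset")
  if (plateau && (is.null(val) || length(val) == 0L))
    .err("plateau scheduling requires a validation split", "sinusplan_no_validation")
  train <- lapply(train, .as_sample)
  val <- if (is.null(val)) list() else lapply(val, .as_sample)
  nLm <- dnetCfg@outChannels

  prep <- function(s) {
    vn <- cbctVolume(normalizeIntensity(s$volume@grid), spacing = s$volume@spacing,
                     origin = s$volume@origin)
    if (stage == "coarse") {
      dsv <- downsampleVolume(vn, dnetCfg@coarseDownsample)
      if (!all(dim(dsv@grid) == dnetCfg@inputSize))
        .err("downsampled volume does not match the configured input size",
             "sinusplan_bad_config")
      list(vol = dsv, lm = s$landmarks)
    } else list(vol = vn, lm = s$landmarks)
  }
  trainPrep <- lapply(train, prep)
  valPrep <- lapply(val, prep)
  sigma <- if (stage == "coarse") dnetCfg@sigmaCoarse else dnetCfg@sigmaFine
  shape <- if (stage == "coarse") dnetCfg@inputSize else dnetCfg@finePatchSize
  ## the network runs on its stage's grid: whole (downsampled) volumes for
  ## the coarse stage, VOI patches for the fine stage
  netCfg <- dnetCfg
  netCfg@inputSize <- as.integer(shape)
  .check_divisible(netCfg@inputSize, netCfg@levels)
  nvox <- prod(shape)
  baseRate <- min(max((2 * pi * sigma^2)^1.5 / nvox, 1e-4), 0.3)

  ## assemble one training example: input column block + target block
  makeExample <- function(p, epoch, idx, augment) {
    if (augment) {
      rot <- runif(1, trainCfg@rotationRange[1], trainCfg@rotationRange[2])
      sc <- 1 + runif(1, trainCfg@rescaleRange[1], trainCfg@rescaleRange[2])
      br <- runif(1, -trainCfg@brightnessJitter, trainCfg@brightnessJitter)
      ct <- 1 + runif(1, -trainCfg@contrastJitter, trainCfg@contrastJitter)
    } else { rot <- 0; sc <- 1; br <- 0; ct <- 1 }
    if (stage == "coarse") {
      a <- augmentSample(p$vol, p$lm, rotation = rot, rescale = sc - 1,
                         brightness = br, contrast = ct)
      vc <- unclass(worldToVoxel(a$landmarks@coords, a$volume))
      list(x = as.numeric(a$volume@grid),
           H = .heat_target(vc, shape, sigma, nLm, LANDMARK_NAMES),
           mask = rep(1, nLm))
    } else {
      li <- ((idx - 1L + epoch - 1L) %% nLm) + 1L
      nm <- LANDMARK_NAMES[li]
      d <- dim(p$vol@grid)
      center <- p$vol@origin + (d - 1) / 2 * p$vol@spacing
      lw <- .transform_points(p$lm@coords[nm, , drop = FALSE], center, rot, sc)
      cv <- as.numeric(worldToVoxel(as.numeric(lw), p$vol))
      jit <- if (augment) runif(3, -2, 2) else rep(0, 3)
      corner <- round(cv + jit) - shape %/% 2L
      corner <- pmin(pmax(corner, 0L), d - shape)
      g <- .augment_patch(p$vol, corner, shape, rot, sc, br, ct)
      local <- pmin(pmax(cv - corner, 0), shape - 1)
      H <- matrix(0, nLm, nvox)
      H[li, ] <- as.numeric(encodeHeatmap(local, shape, sigma))
      mask <- rep(0, nLm); mask[li] <- 1
      list(x = as.numeric(g), H = H, mask = mask)
    }
  }

  batchLoss <- function(model, bn, xs, Hs, masks, b, trainMode) {
    fwd <- .dnetFwd(model, bn, xs, netCfg, b, train = trainMode)
    ## per-channel mask (fine stage supervises only the target channel)
    Hm <- Hs
    nEff <- sum(masks)
    dz <- list(); loss <- 0
    for (nm in names(fwd$sides)) {
      P <- fwd$sides[[nm]]
      diff <- (P - Hm) * masks
      Pc <- pmin(pmax(P, 1e-7), 1 - 1e-7)
      ll <- -(Hm * log(Pc) + (1 - Hm) * log(1 - Pc)) * masks
      loss <- loss + sum(ll) / nEff
      dz[[nm]] <- diff / nEff
    }
    list(loss = loss, dz = dz, fwd = fwd)
  }

  .with_seed(trainCfg@seed, {
    net <- buildDNet(netCfg, seed = sample.int(1e6, 1), baseRate = baseRate)
    wts <- net@weights; bn <- net@bnStats
    opt <- rmspropInit(wts)
    lr <- trainCfg@initialLr
    hist <- vector("list", trainCfg@epochs)
    valLosses <- numeric(0)
    nTr <- length(trainPrep)
    for (epoch in seq_len(trainCfg@epochs)) {
      ord <- sample(nTr)
      epLoss <- 0; nb <- 0L
      for (start in seq(1L, nTr, by = trainCfg@batchSize)) {
        ids <- ord[start:min(start + trainCfg@batchSize - 1L, nTr)]
        b <- length(ids)
        ex <- lapply(seq_along(ids), function(j)
          makeExample(trainPrep[[ids[j]]], epoch, ids[j], augment = TRUE))
        xs <- matrix(unlist(lapply(ex, `[[`, "x")), nrow = 1L)
        Hs <- do.call(cbind, lapply(ex, `[[`, "H"))
        masks <- do.call(cbind, lapply(ex, function(e)
          matrix(rep(e$mask, nvox), nLm, nvox)))
        bl <- batchLoss(wts, bn, xs, Hs, masks, b, trainMode = TRUE)
        bn <- bl$fwd$bn
        grads <- .dnetBwd(wts, netCfg, bl$fwd$cache, bl$dz, b)
        st <- rmspropStep(wts, grads, opt, lr)
        wts <- st$weights; opt <- st$state
        epLoss <- epLoss + bl$loss; nb <- nb + 1L
      }
      trLoss <- epLoss / nb
      vLoss <- NA_real_
      if (length(valPrep)) {
        vl <- 0; nvb <- 0L
        for (start in seq(1L, length(valPrep), by = trainCfg@batchSize)) {
          ids <- start:min(start + trainCfg@batchSize - 1L, length(valPrep))
          b <- length(ids)
          ex <- lapply(ids, function(j)
            makeExample(valPrep[[j]], 1L, j, augment = FALSE))
          xs <- matrix(unlist(lapply(ex, `[[`, "x")), nrow = 1L)
          Hs <- do.call(cbind, lapply(ex, `[[`, "H"))
          masks <- do.call(cbind, lapply(ex, function(e)
            matrix(rep(e$mask, nvox), nLm, nvox)))
          bl <- batchLoss(wts, bn, xs, Hs, masks, b, trainMode = FALSE)
          vl <- vl + bl$loss * b; nvb <- nvb + b
        }
        vLoss <- vl / nvb
        valLosses <- c(valLosses, vLoss)
        if (plateau)
          lr <- tail(schedulePlateau(valLosses, trainCfg@initialLr,
                                     trainCfg@plateauFactor,
                                     trainCfg@plateauPatience), 1L)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train = trLoss, val = vLoss, lr = lr)
      if (verbose)
        message(sprintf("[%s] epoch %d/%d train %.5f val %.5f lr %.2g",
                        stage, epoch, trainCfg@epochs, trLoss, vLoss, lr))
    }
    new("NetModel", weights = wts, bnStats = bn, config = netCfg,
        history = do.call(rbind, hist),
        meta = list(stage = stage, sigma = sigma,
                    coarseDownsample = netCfg@coarseDownsample,
                    landmarkNames = LANDMARK_NAMES[seq_len(nLm)]))
  })
}

## ---- inference --------------------------------------------------------

## forward a single grid through a NetModel, returning the head's sigmoid
## maps as a (outChannels x nvox) matrix
.net_predict <- function(model, grid) {
  x <- matrix(as.numeric(grid), nrow = 1L)
  fwd <- .dnetFwd(model@weights, model@bnStats, x, model@config, 1L, train = FALSE)
  fwd$sides[["l1"]]
}

#' Detect the five landmarks with the coarse-to-fine cascade
#'
#' The coarse network predicts whole-volume heatmaps on the downsampled
#' grid; each channel is decoded to a peak, a VOI patch is cropped around
#' the peak at native resolution (clamped at boundaries, never padded), the
#' fine network re-predicts within the patch, and the decoded fine peak is
#' mapped back through the patch offset to world mm.  A constant
#' (degenerate) coarse channel flags that landmark as undetected; a
#' degenerate fine channel falls back to the coarse estimate.
#'
#' @param coarse,fine trained [NetModel-class] handles (or, for oracle
#'   testing, functions: `coarse(volume)` returning a [HeatmapStack-class]
#'   on the full grid and `fine(patchArray, name)` returning a 3D array).
#' @param volume a [CBCTVolume-class].
#' @param returnStack also return full-grid fine heatmaps for the
#'   classifier (default TRUE).
#' @return List with `landmarks` (a predicted [LandmarkSet-class];
#'   undetected names in attribute `"undetected"`) and `stack` (a
#'   [HeatmapStack-class] on the full grid, zero outside each VOI).
#' @export
detectLandmarks <- function(coarse, fine, volume, returnStack = TRUE) {
  vn <- cbctVolume(normalizeIntensity(volume@grid), spacing = volume@spacing,
                   origin = volume@origin)
  if (is.function(coarse)) {
    stackC <- coarse(volume)
    refVol <- volume
    arrC <- stackC@data
    names <- stackC@landmarkNames
    fineSize <- rep(min(16L, min(dim(volume@grid))), 3L)
    sigmaF <- stackC@sigma
  } else {
    refVol <- downsampleVolume(vn, coarse@config@coarseDownsample)
    P <- .net_predict(coarse, refVol@grid)
    names <- coarse@meta$landmarkNames
    arrC <- array(t(P), c(dim(refVol@grid), length(names)))
    fineSize <- if (is.function(fine)) coarse@config@finePatchSize else
      fine@config@finePatchSize
    sigmaF <- if (is.function(fine)) coarse@config@sigmaFine else
      fine@config@sigmaFine
  }
  d <- dim(volume@grid)
  undetected <- character(0)
  pts <- list()
  stackArr <- if (returnStack) array(0, c(d, length(names))) else NULL
  offsets <- matrix(0L, length(names), 3L)
  for (i in seq_along(names)) {
    nm <- names[i]
    pkC <- tryCatch(decodeHeatmap(arrC[, , , i]), error = function(e) NULL)
    if (is.null(pkC)) { undetected <- c(undetected, nm); next }
    wC <- voxelToWorld(pkC, refVol)
    cFull <- as.numeric(worldToVoxel(wC, volume))
    patch <- cropVOI(vn, cFull, fineSize)
    if (is.function(fine)) {
      chF <- fine(patch@grid, nm)
    } else {
      PF <- .net_predict(fine, patch@grid)
      chF <- array(PF[i, ], dim(patch@grid))
    }
    pkF <- tryCatch(decodeHeatmap(chF), error = function(e) NULL)
    if (is.null(pkF)) {
      pts[[nm]] <- as.numeric(wC)       # fall back to the coarse estimate
    } else {
      parentIdx <- patchToParent(pkF, patch)
      pts[[nm]] <- as.numeric(voxelToWorld(parentIdx, volume))
      if (returnStack) {
        stackArr[patch@offset[1] + seq_len(fineSize[1]),
                 patch@offset[2] + seq_len(fineSize[2]),
                 patch@offset[3] + seq_len(fineSize[3]), i] <- chF
      }
    }
    offsets[i, ] <- patch@offset
  }
  if (!length(pts)) .err("no landmark could be detected", "sinusplan_no_detection")
  lm <- landmarkSet(pts, provenance = "predicted")
  attr(lm, "undetected") <- undetected
  out <- list(landmarks = lm)
  if (returnStack)
    out$stack <- heatmapStack(pmin(pmax(stackArr, 0), 1), sigma = sigmaF,
                              landmarkNames = names)
  out
}
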