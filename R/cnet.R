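## Distance-prior-guided 3D classification network (C-Net).
##
## Two-channel input (normalised intensity + the voxelwise maximum over the
## five landmark heatmaps), 3x3x3 conv + batch-norm + ReLU stages with
## max-pooling, 3D global average pooling, concatenation of the three
## normalised inter-landmark distance priors, and a dense softmax head over
## the five surgical classes.

#' CNetConfig: classification-network configuration
#'
#' @slot convWidths integer vector, channel width per conv stage.
#' @slot inputSize integer(3), classifier grid dims.
#' @slot priorNormalization numeric, divisor applied to mm distances before
#'   concatenation (keeps them O(1)).
#' @slot usePriors logical; FALSE disables the prior pathway (ablation).
#' @slot heatmapFusion `"max"` fuses the five heatmaps into one channel by
#'   voxelwise maximum (two-channel input); `"channels"` keeps them
#'   separate (six-channel input).
#' @slot hiddenUnits integer, width of the dense hidden layer.
#' @slot nClasses integer, fixed at 5.
#' @exportClass CNetConfig
setClass("CNetConfig",
  representation(convWidths = "integer", inputSize = "integer",
                 priorNormalization = "numeric", usePriors = "logical",
                 heatmapFusion = "character", hiddenUnits = "integer",
                 nClasses = "integer"))

setValidity("CNetConfig", function(object) {
  if (object@nClasses != 5L) return("nClasses must be 5")
  if (any(object@convWidths < 1L)) return("conv widths must be positive")
  if (!object@heatmapFusion %in% c("max", "channels"))
    return("heatmapFusion must be 'max' or 'channels'")
  if (any(object@inputSize %% 2L^length(object@convWidths) != 0L))
    return("inputSize must be divisible by 2^(number of conv stages)")
  if (object@priorNormalization <= 0) return("priorNormalization must be > 0")
  TRUE
})

#' Construct a CNetConfig
#'
#' @param convWidths channel widths of the conv stages.
#' @param inputSize classifier grid dims (recycled to 3).
#' @param priorNormalization divisor for the mm distance priors.
#' @param usePriors include the distance-prior pathway.
#' @param heatmapFusion `"max"` or `"channels"`.
#' @param hiddenUnits dense hidden width.
#' @return A validated [CNetConfig-class].
#' @export
cnetConfig <- function(convWidths = c(8L, 16L, 32L), inputSize = 16L,
                       priorNormalization = 20, usePriors = TRUE,
                       heatmapFusion = "max", hiddenUnits = 32L) {
  new("CNetConfig", convWidths = as.integer(convWidths),
      inputSize = rep(as.integer(inputSize), length.out = 3L),
      priorNormalization = priorNormalization, usePriors = usePriors,
      heatmapFusion = heatmapFusion, hiddenUnits = as.integer(hiddenUnits),
      nClasses = 5L)
}

#' Compute the three distance priors from a landmark set
#'
#' The absolute Euclidean distances |AC-SF| (residual bone height),
#' |MH-LH| (horizontal bone width) and |AC-CEJ| (vertical step), in world
#' mm; invariant to rigid translation and rotation of the landmark set.
#'
#' @param landmarks a [LandmarkSet-class] with all five landmarks.
#' @return A [DistancePriors-class].
#' @examples
#' lm <- landmarkSet(list(AC = c(0, 0, 0), SF = c(0, 0, 7),
#'                        MH = c(-4, 0, 0), LH = c(4, 0, 0),
#'                        CEJ = c(0, 0, -1)))
#' priorValues(computeDistancePriors(lm))
#' @export
computeDistancePriors <- function(landmarks) {
  cc <- landmarks@coords
  if (!all(LANDMARK_NAMES %in% rownames(cc)))
    .err(paste0("missing landmark(s): ",
                paste(setdiff(LANDMARK_NAMES, rownames(cc)), collapse = ", ")),
         "sinusplan_missing_landmark")
  d <- function(a, b) sqrt(sum((cc[a, ] - cc[b, ])^2))
  distancePriors(d("AC", "SF"), d("MH", "LH"), d("AC", "CEJ"))
}

#' Build an untrained classification network
#'
#' The feature vector after 3D global average pooling has length equal to
#' the last conv width; with the prior pathway enabled the three normalised
#' distances are concatenated, giving pooled + 3 features into the dense
#' head.
#'
#' @param config a [CNetConfig-class].
#' @param seed RNG seed for initialisation.
#' @return An untrained [NetModel-class].
#' @export
buildCNet <- function(config, seed = 1L) {
  validObject(config)
  nIn <- if (config@heatmapFusion == "max") 2L else 6L
  widths <- config@convWidths
  .with_seed(seed, {
    wts <- list()
    wts$conv <- lapply(seq_along(widths), function(l) {
      cin <- if (l == 1L) nIn else widths[l - 1L]
      list(W = .he_init(widths[l], 27 * cin, 27 * cin),
           g = rep(1, widths[l]), b = rep(0, widths[l]))
    })
    featLen <- tail(widths, 1L) + if (config@usePriors) 3L else 0L
    wts$fc1 <- list(W = .he_init(config@hiddenUnits, featLen, featLen),
                    b = rep(0, config@hiddenUnits))
    wts$fc2 <- list(W = .he_init(config@nClasses, config@hiddenUnits,
                                 config@hiddenUnits),
                    b = rep(0, config@nClasses))
    bn <- list(conv = lapply(widths, function(w)
      list(mean = rep(0, w), var = rep(1, w))))
    new("NetModel", weights = wts, bnStats = bn, config = config,
        history = data.frame(), meta = list(stage = "untrained"))
  })
}

#' Build the classifier input tensor from a volume and a heatmap stack
#'
#' Channel 1 is the min-max normalised intensity, block-averaged to the
#' classifier grid; the heatmap channels follow the configured fusion
#' (voxelwise maximum by default).  The stack must live on the volume's
#' full grid.
#'
#' @param volume a [CBCTVolume-class].
#' @param stack a [HeatmapStack-class] on the same grid.
#' @param config a [CNetConfig-class].
#' @return Numeric matrix, channels x classifier-grid voxels.
#' @export
prepareCNetInput <- function(volume, stack, config) {
  d <- dim(volume@grid)
  f <- unique(d %/% config@inputSize)
  if (length(f) != 1L || any(config@inputSize * f != d))
    .err("volume dims must be an integer multiple of the classifier input size",
         "sinusplan_shape_mismatch")
  vn <- normalizeIntensity(volume@grid)
  ch1 <- cpp_avgpool(matrix(as.numeric(vn), nrow = 1L), 1L, d[1], d[2], d[3],
                     1L, f)
  hm <- stack@data
  if (!all(dim(hm)[1:3] == d))
    .err("heatmap stack grid must match the volume grid", "sinusplan_shape_mismatch")
  if (config@heatmapFusion == "max") {
    fused <- hm[, , , 1]
    for (i in seq_len(dim(hm)[4])[-1]) fused <- pmax(fused, hm[, , , i])
    ch2 <- cpp_avgpool(matrix(as.numeric(fused), nrow = 1L), 1L,
                       d[1], d[2], d[3], 1L, f)
    rbind(ch1, ch2)
  } else {
    chs <- lapply(seq_len(dim(hm)[4]), function(i)
      cpp_avgpool(matrix(as.numeric(hm[, , , i]), nrow = 1L), 1L,
                  d[1], d[2], d[3], 1L, f))
    do.call(rbind, c(list(ch1), chs))
  }
}

.softmax <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

## Forward: xs (channels x nvox*b), priors (3 x b).  Returns class
## probabilities (5 x b) and caches for the backward pass.
.cnetFwd <- function(wts, bn, xs, priors, cfg, b, train = FALSE) {
  dims <- cfg@inputSize
  caches <- list(); cur <- xs
  for (l in seq_along(wts$conv)) {
    w <- wts$conv[[l]]
    cb <- .conv_block_fwd(w$W, w$g, w$b, cur, dims, b, train, bn$conv[[l]])
    bn$conv[[l]] <- cb$stats
    mp <- cpp_maxpool2(cb$y, nrow(cb$y), dims[1], dims[2], dims[3], b)
    caches[[l]] <- list(block = cb$cache, arg = mp$argmax,
                        dims = dims, ncolIn = as.integer(prod(dims)) * b)
    cur <- mp$y
    dims <- dims %/% 2L
  }
  ## global average pooling per sample
  nvox <- prod(dims)
  feat <- cur %*% kronecker(diag(b), matrix(1 / nvox, nvox, 1))
  featIn <- feat
  if (cfg@usePriors)
    featIn <- rbind(feat, priors / cfg@priorNormalization)
  f1 <- nnDenseFwd(wts$fc1$W, wts$fc1$b, featIn)
  h1 <- nnReluFwd(f1$y)
  f2 <- nnDenseFwd(wts$fc2$W, wts$fc2$b, h1)
  probs <- .softmax(f2$y)
  list(probs = probs, bn = bn,
       cache = list(conv = caches, featIn = featIn, h1 = h1, f2x = h1,
                    poolDims = dims, cur = cur, logits = f2$y))
}

.cnetBwd <- function(wts, cfg, cache, dlogits, b) {
  g2 <- nnDenseBwd(wts$fc2$W, cache$h1, dlogits)
  dh1 <- nnReluBwd(cache$h1, g2$dx)
  g1 <- nnDenseBwd(wts$fc1$W, cache$featIn, dh1)
  dfeatIn <- g1$dx
  nFeat <- nrow(cache$cur)
  dfeat <- dfeatIn[seq_len(nFeat), , drop = FALSE]
  nvox <- prod(cache$poolDims)
  ## spread GAP gradient uniformly over the pooled voxels
  dcur <- matrix(0, nFeat, nvox * b)
  for (s in seq_len(b))
    dcur[, (s - 1L) * nvox + seq_len(nvox)] <- dfeat[, s] / nvox
  gconv <- vector("list", length(wts$conv))
  for (l in rev(seq_along(wts$conv))) {
    cc <- cache$conv[[l]]
    w <- wts$conv[[l]]
    dpool <- cpp_maxpool2_bwd(dcur, cc$arg, cc$ncolIn)
    cb <- .conv_block_bwd(w$W, w$g, cc$block, dpool, cc$dims, b, needDx = l > 1L)
    gconv[[l]] <- list(W = cb$dW, g = cb$dg, b = cb$db)
    dcur <- cb$dx
  }
  list(conv = gconv, fc1 = list(W = g1$dW, b = g1$db),
       fc2 = list(W = g2$dW, b = g2$db))
}

#' Train the classification network
#'
#' Optimises categorical cross-entropy over the five surgical classes with
#' RMSprop and the same plateau schedule contract as the detection stage.
#' Heatmaps in the records may come from D-Net predictions (the default
#' pipeline) or from ground-truth encodings (teacher mode); both pass
#' through the same interface.
#'
#' @param records list of records, each `list(x = input tensor from
#'   [prepareCNetInput()], priors = DistancePriors or numeric(3) mm,
#'   label = class)`.
#' @param val optional validation records (required for plateau scheduling).
#' @param config a [CNetConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param plateau enable reduce-on-plateau scheduling.
#' @param verbose print per-epoch losses.
#' @return A trained [NetModel-class].
#' @export
trainCNet <- function(records, val = NULL, config = cnetConfig(),
                      trainCfg = trainConfig(), plateau = TRUE,
                      verbose = FALSE) {
  if (length(records) == 0L) .err("empty training dataset", "sinusplan_empty_dataset")
  if (plateau && (is.null(val) || length(val) == 0L))
    .err("plateau scheduling requires a validation split", "sinusplan_no_validation")
  labs <- vapply(records, function(r) r$label, "")
  if (!all(labs %in% SURGICAL_CLASSES))
    .err("labels must be surgical classes A, B, B', C, C'", "sinusplan_bad_class")
  absent <- setdiff(SURGICAL_CLASSES, labs)
  if (length(absent))
    warning("class(es) absent from training labels: ",
            paste(absent, collapse = ", "))
  getPriors <- function(r) {
    p <- r$priors
    if (is(p, "DistancePriors")) unname(priorValues(p)) else as.numeric(p)
  }
  Y <- function(lab) { y <- numeric(5); y[match(lab, SURGICAL_CLASSES)] <- 1; y }

  .with_seed(trainCfg@seed, {
    net <- buildCNet(config, seed = sample.int(1e6, 1))
    wts <- net@weights; bn <- net@bnStats
    opt <- rmspropInit(wts)
    lr <- trainCfg@initialLr
    hist <- vector("list", trainCfg@epochs)
    valLosses <- numeric(0)
    n <- length(records)
    evalSet <- function(set, wts, bn) {
      tl <- 0
      for (start in seq(1L, length(set), by = trainCfg@batchSize)) {
        ids <- start:min(start + trainCfg@batchSize - 1L, length(set))
        b <- length(ids)
        xs <- do.call(cbind, lapply(set[ids], `[[`, "x"))
        pr <- vapply(set[ids], getPriors, numeric(3))
        ys <- vapply(set[ids], function(r) Y(r$label), numeric(5))
        fwd <- .cnetFwd(wts, bn, xs, pr, config, b, train = FALSE)
        P <- pmin(pmax(fwd$probs, 1e-12), 1)
        tl <- tl - sum(log(P[cbind(match(vapply(set[ids], `[[`, "", "label"),
                                         SURGICAL_CLASSES), seq_len(b))]))
      }
      tl / length(set)
    }
    for (epoch in seq_len(trainCfg@epochs)) {
      ord <- sample(n)
      epLoss <- 0; nb <- 0L
      for (start in seq(1L, n, by = trainCfg@batchSize)) {
        ids <- ord[start:min(start + trainCfg@batchSize - 1L, n)]
        b <- length(ids)
        xs <- do.call(cbind, lapply(records[ids], `[[`, "x"))
        pr <- vapply(records[ids], getPriors, numeric(3))
        ys <- vapply(records[ids], function(r) Y(r$label), numeric(5))
        fwd <- .cnetFwd(wts, bn, xs, pr, config, b, train = TRUE)
        bn <- fwd$bn
        P <- fwd$probs
        loss <- -mean(log(pmax(P[ys > 0], 1e-12)))
        dlogits <- (P - ys) / b
        grads <- .cnetBwd(wts, config, fwd$cache, dlogits, b)
        st <- rmspropStep(wts, grads, opt, lr)
        wts <- st$weights; opt <- st$state
        epLoss <- epLoss + loss; nb <- nb + 1L
      }
      vLoss <- NA_real_
      if (!is.null(val) && length(val)) {
        vLoss <- evalSet(val, wts, bn)
        valLosses <- c(valLosses, vLoss)
        if (plateau)
          lr <- tail(schedulePlateau(valLosses, trainCfg@initialLr,
                                     trainCfg@plateauFactor,
                                     trainCfg@plateauPatience), 1L)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train = epLoss / nb,
                                  val = vLoss, lr = lr)
      if (verbose)
        message(sprintf("[cnet] epoch %d/%d train %.5f val %.5f",
                        epoch, trainCfg@epochs, epLoss / nb, vLoss))
    }
    new("NetModel", weights = wts, bnStats = bn, config = config,
        history = do.call(rbind, hist), meta = list(stage = "cnet"))
  })
}

#' Classify a volume into a surgical class
#'
#' Channel 1 is the normalised intensity, channel 2 the voxelwise maximum
#' over the five landmark heatmaps (fusion is symmetric under channel
#' permutation); the three distance priors join the feature vector after
#' global average pooling.  The argmax class is returned with ties broken
#' by the fixed class order A, B, B', C, C'.
#'
#' @param model a trained C-Net [NetModel-class].
#' @param volume a [CBCTVolume-class].
#' @param heatmaps a [HeatmapStack-class] on the same grid.
#' @param priors a [DistancePriors-class].
#' @return List with `class`, `probabilities` (named, sums to 1) and
#'   `priors`.
#' @export
classifySample <- function(model, volume, heatmaps, priors) {
  cfg <- model@config
  xs <- prepareCNetInput(volume, heatmaps, cfg)
  pr <- matrix(unname(priorValues(priors)), 3L, 1L)
  fwd <- .cnetFwd(model@weights, model@bnStats, xs, pr, cfg, 1L, train = FALSE)
  p <- as.numeric(fwd$probs)
  names(p) <- SURGICAL_CLASSES
  cls <- SURGICAL_CLASSES[which.max(p)]
  list(class = cls, probabilities = p, priors = priors)
}

#' Full two-stage prediction: landmarks, heatmaps, priors, class
#'
#' Runs the detection cascade, derives the distance priors from the
#' predicted landmarks, and classifies.  Also reports the rule-based plan
#' from the predicted landmarks for comparison.
#'
#' @param volume a [CBCTVolume-class].
#' @param coarse,fine trained detection [NetModel-class] handles.
#' @param cnet trained classification [NetModel-class].
#' @param thresholds [DefectThresholds-class] for the rule-based comparison.
#' @return List with `class`, `probabilities`, `priors`, `landmarks`,
#'   `rulePlan`.
#' @export
predictPlan <- function(volume, coarse, fine, cnet,
                        thresholds = defectThresholds()) {
  det <- detectLandmarks(coarse, fine, volume, returnStack = TRUE)
  priors <- computeDistancePriors(det$landmarks)
  cls <- classifySample(cnet, volume, det$stack, priors)
  rule <- planFromLandmarks(det$landmarks, thresholds)
  list(class = cls$class, probabilities = cls$probabilities, priors = priors,
       landmarks = det$landmarks, rulePlan = rule)
}
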