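## Minibatch neural-network primitives for the volumetric networks.
##
## Feature tensors are matrices with channels in rows and voxels in columns
## (x fastest, then y, z, then batch sample), matching the layout of the
## compiled routines.  Convolutions run as 27 shifted BLAS GEMMs on a
## 1-voxel zero-padded copy of the tensor (no im2col buffer); every
## primitive returns the values needed for its exact backward pass.  All
## computation is double precision and single-threaded deterministic.

.he_init <- function(nout, nin, fan) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / fan)), nout, nin)
}

## ---- 3x3x3 convolution (zero-padded, stride 1) ------------------------

nnConv3Fwd <- function(W, x, dims, b) {
  cin <- nrow(x)
  list(y = cpp_conv3_fwd(x, W, cin, dims[1], dims[2], dims[3], b), x = x)
}

nnConv3Bwd <- function(W, x, dy, dims, b, needDx = TRUE) {
  cin <- ncol(W) %/% 27L
  r <- cpp_conv3_bwd(x, W, dy, cin, dims[1], dims[2], dims[3], b, needDx)
  list(dx = if (needDx) r$dx else NULL, dW = r$dW)
}

## ---- 1x1x1 convolution (a per-voxel linear map) -----------------------

nnConv1Fwd <- function(W, bias, x) list(y = W %*% x + bias, x = x)
nnConv1Bwd <- function(W, x, dy)
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))

## ---- transposed convolution, kernel 2 stride 2 ------------------------

nnUpconvFwd <- function(W2, x, dims, b) {
  ## W2: (8*cout) x cin
  G <- W2 %*% x
  cout <- nrow(W2) %/% 8L
  list(y = cpp_upconv_scatter(G, cout, dims[1], dims[2], dims[3], b), x = x)
}

nnUpconvBwd <- function(W2, x, dy, dims, b) {
  cout <- nrow(W2) %/% 8L
  dG <- cpp_upconv_gather(dy, cout, dims[1], dims[2], dims[3], b)
  list(dx = crossprod(W2, dG), dW = tcrossprod(dG, x))
}

## ---- batch normalisation (fused with ReLU in C++) ---------------------

## batch-norm statistics use eps 1e-5; the fused forward/backward passes
## live in C++ (cpp_bnrelu_fwd / cpp_bnrelu_bwd)
.BN_EPS <- 1e-5

## ---- activations ------------------------------------------------------

nnReluFwd <- function(x) { y <- x; y[y < 0] <- 0; y }
nnReluBwd <- function(y, dy) { dy[y <= 0] <- 0; dy }

nnSigmoid <- function(x) 1 / (1 + exp(-x))

## ---- dense layer ------------------------------------------------------

nnDenseFwd <- function(W, bias, x) list(y = W %*% x + bias, x = x)
nnDenseBwd <- function(W, x, dy)
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))

## ---- bidirectional convolutional LSTM over axial slices ---------------
##
## Operates at the network bottleneck: the (nx, ny, nz) grid is read as a
## sequence of nz axial slices; each direction runs a convLSTM with 3x3
## in-plane gate convolutions and hidden width equal to the input channels;
## the two hidden sequences are concatenated and projected back with a
## 1x1 convolution.

.lstm_slice_cols <- function(dims, b) {
  ## column indices (1-based) of each z slice across the batch
  nxy <- dims[1] * dims[2]
  lapply(seq_len(dims[3]) - 1L, function(k) {
    as.vector(outer(seq_len(nxy), (k + (seq_len(b) - 1L) * dims[3]) * nxy, "+"))
  })
}

nnConvLstmInit <- function(c, seed) {
  h <- c
  .with_seed(seed, {
    mk <- function() {
      W <- .he_init(4 * h, 27 * (c + h), 27 * (c + h)) * 0.5
      bias <- rep(0, 4 * h)
      bias[(h + 1):(2 * h)] <- 1      # forget-gate bias
      list(W = W, b = bias)
    }
    list(fwd = mk(), bwd = mk(),
         proj = list(W = .he_init(c, 2 * h, 2 * h), b = rep(0, c)))
  })
}

.lstm_dir_fwd <- function(Wg, bg, x, dims, b, order) {
  c <- nrow(x); h <- c
  sliceCols <- .lstm_slice_cols(dims, b)
  ncolSlice <- length(sliceCols[[1]])
  hprev <- matrix(0, h, ncolSlice); cprev <- matrix(0, h, ncolSlice)
  caches <- vector("list", dims[3]); hs <- vector("list", dims[3])
  d2 <- c(dims[1], dims[2], 1L)
  for (t in order) {
    xt <- x[, sliceCols[[t]], drop = FALSE]
    inp <- rbind(xt, hprev)
    z <- cpp_conv3_fwd(inp, Wg, c + h, d2[1], d2[2], 1L, b) + bg
    ig <- nnSigmoid(z[1:h, , drop = FALSE])
    fg <- nnSigmoid(z[(h + 1):(2 * h), , drop = FALSE])
    og <- nnSigmoid(z[(2 * h + 1):(3 * h), , drop = FALSE])
    gg <- tanh(z[(3 * h + 1):(4 * h), , drop = FALSE])
    cell <- fg * cprev + ig * gg
    tc <- tanh(cell)
    ht <- og * tc
    caches[[t]] <- list(inp = inp, i = ig, f = fg, o = og, g = gg,
                        cprev = cprev, tc = tc)
    hs[[t]] <- ht
    hprev <- ht; cprev <- cell
  }
  list(hs = hs, caches = caches, sliceCols = sliceCols)
}

.lstm_dir_bwd <- function(Wg, dirCache, dH, dims, b) {
  h <- nrow(dH[[1]]); c <- h
  d2 <- c(dims[1], dims[2], 1L)
  ncolSlice <- ncol(dH[[1]])
  dhn <- matrix(0, h, ncolSlice); dcn <- matrix(0, h, ncolSlice)
  dW <- matrix(0, nrow(Wg), ncol(Wg)); db <- rep(0, nrow(Wg))
  dxs <- vector("list", dims[3])
  for (t in rev(dirCache$order)) {
    cc <- dirCache$caches[[t]]
    dh <- dH[[t]] + dhn
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dcn
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$cprev
    dcn <- dc * cc$f
    dz <- rbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o), dg * (1 - cc$g^2))
    r <- cpp_conv3_bwd(cc$inp, Wg, dz, 2L * c, d2[1], d2[2], 1L, b, TRUE)
    dW <- dW + r$dW
    db <- db + rowSums(dz)
    dxs[[t]] <- r$dx[1:c, , drop = FALSE]
    dhn <- r$dx[(c + 1):(2 * c), , drop = FALSE]
  }
  list(dxs = dxs, dW = dW, db = db)
}

nnConvLstmFwd <- function(P, x, dims, b) {
  c <- nrow(x)
  fw <- .lstm_dir_fwd(P$fwd$W, P$fwd$b, x, dims, b, seq_len(dims[3]))
  fw$order <- seq_len(dims[3])
  bw <- .lstm_dir_fwd(P$bwd$W, P$bwd$b, x, dims, b, rev(seq_len(dims[3])))
  bw$order <- rev(seq_len(dims[3]))
  Hcat <- matrix(0, 2 * c, ncol(x))
  for (t in seq_len(dims[3])) {
    cols <- fw$sliceCols[[t]]
    Hcat[1:c, cols] <- fw$hs[[t]]
    Hcat[(c + 1):(2 * c), cols] <- bw$hs[[t]]
  }
  proj <- P$proj$W %*% Hcat + P$proj$b
  y <- nnReluFwd(proj)
  list(y = y, fw = fw, bw = bw, Hcat = Hcat, yRaw = y)
}

nnConvLstmBwd <- function(P, cache, x, dims, b, dy) {
  c <- nrow(x)
  dy <- nnReluBwd(cache$yRaw, dy)
  dprojW <- tcrossprod(dy, cache$Hcat)
  dprojB <- rowSums(dy)
  dHcat <- crossprod(P$proj$W, dy)
  dHf <- lapply(seq_len(dims[3]), function(t)
    dHcat[1:c, cache$fw$sliceCols[[t]], drop = FALSE])
  dHb <- lapply(seq_len(dims[3]), function(t)
    dHcat[(c + 1):(2 * c), cache$fw$sliceCols[[t]], drop = FALSE])
  gf <- .lstm_dir_bwd(P$fwd$W, cache$fw, dHf, dims, b)
  gb <- .lstm_dir_bwd(P$bwd$W, cache$bw, dHb, dims, b)
  dx <- matrix(0, c, ncol(x))
  for (t in seq_len(dims[3])) {
    cols <- cache$fw$sliceCols[[t]]
    dx[, cols] <- gf$dxs[[t]] + gb$dxs[[t]]
  }
  list(dx = dx,
       grads = list(fwd = list(W = gf$dW, b = gf$db),
                    bwd = list(W = gb$dW, b = gb$db),
                    proj = list(W = dprojW, b = dprojB)))
}

## ---- RMSprop ----------------------------------------------------------

rmspropInit <- function(weights) rapply(weights, function(w) w * 0, how = "replace")

rmspropStep <- function(weights, grads, state, lr, rho = 0.9, eps = 1e-7) {
  upd <- function(w, g, v) {
    v <- rho * v + (1 - rho) * g * g
    list(w = w - lr * g / (sqrt(v) + eps), v = v)
  }
  walk <- function(w, g, v) {
    if (is.list(w)) {
      out <- Map(walk, w, g, v)
      list(w = lapply(out, `[[`, "w"), v = lapply(out, `[[`, "v"))
    } else upd(w, g, v)
  }
  res <- walk(weights, grads, state)
  list(weights = res$w, state = res$v)
}

## ---- learning-rate plateau schedule -----------------------------------

#' Reduce-on-plateau learning-rate schedule
#'
#' Tracks the best (lowest) validation loss; after `patience` consecutive
#' epochs without strict improvement the learning rate is multiplied by
#' `factor` and the patience counter restarts, so each completed plateau
#' reduces the rate exactly once.
#'
#' @param valLosses numeric vector of per-epoch validation losses so far.
#' @param initialLr starting learning rate.
#' @param factor multiplicative reduction factor in (0, 1) (default 0.5).
#' @param patience epochs without improvement before reducing (default 25).
#' @return Numeric vector: the learning rate in effect *after* each epoch
#'   (element t is the rate for epoch t + 1).
#' @export
schedulePlateau <- function(valLosses, initialLr, factor = 0.5, patience = 25) {
  if (factor <= 0 || factor >= 1) .err("factor must be in (0,1)", "sinusplan_bad_config")
  if (patience < 1) .err("patience must be >= 1", "sinusplan_bad_config")
  lr <- initialLr; best <- Inf; wait <- 0L
  out <- numeric(length(valLosses))
  for (t in seq_along(valLosses)) {
    if (valLosses[t] < best) { best <- valLosses[t]; wait <- 0L }
    else {
      wait <- wait + 1L
      if (wait >= patience) { lr <- lr * factor; wait <- 0L }
    }
    out[t] <- lr
  }
  out
}
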