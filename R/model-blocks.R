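## Block-level forward and backward passes.  Each .xxxFwd returns
## list(y, cache, state); each .xxxBwd consumes (params, cache, dy) and
## returns list(dx, grads) with grads mirroring the parameter structure.

.bnMomentum <- 0.9

.bnFwd <- function(p, st, x, cfg, training) {
  out <- batchNormForward(x, p$gamma, p$beta, eps = cfg$bn_eps,
                          form = cfg$bn_form, training = training,
                          running = st)
  newSt <- st
  if (training) {
    newSt$mean <- .bnMomentum * st$mean + (1 - .bnMomentum) * out$batchMean
    newSt$sigma <- .bnMomentum * st$sigma + (1 - .bnMomentum) * out$batchSigma
  }
  list(y = out$y, cache = out$cache, state = newSt)
}

## ---- ECLF: entry conv -> BN -> ReLU -> multi-kernel branches -> concat
##      -> ReLU -> BN -> 2x2 max-pool ---------------------------------------

.eclfFwd <- function(p, st, x, cfg, training) {
  c1 <- convForward(x, p$entry$W, p$entry$b, 1L)
  bn1 <- .bnFwd(p$bn1, st$bn1, c1, cfg, training)
  r1 <- reluForward(bn1$y)
  y1 <- convForward(r1$y, p$b1$W, p$b1$b, 1L)
  y2 <- convForward(r1$y, p$b2$W, p$b2$b, 1L)
  y3 <- convForward(r1$y, p$b3$W, p$b3$b, 1L)
  cat3 <- .catChannels(list(y1, y2, y3))
  r2 <- reluForward(cat3)
  bn2 <- .bnFwd(p$bn2, st$bn2, r2$y, cfg, training)
  pl <- poolForward(bn2$y)
  list(y = pl$y,
       cache = list(x = x, c1 = c1, bn1 = bn1$cache, r1mask = r1$mask,
                    r1y = r1$y, r2mask = r2$mask, bn2 = bn2$cache,
                    bn2dim = dim(bn2$y), argmax = pl$argmax,
                    bsz = vapply(list(y1, y2, y3),
                                 function(a) dim(a)[3], integer(1))),
       state = list(bn1 = bn1$state, bn2 = bn2$state))
}

.eclfBwd <- function(p, cache, dy) {
  dpool <- poolBackward(dy, cache$argmax, cache$bn2dim)
  b2 <- batchNormBackward(dpool, cache$bn2)
  dcat <- reluBackward(b2$dx, cache$r2mask)
  parts <- .splitChannels(dcat, cache$bsz)
  g1 <- convBackward(cache$r1y, p$b1$W, parts[[1]], 1L)
  g2 <- convBackward(cache$r1y, p$b2$W, parts[[2]], 1L)
  g3 <- convBackward(cache$r1y, p$b3$W, parts[[3]], 1L)
  dr1 <- reluBackward(g1$dx + g2$dx + g3$dx, cache$r1mask)
  b1 <- batchNormBackward(dr1, cache$bn1)
  ge <- convBackward(cache$x, p$entry$W, b1$dx, 1L)
  list(dx = ge$dx,
       grads = list(
         entry = list(W = ge$dw, b = ge$db),
         bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
         b1 = list(W = g1$dw, b = g1$db),
         b2 = list(W = g2$dw, b = g2$db),
         b3 = list(W = g3$dw, b = g3$db),
         bn2 = list(gamma = b2$dgamma, beta = b2$dbeta)))
}

## ---- SCAN: spatial attention then channel attention ----------------------

.scanFwd <- function(p, x, cfg, training) {
  s2 <- convForward(x, p$sconv2$W, p$sconv2$b, 1L)
  s1 <- convForward(s2, p$sconv1$W, p$sconv1$b, 1L)
  A <- sigmoidStable(s1)                     # (H, W, 1, N), strictly (0,1)
  xs <- .mulSpatial(x, A)
  pooled <- globalAvgPool(xs)
  f1 <- denseForward(pooled, p$fc1$W, p$fc1$b)
  r <- reluForward(f1$y)
  f2 <- denseForward(r$y, p$fc2$W, p$fc2$b)
  Ac <- sigmoidStable(f2$y)                  # N x C, strictly (0,1)
  y <- .mulChannel(xs, Ac)
  list(y = y,
       cache = list(x = x, s2 = s2, A = A, xs = xs, f1 = f1,
                    rmask = r$mask, f2 = f2, Ac = Ac),
       state = NULL, A = A, Ac = Ac)
}

.scanBwd <- function(p, cache, dy) {
  dxs <- .mulChannel(dy, cache$Ac)
  dAc <- .sumToChannelMat(dy * cache$xs)
  df2 <- dAc * cache$Ac * (1 - cache$Ac)
  g2 <- denseBackward(df2, cache$f2, p$fc2$W)
  dr <- reluBackward(g2$dx, cache$rmask)
  g1 <- denseBackward(dr, cache$f1, p$fc1$W)
  dxs <- dxs + gapBackward(g1$dx, dim(cache$xs))
  dx <- .mulSpatial(dxs, cache$A)
  dA <- .sumSpatialChannels(dxs * cache$x)
  ds1 <- dA * cache$A * (1 - cache$A)
  c1 <- convBackward(cache$s2, p$sconv1$W, ds1, 1L)
  c2 <- convBackward(cache$x, p$sconv2$W, c1$dx, 1L)
  list(dx = dx + c2$dx,
       grads = list(
         sconv2 = list(W = c2$dw, b = c2$db),
         sconv1 = list(W = c1$dw, b = c1$db),
         fc1 = list(W = g1$dw, b = g1$db),
         fc2 = list(W = g2$dw, b = g2$db)))
}

## ---- HDCB: parallel dilated convs -> fuse -> BN -> ReLU -------------------

.hdcbFwd <- function(p, st, x, cfg, training) {
  rates <- cfg$dilation_rates
  ys <- lapply(seq_along(rates), function(i)
    convForward(x, p[[paste0("d", i)]]$W, p[[paste0("d", i)]]$b, rates[i]))
  if (cfg$hdcb_fusion == "concat") {
    cat3 <- .catChannels(ys)
    fused <- convForward(cat3, p$fuse$W, p$fuse$b, 1L)
    bn <- .bnFwd(p$bn, st$bn, fused, cfg, training)
  } else {
    fused <- Reduce(`+`, ys)
    cat3 <- NULL
    bn <- .bnFwd(p$bn, st$bn, fused, cfg, training)
  }
  r <- reluForward(bn$y)
  list(y = r$y,
       cache = list(x = x, cat3 = cat3, bn = bn$cache, rmask = r$mask,
                    bsz = vapply(ys, function(a) dim(a)[3], integer(1))),
       state = list(bn = bn$state))
}

.hdcbBwd <- function(p, cache, dy, cfg) {
  rates <- cfg$dilation_rates
  dbn <- reluBackward(dy, cache$rmask)
  b <- batchNormBackward(dbn, cache$bn)
  grads <- list()
  if (cfg$hdcb_fusion == "concat") {
    gf <- convBackward(cache$cat3, p$fuse$W, b$dx, 1L)
    parts <- .splitChannels(gf$dx, cache$bsz)
    grads$fuse <- list(W = gf$dw, b = gf$db)
  } else {
    parts <- rep(list(b$dx), length(rates))
  }
  dx <- NULL
  for (i in seq_along(rates)) {
    gi <- convBackward(cache$x, p[[paste0("d", i)]]$W, parts[[i]], rates[i])
    grads[[paste0("d", i)]] <- list(W = gi$dw, b = gi$db)
    dx <- if (is.null(dx)) gi$dx else dx + gi$dx
  }
  grads$bn <- list(gamma = b$dgamma, beta = b$dbeta)
  list(dx = dx, grads = grads)
}

## ---- RPCC: residual blocks X_k = X_{k-1} + F_k(X_{k-1}) -------------------
## F = Conv -> BN -> ReLU -> Conv; a 1x1 projection aligns the skip path
## when input channels differ from the block's filter count.

.rpccFwd <- function(p, st, x, cfg, training) {
  caches <- list(); states <- list()
  cur <- x
  for (bi in seq_len(cfg$residual_blocks)) {
    nm <- paste0("block", bi)
    blk <- p[[nm]]
    c1 <- convForward(cur, blk$conv1$W, blk$conv1$b, 1L)
    bn <- .bnFwd(blk$bn, st[[nm]]$bn, c1, cfg, training)
    r <- reluForward(bn$y)
    c2 <- convForward(r$y, blk$conv2$W, blk$conv2$b, 1L)
    skip <- if (!is.null(blk$proj))
      convForward(cur, blk$proj$W, blk$proj$b, 1L) else cur
    nxt <- skip + c2
    caches[[nm]] <- list(xin = cur, bn = bn$cache, rmask = r$mask,
                         ry = r$y, hasProj = !is.null(blk$proj))
    states[[nm]] <- list(bn = bn$state)
    cur <- nxt
  }
  list(y = cur, cache = caches, state = states)
}

.rpccBwd <- function(p, cache, dy, cfg) {
  grads <- list()
  for (bi in rev(seq_len(cfg$residual_blocks))) {
    nm <- paste0("block", bi)
    blk <- p[[nm]]; ch <- cache[[nm]]
    g2 <- convBackward(ch$ry, blk$conv2$W, dy, 1L)
    dr <- reluBackward(g2$dx, ch$rmask)
    b <- batchNormBackward(dr, ch$bn)
    g1 <- convBackward(ch$xin, blk$conv1$W, b$dx, 1L)
    gb <- list(conv1 = list(W = g1$dw, b = g1$db),
               bn = list(gamma = b$dgamma, beta = b$dbeta),
               conv2 = list(W = g2$dw, b = g2$db))
    if (ch$hasProj) {
      gp <- convBackward(ch$xin, blk$proj$W, dy, 1L)
      gb$proj <- list(W = gp$dw, b = gp$db)
      dy <- g1$dx + gp$dx
    } else {
      dy <- g1$dx + dy
    }
    grads[[nm]] <- gb
  }
  list(dx = dy, grads = grads)
}

## ---- head: GAP -> dense 512 -> ReLU -> dropout -> dense 256 -> ReLU
##      -> dropout -> dense 1 -> sigmoid ------------------------------------

.headFwd <- function(p, x, cfg, training) {
  pooled <- globalAvgPool(x)
  f1 <- denseForward(pooled, p$fc1$W, p$fc1$b)
  r1 <- reluForward(f1$y)
  d1 <- dropoutForward(r1$y, cfg$dropout, training)
  f2 <- denseForward(d1$y, p$fc2$W, p$fc2$b)
  r2 <- reluForward(f2$y)
  d2 <- dropoutForward(r2$y, cfg$dropout, training)
  fo <- denseForward(d2$y, p$out$W, p$out$b)
  z <- fo$y
  list(prob = sigmoidStable(z), z = z,
       cache = list(xdim = dim(x), f1 = f1, r1mask = r1$mask, d1mask = d1$mask,
                    f2 = f2, r2mask = r2$mask, d2mask = d2$mask, fo = fo))
}

.headBwd <- function(p, cache, dz) {
  go <- denseBackward(dz, cache$fo, p$out$W)
  dd2 <- dropoutBackward(go$dx, cache$d2mask)
  dr2 <- reluBackward(dd2, cache$r2mask)
  g2 <- denseBackward(dr2, cache$f2, p$fc2$W)
  dd1 <- dropoutBackward(g2$dx, cache$d1mask)
  dr1 <- reluBackward(dd1, cache$r1mask)
  g1 <- denseBackward(dr1, cache$f1, p$fc1$W)
  dx <- gapBackward(g1$dx, cache$xdim)
  list(dx = dx,
       grads = list(fc1 = list(W = g1$dw, b = g1$db),
                    fc2 = list(W = g2$dw, b = g2$db),
                    out = list(W = go$dw, b = go$db)))
}

## ---- full network --------------------------------------------------------

forwardPass <- function(model, x, training = FALSE) {
  cfg <- model$config; p <- model$params; st <- model$state
  caches <- list(); newState <- st
  cur <- x
  if (cfg$use_eclf) {
    e <- .eclfFwd(p$eclf, st$eclf, cur, cfg, training)
    cur <- e$y; caches$eclf <- e$cache; newState$eclf <- e$state
  }
  if (cfg$use_scan) {
    sc <- .scanFwd(p$scan, cur, cfg, training)
    cur <- sc$y; caches$scan <- sc$cache
    caches$attention <- list(spatial = sc$A, channel = sc$Ac)
  }
  if (cfg$use_hdcb) {
    h <- .hdcbFwd(p$hdcb, st$hdcb, cur, cfg, training)
    cur <- h$y; caches$hdcb <- h$cache; newState$hdcb <- h$state
  }
  if (cfg$use_rpcc) {
    r <- .rpccFwd(p$rpcc, st$rpcc, cur, cfg, training)
    cur <- r$y; caches$rpcc <- r$cache; newState$rpcc <- r$state
  }
  hd <- .headFwd(p$head, cur, cfg, training)
  caches$head <- hd$cache
  list(prob = as.numeric(hd$prob), z = hd$z, caches = caches,
       state = newState)
}

backwardPass <- function(model, caches, dz) {
  cfg <- model$config; p <- model$params
  grads <- list()
  hb <- .headBwd(p$head, caches$head, dz)
  grads$head <- hb$grads
  dcur <- hb$dx
  if (cfg$use_rpcc) {
    rb <- .rpccBwd(p$rpcc, caches$rpcc, dcur, cfg)
    grads$rpcc <- rb$grads; dcur <- rb$dx
  }
  if (cfg$use_hdcb) {
    hb2 <- .hdcbBwd(p$hdcb, caches$hdcb, dcur, cfg)
    grads$hdcb <- hb2$grads; dcur <- hb2$dx
  }
  if (cfg$use_scan) {
    sb <- .scanBwd(p$scan, caches$scan, dcur)
    grads$scan <- sb$grads; dcur <- sb$dx
  }
  if (cfg$use_eclf) {
    eb <- .eclfBwd(p$eclf, caches$eclf, dcur)
    grads$eclf <- eb$grads; dcur <- eb$dx
  }
  grads
}

#' Forward pass: per-sample sepsis probabilities
#'
#' Evaluation-mode forward through the whole network; deterministic for
#' fixed weights (dropout inactive, batch norm uses running statistics).
#'
#' @param model a `sepnetModel`.
#' @param x input tensor `(T, F, 1, N)` matching the model configuration.
#' @param batchSize samples per forward chunk (memory control).
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
predictProb <- function(model, x, batchSize = 512L) {
  x <- .as4d(x)
  d <- dim(x)
  cfg <- model$config
  if (d[1] != cfg$window || d[2] != cfg$features || d[3] != 1L)
    sepnetStop(sprintf(
      "input windows are %dx%dx%d but the model expects %dx%dx1",
      d[1], d[2], d[3], cfg$window, cfg$features), "sepnetShapeError")
  n <- d[4]
  out <- numeric(n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + batchSize - 1L, n)
    out[idx] <- forwardPass(model,
                            x[, , , idx, drop = FALSE],
                            training = FALSE)$prob
    at <- at + batchSize
  }
  out
}

## ---- exported block inspectors (evaluation mode) -------------------------

#' Run the multi-kernel entry block on a tensor
#'
#' @param model a `sepnetModel` built with `use_eclf = TRUE`.
#' @param x tensor `(T, F, 1, N)` (or 3-D for a single sample).
#' @return The pooled feature tensor `(T/2, F/2, 3 * branch_filters, N)`.
#' @export
eclfForward <- function(model, x) {
  .eclfFwd(model$params$eclf, model$state$eclf, .as4d(x), model$config,
           training = FALSE)$y
}

#' Spatial attention map and reweighted tensor
#'
#' Computes `A = sigmoid(Conv1(Conv2(X)))` — a 1x1 channel reduction to
#' `max(C/8, 1)` channels followed by a 7x7 convolution to a single channel
#' — and the spatially reweighted tensor `X * A` (broadcast over channels).
#'
#' @param model a `sepnetModel` with `use_scan = TRUE`.
#' @param x tensor whose channel count matches the attention block.
#' @return List with `attention` (`(H, W, 1, N)`, all values strictly in
#'   (0, 1)) and `output`.
#' @export
spatialAttention <- function(model, x) {
  x <- .as4d(x)
  p <- model$params$scan
  s2 <- convForward(x, p$sconv2$W, p$sconv2$b, 1L)
  A <- sigmoidStable(convForward(s2, p$sconv1$W, p$sconv1$b, 1L))
  list(attention = A, output = .mulSpatial(x, A))
}

#' Channel attention weights and reweighted tensor
#'
#' Global average pooling per channel, a two-layer bottleneck
#' (`C -> 64 -> C`) with ReLU then sigmoid, and channel-wise reweighting.
#'
#' @inheritParams spatialAttention
#' @return List with `pooled` (`N x C` channel descriptors), `attention`
#'   (`N x C`, strictly in (0, 1)) and `output`.
#' @export
channelAttention <- function(model, x) {
  x <- .as4d(x)
  p <- model$params$scan
  pooled <- globalAvgPool(x)
  h <- reluForward(denseForward(pooled, p$fc1$W, p$fc1$b)$y)$y
  Ac <- sigmoidStable(denseForward(h, p$fc2$W, p$fc2$b)$y)
  list(pooled = pooled, attention = Ac, output = .mulChannel(x, Ac))
}

#' Sequential spatio-channel attention
#'
#' Applies spatial then channel attention:
#' `X_final = (X * A_spatial) * A_channel`.  Equals composing
#' [spatialAttention()] and [channelAttention()] with the same weights.
#'
#' @inheritParams spatialAttention
#' @return List with `output`, `spatial` and `channel` attention maps.
#' @export
scanForward <- function(model, x) {
  sc <- .scanFwd(model$params$scan, .as4d(x), model$config, training = FALSE)
  list(output = sc$y, spatial = sc$A, channel = sc$Ac)
}

#' Run the hierarchically dilated block on a tensor
#'
#' Three parallel shape-preserving 3x3 convolutions at dilation rates 1, 2,
#' 3, fused by concatenation and a 1x1 convolution (or by summation), then
#' batch norm and ReLU.
#'
#' @inheritParams spatialAttention
#' @return The fused feature tensor (128 channels under the default
#'   concatenation fusion).
#' @export
hdcbForward <- function(model, x) {
  .hdcbFwd(model$params$hdcb, model$state$hdcb, .as4d(x), model$config,
           training = FALSE)$y
}

#' Run the residual convolutional chain on a tensor
#'
#' `X_k = X_{k-1} + F_k(X_{k-1})` with `F = Conv -> BN -> ReLU -> Conv`;
#' a 1x1 projection aligns the skip path when the input channel count
#' differs from the block filters.
#'
#' @inheritParams spatialAttention
#' @param fns optional list of residual-function stubs, one per block; each
#'   takes and returns a tensor.  When supplied the chain is evaluated with
#'   the stubs in place of the convolutional residual functions (no
#'   projection), which exposes the bare recursion for verification.
#' @return The output tensor of the chain.
#' @export
rpccForward <- function(model, x, fns = NULL) {
  x <- .as4d(x)
  if (!is.null(fns)) {
    cur <- x
    for (f in fns) cur <- cur + f(cur)
    return(cur)
  }
  .rpccFwd(model$params$rpcc, model$state$rpcc, x, model$config,
           training = FALSE)$y
}

#' Save / load model checkpoints
#'
#' Serializes the configuration, weights and batch-norm running statistics.
#'
#' @param model a `sepnetModel`.
#' @param path checkpoint file.
#' @return `path` (write) or the restored `sepnetModel` (read).
#' @export
writeModelCheckpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname writeModelCheckpoint
#' @export
readModelCheckpoint <- function(path) {
  m <- readRDS(path)
  m$config <- structure(m$config, class = "modelConfig")
  structure(m, class = "sepnetModel")
}

#' Export attention maps of a batch as CSV grids
#'
#' @param model a `sepnetModel` with the attention block enabled.
#' @param x input tensor.
#' @param dir output directory; writes `spatial_attention.csv` (one row per
#'   sample, flattened H x W grid) and `channel_attention.csv`.
#' @return The two file paths, invisibly.
#' @export
exportAttentionMaps <- function(model, x, dir = ".") {
  fw <- forwardPass(model, .as4d(x), training = FALSE)
  att <- fw$caches$attention
  if (is.null(att))
    sepnetStop("model has no attention block (use_scan = FALSE)",
               "sepnetConfigError")
  d <- dim(att$spatial)
  spm <- t(matrix(att$spatial, d[1] * d[2], d[4]))  # one row per sample
  f1 <- file.path(dir, "spatial_attention.csv")
  f2 <- file.path(dir, "channel_attention.csv")
  utils::write.table(spm, f1, sep = ",", row.names = FALSE,
                     col.names = paste0("p", seq_len(ncol(spm))))
  utils::write.table(att$channel, f2, sep = ",", row.names = FALSE,
                     col.names = paste0("ch", seq_len(ncol(att$channel))))
  invisible(c(f1, f2))
}
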