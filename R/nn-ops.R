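## Differentiable tensor operations.  Tensors are numeric arrays with dim
## (H, W, C, N); convolution weights have dim (kh, kw, Cin, Cout).  Each
## forward returns what its backward needs; backward passes are derived by
## hand and verified against finite differences in the test suite.

.as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("tensor input must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("tensor must have 2-4 dimensions")
  x
}

#' Dilated (atrous) convolution
#'
#' Shape-preserving zero-padded convolution whose kernel taps are spaced by
#' the dilation rate `d`: output position (i, j) accumulates
#' `X[i + m d, j + n d] * W[m, n]` over kernel offsets (m, n) centred on
#' the tap.  With a 3-D kernel `(kh, kw, C)` the operator acts per channel
#' (one kernel slice per input channel, channel count preserved); with a
#' 4-D kernel `(kh, kw, Cin, Cout)` it is the standard multi-channel
#' convolution summing over input channels.
#'
#' @param x input tensor, dim `(H, W, C)` or `(H, W, C, N)`.
#' @param w kernel array, 3-D (per-channel) or 4-D (channel-mixing); odd
#'   spatial extents.
#' @param dilation integer dilation rate >= 1.
#' @param bias optional per-output-channel bias (4-D kernels only).
#' @return Tensor of the same spatial size; channels follow the kernel.
#' @export
dilatedConv <- function(x, w, dilation = 1L, bias = NULL) {
  stopifnot(dilation >= 1)
  x4 <- .as4d(x)
  dw <- dim(w)
  if (length(dw) == 3L) {
    H <- dim(x4)[1]; W <- dim(x4)[2]; C <- dim(x4)[3]; N <- dim(x4)[4]
    stopifnot(dw[3] == C, dw[1] %% 2 == 1, dw[2] %% 2 == 1)
    if ((dw[1] - 1) %/% 2 * dilation >= H + dw[1] ||
        (dw[2] - 1) %/% 2 * dilation >= W + dw[2])
      sepnetStop("kernel larger than padded input", "sepnetShapeError")
    y <- array(0, dim(x4))
    rh <- (dw[1] - 1) / 2; rw <- (dw[2] - 1) / 2
    for (m in seq_len(dw[1])) for (n in seq_len(dw[2])) {
      di <- (m - 1 - rh) * dilation; dj <- (n - 1 - rw) * dilation
      si <- seq_len(H) + di; sj <- seq_len(W) + dj
      vi <- si >= 1 & si <= H; vj <- sj >= 1 & sj <= W
      if (!any(vi) || !any(vj)) next
      for (c in seq_len(C))
        y[vi, vj, c, ] <- y[vi, vj, c, , drop = FALSE] +
          x4[si[vi], sj[vj], c, , drop = FALSE] * w[m, n, c]
    }
    if (length(dim(x)) < 4L) dim(y) <- dim(x)
    y
  } else if (length(dw) == 4L) {
    if (is.null(bias)) bias <- numeric(dw[4])
    y <- .conv2dFwd(x4, dim(x4), w, dw, bias, as.integer(dilation))
    if (length(dim(x)) == 3L) dim(y) <- dim(y)[1:3]
    y
  } else stop("kernel must be a 3-D or 4-D array")
}

convForward <- function(x, w, b, dilation = 1L) {
  .conv2dFwd(x, dim(x), w, dim(w), b, as.integer(dilation))
}

convBackward <- function(x, w, dy, dilation = 1L) {
  .conv2dBwd(x, dim(x), w, dim(w), dy, as.integer(dilation))
}

poolForward <- function(x) .maxpool2Fwd(x, dim(x))
poolBackward <- function(dy, argmax, xdim) .maxpool2Bwd(dy, argmax, xdim)

reluForward <- function(x) {
  y <- .reluFwd(x)
  list(y = y, mask = y)        # y itself encodes the active set (y > 0)
}
reluBackward <- function(dy, mask) .reluBwd(dy, mask)

sigmoidStable <- function(z) 1 / (1 + exp(-z))

## ---- batch normalization -------------------------------------------------
## Per-channel statistics over all spatial positions and samples.  The
## default normalizer divides by (sigma + eps) where sigma is the population
## standard deviation; form = "variance" uses the conventional
## sqrt(variance + eps).  Heavy lifting happens in C++ (.bnFwdC/.bnBwdC).

#' Batch normalization
#'
#' Normalizes each channel by its batch mean and standard deviation,
#' `xhat = (x - mu_B) / (sigma_B + eps)`, then rescales with learnable
#' `gamma` and `beta`.  `form = "variance"` switches the denominator to the
#' conventional `sqrt(sigma_B^2 + eps)`.  In inference mode the running
#' statistics are used instead of batch statistics.
#'
#' @param x tensor `(H, W, C, N)`.
#' @param gamma,beta per-channel scale and shift.
#' @param eps stabilizer, default 1e-5.
#' @param form `"paper"` (`sigma + eps` denominator) or `"variance"`.
#' @param training use batch statistics (`TRUE`) or running ones.
#' @param running list with `mean` and `sigma` per channel (inference).
#' @return List with `y` and a `cache` for [batchNormBackward()]; in
#'   training mode also `batchMean`/`batchSigma`.
#' @export
batchNormForward <- function(x, gamma, beta, eps = 1e-5,
                             form = c("paper", "variance"),
                             training = TRUE, running = NULL) {
  form <- match.arg(form)
  x <- .as4d(x)
  d <- dim(x)
  out <- .bnFwdC(x, d, gamma, beta, eps,
                 if (form == "paper") 0L else 1L, training,
                 if (is.null(running)) numeric(d[3]) else running$mean,
                 if (is.null(running)) rep(1, d[3]) else running$sigma)
  list(y = out$y,
       cache = list(xhat = out$xhat, s = out$s, sig = out$sigma,
                    gamma = gamma, d = d, form = form, training = training),
       batchMean = out$mu, batchSigma = out$sigma)
}

#' @describeIn batchNormForward Backward pass; returns `dx`, `dgamma`,
#'   `dbeta`.
#' @param dy upstream gradient tensor.
#' @param cache cache from the forward pass.
#' @export
batchNormBackward <- function(dy, cache) {
  out <- .bnBwdC(.as4d(dy), cache$xhat, cache$d, cache$gamma, cache$sig,
                 cache$s, if (cache$form == "paper") 0L else 1L,
                 cache$training)
  list(dx = out$dx, dgamma = out$dgamma, dbeta = out$dbeta)
}

## ---- dense layers --------------------------------------------------------

denseForward <- function(x, w, b) {        # x: N x in, w: in x out
  list(y = sweep(x %*% w, 2, b, "+"), x = x)
}
denseBackward <- function(dy, cache, w) {
  list(dx = dy %*% t(w), dw = t(cache$x) %*% dy, db = colSums(dy))
}

## ---- global average pooling ----------------------------------------------

#' Global average pooling
#'
#' Averages each channel over all spatial positions:
#' `xhat_k = mean_{i,j} X[i, j, k]`.
#'
#' @param x tensor `(H, W, C, N)`.
#' @return Matrix `N x C` of pooled channel descriptors.
#' @export
globalAvgPool <- function(x) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
  t(matrix(colMeans(m), d[3], d[4]))       # N x C
}

gapBackward <- function(dy, d) {           # dy: N x C
  ## spread each (c, n) gradient evenly over its H*W block; t(dy) vectorizes
  ## in (c, n) order, matching the (H, W, C, N) column-major layout
  array(rep(as.vector(t(dy)) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

## ---- dropout -------------------------------------------------------------

dropoutForward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(y = x * mask, mask = mask)
}
dropoutBackward <- function(dy, mask) if (is.null(mask)) dy else dy * mask
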