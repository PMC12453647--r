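## Shared fixtures and independent oracles for the test suite.

## Brute-force nested-sum dilated convolution (channel-mixing, 4-D kernel):
## the independent oracle the fast im2col path is checked against.
bruteConv4 <- function(x, w, b, d) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  rh <- (kh - 1) / 2; rw <- (kw - 1) / 2
  y <- array(0, c(H, W, Co, N))
  for (n in 1:N) for (i in 1:H) for (j in 1:W) for (o in 1:Co) {
    s <- b[o]
    for (m in 1:kh) for (mm in 1:kw) for (c in 1:C) {
      si <- i + (m - 1 - rh) * d; sj <- j + (mm - 1 - rw) * d
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        s <- s + x[si, sj, c, n] * w[m, mm, c, o]
    }
    y[i, j, o, n] <- s
  }
  y
}

## Per-channel (depthwise) brute-force variant for 3-D kernels.
bruteConv3 <- function(x, w, d) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]
  rh <- (kh - 1) / 2; rw <- (kw - 1) / 2
  y <- array(0, dim(x))
  for (i in 1:H) for (j in 1:W) for (c in 1:C) {
    s <- 0
    for (m in 1:kh) for (mm in 1:kw) {
      si <- i + (m - 1 - rh) * d; sj <- j + (mm - 1 - rw) * d
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        s <- s + x[si, sj, c] * w[m, mm, c]
    }
    y[i, j, c] <- s
  }
  y
}

## Exhaustive O(n^2) pairwise AUC oracle: P(score_pos > score_neg) + ties/2.
pairwiseAuc <- function(prob, labels) {
  pos <- prob[labels == 1]; neg <- prob[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## Two-vital schema and a hand-built cohort writer for IO tests.
tinySchema <- function() {
  featureSchema(c("HR", "Temp", "Gender"),
                c("vital", "vital", "demographic"),
                categoryLevels = list(Gender = c("Male", "Female", "Other")))
}

writeTinyCsv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

## A small but fully wired model configuration for fast tests.
tinyModelConfig <- function(...) {
  args <- utils::modifyList(
    list(features = 5, window = 6, entry_filters = 4, branch_filters = 3,
         hdcb_filters = 3, fuse_filters = 6, rpcc_filters = 6,
         residual_blocks = 2, dense_units = c(12, 6),
         channel_bottleneck = 4, dropout = 0),
    list(...))
  do.call(modelConfig, args)
}

randomTensor <- function(H, W, C = 1, N = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(H * W * C * N), c(H, W, C, N))
}
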