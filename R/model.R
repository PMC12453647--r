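## The convolutional sepsis classifier.
##
## Pipeline: tensorized T x F x 1 windows -> multi-kernel entry block
## (ECLF) -> sequential spatial/channel attention (SCAN) -> hierarchically
## dilated block (HDCB) -> residual chain (RPCC) -> global average pooling
## -> dense head -> sigmoid probability.  Every block can be bypassed for
## ablation; channel bookkeeping is resolved once at build time.

#' Model architecture configuration
#'
#' All architectural hyperparameters of the classifier with their default
#' values: a 64-filter 3x3 entry convolution feeding three parallel branches
#' with kernel sizes 3/5/7 and a single 2x2 max-pool; a 7x7 spatial-attention
#' convolution (after a 1x1 channel reduction to `max(C/8, 1)`) and a
#' 64-unit channel-attention bottleneck; three 3x3/64-filter dilated
#' convolutions at rates 1, 2, 3 fused by concatenation and a 1x1
#' convolution with 128 filters; two residual blocks of paired 3x3/128
#' convolutions; and a 512/256 dense head with 0.5 dropout and a single
#' sigmoid output.
#'
#' @param features number of input feature columns F (after preprocessing).
#' @param window window length T in hours (>= 2), default 8.
#' @param kernel_sizes entry-branch kernel sizes, default `c(3, 5, 7)`.
#' @param entry_filters,branch_filters entry/branch filter counts, default 64.
#' @param spatial_kernel spatial-attention kernel size, default 7.
#' @param channel_bottleneck channel-attention hidden units, default 64.
#' @param hdcb_filters filters per dilated branch, default 64.
#' @param dilation_rates dilation rates of the dilated block, default 1:3.
#' @param hdcb_fusion `"concat"` (then a 1x1 convolution with
#'   `fuse_filters`) or `"sum"`.
#' @param fuse_filters 1x1 fusion filters, default 128.
#' @param residual_blocks number of residual blocks N, default 2.
#' @param rpcc_filters filters of the residual convolutions, default 128.
#' @param dense_units dense head widths, default `c(512, 256)`.
#' @param dropout head dropout rate in [0, 1), default 0.5.
#' @param bn_form batch-norm denominator: `"paper"` (`sigma + eps`) or
#'   `"variance"` (`sqrt(var + eps)`).
#' @param bn_eps batch-norm stabilizer, default 1e-5.
#' @param use_eclf,use_scan,use_hdcb,use_rpcc block toggles for ablation
#'   (identity bypass; channel adapters are part of the downstream blocks).
#' @return A list of class `modelConfig`.
#' @export
modelConfig <- function(features, window = 8L, kernel_sizes = c(3L, 5L, 7L),
                        entry_filters = 64L, branch_filters = 64L,
                        spatial_kernel = 7L, channel_bottleneck = 64L,
                        hdcb_filters = 64L, dilation_rates = c(1L, 2L, 3L),
                        hdcb_fusion = c("concat", "sum"),
                        fuse_filters = 128L, residual_blocks = 2L,
                        rpcc_filters = 128L, dense_units = c(512L, 256L),
                        dropout = 0.5, bn_form = c("paper", "variance"),
                        bn_eps = 1e-5,
                        use_eclf = TRUE, use_scan = TRUE,
                        use_hdcb = TRUE, use_rpcc = TRUE) {
  cfg <- list(features = as.integer(features), window = as.integer(window),
              kernel_sizes = as.integer(kernel_sizes),
              entry_filters = as.integer(entry_filters),
              branch_filters = as.integer(branch_filters),
              spatial_kernel = as.integer(spatial_kernel),
              channel_bottleneck = as.integer(channel_bottleneck),
              hdcb_filters = as.integer(hdcb_filters),
              dilation_rates = as.integer(dilation_rates),
              hdcb_fusion = match.arg(hdcb_fusion),
              fuse_filters = as.integer(fuse_filters),
              residual_blocks = as.integer(residual_blocks),
              rpcc_filters = as.integer(rpcc_filters),
              dense_units = as.integer(dense_units),
              dropout = dropout, bn_form = match.arg(bn_form),
              bn_eps = bn_eps,
              use_eclf = isTRUE(use_eclf), use_scan = isTRUE(use_scan),
              use_hdcb = isTRUE(use_hdcb), use_rpcc = isTRUE(use_rpcc))
  if (cfg$window < 2L)
    sepnetStop("window must be >= 2 (pooling needs spatial extent)",
               "sepnetConfigError")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    sepnetStop("dropout must be in [0, 1)", "sepnetConfigError")
  if (any(c(cfg$features, cfg$entry_filters, cfg$branch_filters,
            cfg$hdcb_filters, cfg$fuse_filters, cfg$residual_blocks,
            cfg$rpcc_filters, cfg$dense_units, cfg$channel_bottleneck) < 1L))
    sepnetStop("all layer sizes must be >= 1", "sepnetConfigError")
  if (any(cfg$dilation_rates < 1L))
    sepnetStop("dilation rates must be >= 1", "sepnetConfigError")
  if (any(cfg$kernel_sizes %% 2L == 0L) || cfg$spatial_kernel %% 2L == 0L)
    sepnetStop("kernels must be odd-sized for shape-preserving padding",
               "sepnetConfigError")
  structure(cfg, class = "modelConfig")
}

.heConv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}
.heDense <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}
.bnInit <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
.bnState <- function(c) list(mean = rep(0, c), sigma = rep(1, c))

## Channel/spatial geometry implied by a config (used by build, the
## parameter-count oracle tests, and ablation accounting).
.geometry <- function(cfg) {
  H <- cfg$window; W <- cfg$features; C <- 1L
  if (cfg$use_eclf) {
    C <- 3L * cfg$branch_filters
    H <- H %/% 2L; W <- W %/% 2L
  }
  cScan <- C
  if (cfg$use_hdcb)
    C <- if (cfg$hdcb_fusion == "concat") cfg$fuse_filters else cfg$hdcb_filters
  cHdcbIn <- cScan
  cRpccIn <- C
  if (cfg$use_rpcc) C <- cfg$rpcc_filters
  list(H = H, W = W, cScan = cScan, cHdcbIn = cHdcbIn, cRpccIn = cRpccIn,
       cHead = C)
}

#' Build the classifier with freshly initialized weights
#'
#' Weights use fan-in-scaled (He) gaussian initialization from the given
#' seed; biases start at zero, batch-norm scales at one.
#'
#' @param config a [modelConfig()].
#' @param seed integer RNG seed for the initialization.
#' @return A list of class `sepnetModel` with elements `config`, `params`
#'   (nested weight arrays) and `state` (batch-norm running statistics).
#' @export
buildModel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "modelConfig"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  g <- .geometry(config)
  p <- list(); s <- list()

  if (config$use_eclf) {
    ef <- config$entry_filters; bf <- config$branch_filters
    k <- config$kernel_sizes
    p$eclf <- list(
      entry = list(W = .heConv(3, 3, 1, ef), b = rep(0, ef)),
      bn1 = .bnInit(ef),
      b1 = list(W = .heConv(k[1], k[1], ef, bf), b = rep(0, bf)),
      b2 = list(W = .heConv(k[2], k[2], ef, bf), b = rep(0, bf)),
      b3 = list(W = .heConv(k[3], k[3], ef, bf), b = rep(0, bf)),
      bn2 = .bnInit(3 * bf))
    s$eclf <- list(bn1 = .bnState(ef), bn2 = .bnState(3 * bf))
  }
  if (config$use_scan) {
    C <- g$cScan; Cr <- max(C %/% 8L, 1L); sk <- config$spatial_kernel
    cb <- config$channel_bottleneck
    p$scan <- list(
      sconv2 = list(W = .heConv(1, 1, C, Cr), b = rep(0, Cr)),
      sconv1 = list(W = .heConv(sk, sk, Cr, 1), b = rep(0, 1)),
      fc1 = list(W = .heDense(C, cb), b = rep(0, cb)),
      fc2 = list(W = .heDense(cb, C), b = rep(0, C)))
  }
  if (config$use_hdcb) {
    Ci <- g$cHdcbIn; hf <- config$hdcb_filters
    p$hdcb <- list()
    for (i in seq_along(config$dilation_rates))
      p$hdcb[[paste0("d", i)]] <-
        list(W = .heConv(3, 3, Ci, hf), b = rep(0, hf))
    if (config$hdcb_fusion == "concat") {
      nb <- length(config$dilation_rates)
      p$hdcb$fuse <- list(W = .heConv(1, 1, nb * hf, config$fuse_filters),
                          b = rep(0, config$fuse_filters))
      p$hdcb$bn <- .bnInit(config$fuse_filters)
      s$hdcb <- list(bn = .bnState(config$fuse_filters))
    } else {
      p$hdcb$bn <- .bnInit(hf)
      s$hdcb <- list(bn = .bnState(hf))
    }
  }
  if (config$use_rpcc) {
    Ci <- g$cRpccIn; rf <- config$rpcc_filters
    p$rpcc <- list(); s$rpcc <- list()
    for (bi in seq_len(config$residual_blocks)) {
      blk <- list(conv1 = list(W = .heConv(3, 3, Ci, rf), b = rep(0, rf)),
                  bn = .bnInit(rf),
                  conv2 = list(W = .heConv(3, 3, rf, rf), b = rep(0, rf)))
      if (Ci != rf)
        blk$proj <- list(W = .heConv(1, 1, Ci, rf), b = rep(0, rf))
      p$rpcc[[paste0("block", bi)]] <- blk
      s$rpcc[[paste0("block", bi)]] <- list(bn = .bnState(rf))
      Ci <- rf
    }
  }
  du <- config$dense_units
  p$head <- list(
    fc1 = list(W = .heDense(g$cHead, du[1]), b = rep(0, du[1])),
    fc2 = list(W = .heDense(du[1], du[2]), b = rep(0, du[2])),
    out = list(W = .heDense(du[2], 1), b = 0))
  structure(list(config = config, params = p, state = s),
            class = "sepnetModel")
}

#' Count trainable parameters
#'
#' @param model a `sepnetModel`.
#' @return Integer: total number of trainable scalars (convolution and dense
#'   weights and biases, batch-norm scales and shifts).
#' @export
countParameters <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.numeric(x)) n <<- n + length(x)
    else if (is.list(x)) for (e in x) walk(e)
  }
  walk(model$params)
  n
}

#' Slide per-patient windows into model input tensors
#'
#' For every patient-timestep of a preprocessed cohort, takes the T most
#' recent hourly rows ending at that timestep (zero-padded at the top for
#' early timesteps) and stacks them into a `(T, F, 1, N)` tensor.  The label
#' of a window is the sepsis label at its final hour; patient provenance is
#' retained so splits stay patient-wise.
#'
#' @param cohort a preprocessed (fully observed) [SepsisCohort-class].
#' @param window window length T >= 2.
#' @return List with `x` (tensor `(T, F, 1, N)`), `y` (0/1 labels),
#'   `patient` (per-window patient ids) and `time` (window end hours).
#' @export
tensorizeWindows <- function(cohort, window = 8L) {
  window <- as.integer(window)
  if (window < 2L)
    sepnetStop("window must be >= 2 (pooling needs spatial extent)",
               "sepnetConfigError")
  vals <- cohortValues(cohort)
  if (anyNA(vals))
    sepnetStop("cohort must be preprocessed (no missing values) before tensorization",
               "sepnetValidationError")
  pid <- patientOf(cohort); lab <- sepsisLabels(cohort)
  nf <- nrow(vals); n <- ncol(vals)
  x <- array(0, c(window, nf, 1L, n))
  blocks <- split(seq_len(n), factor(pid, levels = unique(pid)))
  for (b in blocks) {
    m <- rbind(matrix(0, window - 1L, nf), t(vals[, b, drop = FALSE]))
    for (k in seq_along(b)) {
      x[, , 1L, b[k]] <- m[k:(k + window - 1L), , drop = FALSE]
    }
  }
  list(x = x, y = lab, patient = pid, time = timeIndex(cohort))
}

## ---- channel helpers -----------------------------------------------------

.catChannels <- function(lst) {
  d <- dim(lst[[1]])
  cs <- vapply(lst, function(a) dim(a)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (a in lst) {
    k <- dim(a)[3]
    out[, , at + seq_len(k), ] <- a
    at <- at + k
  }
  out
}
.splitChannels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(k) {
    sl <- x[, , at + seq_len(k), , drop = FALSE]
    at <<- at + k
    sl
  })
}
.mulSpatial <- function(x, a) {        # a: (H, W, 1, N) broadcast over C
  x * a[, , rep(1L, dim(x)[3]), , drop = FALSE]
}
.mulChannel <- function(x, ac) {       # ac: N x C broadcast over (H, W)
  d <- dim(x)
  x * array(rep(as.vector(t(ac)), each = d[1] * d[2]), d)
}
.sumSpatialChannels <- function(x) {   # -> (H, W, 1, N), sum over C
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3], d[4])
  r <- vapply(seq_len(d[4]),
              function(n) rowSums(m[, , n, drop = FALSE], dims = 1),
              numeric(d[1] * d[2]))
  array(r, c(d[1], d[2], 1L, d[4]))
}
.sumToChannelMat <- function(x) {      # -> N x C, sum over (H, W)
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3] * d[4])
  t(matrix(colSums(m), d[3], d[4]))
}
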