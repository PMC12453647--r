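test_that("dilated convolution equals the brute-force nested sum", {
  set.seed(101)
  for (rep in 1:6) {
    H <- sample(4:8, 1); W <- sample(4:8, 1); C <- sample(1:3, 1)
    x <- randomTensor(H, W, C)
    for (d in 1:3) {
      ## channel-mixing 4-D kernel
      Co <- sample(1:4, 1)
      w4 <- array(rnorm(9 * C * Co), c(3, 3, C, Co))
      got <- dilatedConv(x, w4, d)
      expect_lt(max(abs(got - bruteConv4(x, w4, numeric(Co), d))), 1e-6)
      ## per-channel 3-D kernel
      w3 <- array(rnorm(9 * C), c(3, 3, C))
      got3 <- dilatedConv(drop3 <- array(x, c(H, W, C)), w3, d)
      expect_lt(max(abs(got3 - bruteConv3(drop3, w3, d))), 1e-6)
    }
  }
})

test_that("identity kernel and impulse probes behave per the definition", {
  set.seed(7)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  wId <- array(0, c(3, 3, 2))
  wId[2, 2, ] <- 1
  expect_equal(dilatedConv(x, wId, 1), x, tolerance = 1e-12)
  ## impulse through a dilated all-ones kernel: taps spaced d apart
  imp <- array(0, c(7, 7, 1)); imp[4, 4, 1] <- 1
  w1 <- array(1, c(3, 3, 1))
  y <- dilatedConv(imp, w1, 2)
  nz <- which(y[, , 1] != 0, arr.ind = TRUE)
  expect_setequal(nz[, 1], c(2, 4, 6))
  expect_setequal(nz[, 2], c(2, 4, 6))
})

test_that("batch normalization follows the printed form and its toggle", {
  set.seed(11)
  ## batch already zero-mean unit-sd, gamma 1, beta 0: output = input/(1+eps)
  v <- rnorm(400)
  v <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  x <- array(v, c(10, 10, 1, 4))
  out <- batchNormForward(x, gamma = 1, beta = 0, eps = 1e-5, form = "paper")
  expect_equal(out$y, x / (1 + 1e-5), tolerance = 1e-9)
  ## gamma 0: constant beta
  out2 <- batchNormForward(x, gamma = 0, beta = 2.5)
  expect_true(all(out2$y == 2.5))
  ## both denominator forms agree closely when sigma >> eps
  x3 <- array(rnorm(800, 0, 4), c(10, 10, 2, 4))
  yP <- batchNormForward(x3, c(1, 1), c(0, 0), form = "paper")$y
  yV <- batchNormForward(x3, c(1, 1), c(0, 0), form = "variance")$y
  expect_lt(max(abs(yP - yV)), 1e-3)
})

test_that("window tensorization pads, aligns and conserves sample count", {
  sch <- featureSchema(c("a", "b"), "vital")
  ## numbered fixture: value = timestep index
  vals <- rbind(a = 1:5, b = 101:105)
  co <- sepsisCohort(vals, matrix(TRUE, 2, 5), rep("P", 5), 1:5,
                     c(0L, 0L, 1L, 1L, 1L), sch)
  tw <- tensorizeWindows(co, window = 4)
  expect_equal(dim(tw$x), c(4, 2, 1, 5))
  expect_equal(tw$y, c(0L, 0L, 1L, 1L, 1L))
  ## first window: 3 zero rows then row 1
  expect_equal(tw$x[, 1, 1, 1], c(0, 0, 0, 1))
  ## window at t = 5 holds rows 2..5
  expect_equal(tw$x[, 1, 1, 5], 2:5)
  expect_equal(tw$x[, 2, 1, 5], 102:105)
  ## total sample count equals total timestep count
  co2 <- simulateCohort(simConfig(nPatients = 6, seed = 13))
  t2 <- tensorizeWindows(transformCohort(co2, fitPreprocessor(co2)), 8)
  expect_equal(dim(t2$x)[4], ncol(co2))
  expect_error(tensorizeWindows(co, window = 1), class = "sepnetConfigError")
})

test_that("the entry block produces the documented geometry", {
  mc <- modelConfig(features = 44)
  m <- buildModel(mc, seed = 1)
  x <- randomTensor(8, 44, 1, 2, seed = 3)
  y <- eclfForward(m, x)
  expect_equal(dim(y), c(4, 22, 192, 2))
  ## all-zero input with zero biases stays zero through conv/BN/ReLU/pool
  y0 <- eclfForward(m, array(0, c(8, 44, 1, 2)))
  expect_true(all(y0 == 0))
})

test_that("branch concatenation order is K1, K2, K3", {
  mc <- tinyModelConfig(kernel_sizes = c(3L, 3L, 3L))
  m <- buildModel(mc, seed = 5)
  x <- randomTensor(6, 5, 1, 2, seed = 6)
  y1 <- eclfForward(m, x)
  ## swapping branch weights permutes the corresponding channel blocks
  m2 <- m
  m2$params$eclf$b1 <- m$params$eclf$b2
  m2$params$eclf$b2 <- m$params$eclf$b1
  y2 <- eclfForward(m2, x)
  bf <- mc$branch_filters
  expect_equal(y2[, , seq_len(bf), ], y1[, , bf + seq_len(bf), ])
  expect_equal(y2[, , bf + seq_len(bf), ], y1[, , seq_len(bf), ])
  expect_equal(y2[, , 2 * bf + seq_len(bf), ], y1[, , 2 * bf + seq_len(bf), ])
})

test_that("attention maps stay strictly inside (0, 1) and broadcast correctly", {
  mc <- tinyModelConfig()
  m <- buildModel(mc, seed = 2)
  C <- 3 * mc$branch_filters
  x <- randomTensor(3, 2, C, 4, seed = 9)
  sa <- spatialAttention(m, x)
  expect_true(all(sa$attention > 0 & sa$attention < 1))
  ## ratio output/input is constant across channels at each position
  r <- sa$output / x
  expect_lt(max(abs(sweep(r, c(1, 2, 4), r[, , 1, ]))), 1e-9)
  ca <- channelAttention(m, x)
  expect_true(all(ca$attention > 0 & ca$attention < 1))
  expect_equal(dim(ca$attention), c(4, C))
})

test_that("zeroed spatial-attention weights give the closed-form map", {
  mc <- tinyModelConfig()
  m <- buildModel(mc, seed = 4)
  b0 <- 0.7
  m$params$scan$sconv1$W[] <- 0
  m$params$scan$sconv1$b <- b0
  m$params$scan$sconv2$W[] <- 0
  C <- 3 * mc$branch_filters
  x <- randomTensor(3, 2, C, 2, seed = 10)
  sa <- spatialAttention(m, x)
  expect_equal(as.numeric(sa$attention),
               rep(1 / (1 + exp(-b0)), length(sa$attention)),
               tolerance = 1e-12)
  expect_equal(sa$output, x / (1 + exp(-b0)), tolerance = 1e-12)
})

test_that("pooled channel descriptors equal the brute-force mean", {
  mc <- tinyModelConfig()
  m <- buildModel(mc, seed = 2)
  x <- randomTensor(4, 4, 8, 3, seed = 12)
  ## constant channel pools to the constant exactly
  x[, , 2, 1] <- 3.25
  g <- globalAvgPool(x)
  expect_identical(g[1, 2], 3.25)
  oracle <- matrix(0, 3, 8)
  for (n in 1:3) for (c in 1:8) {
    s <- 0
    for (i in 1:4) for (j in 1:4) s <- s + x[i, j, c, n]
    oracle[n, c] <- s / 16
  }
  expect_lt(max(abs(g - oracle)), 1e-6)
})

test_that("sequential attention equals its composition and contracts magnitude", {
  mc <- tinyModelConfig()
  m <- buildModel(mc, seed = 8)
  C <- 3 * mc$branch_filters
  x <- randomTensor(3, 2, C, 3, seed = 14)
  sc <- scanForward(m, x)
  comp <- channelAttention(m, spatialAttention(m, x)$output)
  expect_equal(sc$output, comp$output, tolerance = 1e-12)
  expect_equal(sc$channel, comp$attention, tolerance = 1e-12)
  ## attention weights < 1 so magnitudes never grow
  expect_true(all(abs(sc$output) <= abs(x) + 1e-12))
  expect_equal(dim(sc$output), dim(x))
})

test_that("the dilated block fuses to the configured channel count", {
  mc <- tinyModelConfig()
  m <- buildModel(mc, seed = 3)
  C <- 3 * mc$branch_filters
  x <- randomTensor(3, 2, C, 2, seed = 15)
  y <- hdcbForward(m, x)
  expect_equal(dim(y), c(3, 2, mc$fuse_filters, 2))
  ## spatial dims preserved for a default-config model too
  mBig <- buildModel(modelConfig(features = 20), seed = 1)
  xb <- randomTensor(4, 10, 192, 1, seed = 16)
  expect_equal(dim(hdcbForward(mBig, xb)), c(4, 10, 128, 1))
})

test_that("sum fusion with shared weights triples a single branch", {
  mc <- tinyModelConfig(hdcb_fusion = "sum", dilation_rates = c(1L, 1L, 1L))
  m <- buildModel(mc, seed = 6)
  ## share the three branch kernels
  m$params$hdcb$d2 <- m$params$hdcb$d1
  m$params$hdcb$d3 <- m$params$hdcb$d1
  C <- 3 * mc$branch_filters
  x <- randomTensor(3, 2, C, 2, seed = 17)
  y <- hdcbForward(m, x)
  single <- sepnet:::convForward(x, m$params$hdcb$d1$W, m$params$hdcb$d1$b, 1L)
  ## eval-mode BN with fresh running stats divides by (1 + eps)
  expect_equal(y, sepnet:::reluForward(3 * single / (1 + 1e-5))$y,
               tolerance = 1e-9)
})

test_that("residual chain recursion matches stubbed compositions exactly", {
  mc <- tinyModelConfig()
  m <- buildModel(mc, seed = 7)
  x <- randomTensor(3, 2, mc$rpcc_filters, 2, seed = 18)
  ## zero residual function: identity
  expect_identical(rpccForward(m, x, fns = list(function(z) z * 0)), x)
  ## constant stub R: X + R
  R <- randomTensor(3, 2, mc$rpcc_filters, 2, seed = 19)
  expect_equal(rpccForward(m, x, fns = list(function(z) R)), x + R)
  ## two blocks: X + F1(X) + F2(X + F1(X))
  f1 <- function(z) 0.5 * z
  f2 <- function(z) z^2
  manual <- x + f1(x) + f2(x + f1(x))
  expect_equal(rpccForward(m, x, fns = list(f1, f2)), manual)
  ## learned chain preserves shape
  expect_equal(dim(rpccForward(m, x)), dim(x))
})

test_that("full forward emits probabilities in (0,1), deterministically", {
  mc <- tinyModelConfig(dropout = 0.5)
  m <- buildModel(mc, seed = 21)
  x <- randomTensor(6, 5, 1, 10, seed = 22)
  p1 <- predictProb(m, x)
  p2 <- predictProb(m, x)
  expect_identical(p1, p2)        # evaluation mode is a pure function
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(predictProb(m, randomTensor(4, 5, 1, 2)),
               class = "sepnetShapeError")
})

test_that("parameter count equals the independent layer-by-layer sum", {
  mc <- modelConfig(features = 44)
  m <- buildModel(mc, seed = 1)
  ef <- 64; bf <- 64; C <- 3 * bf; Cr <- C %/% 8
  eclf <- (3 * 3 * 1 * ef + ef) + 2 * ef +
    sum(sapply(c(3, 5, 7), function(k) k * k * ef * bf + bf)) + 2 * C
  scan <- (1 * 1 * C * Cr + Cr) + (7 * 7 * Cr * 1 + 1) +
    (C * 64 + 64) + (64 * C + C)
  hf <- 64; ff <- 128
  hdcb <- 3 * (3 * 3 * C * hf + hf) + (1 * 1 * 3 * hf * ff + ff) + 2 * ff
  rf <- 128
  rpcc <- (3 * 3 * ff * rf + rf) + 2 * rf + (3 * 3 * rf * rf + rf) +
          (3 * 3 * rf * rf + rf) + 2 * rf + (3 * 3 * rf * rf + rf)
  head <- (rf * 512 + 512) + (512 * 256 + 256) + (256 * 1 + 1)
  expect_identical(countParameters(m),
                   as.integer(eclf + scan + hdcb + rpcc + head))
})

test_that("the model is well-formed across window and feature sizes", {
  for (Tw in c(4L, 9L, 16L)) {
    for (Fn in c(8L, 21L, 64L)) {
      mc <- tinyModelConfig(features = Fn, window = Tw)
      m <- buildModel(mc, seed = 1)
      p <- predictProb(m, randomTensor(Tw, Fn, 1, 2, seed = Tw + Fn))
      expect_length(p, 2L)
      expect_true(all(p > 0 & p < 1))
    }
  }
})

test_that("checkpoints restore an identical model", {
  mc <- tinyModelConfig()
  m <- buildModel(mc, seed = 30)
  x <- randomTensor(6, 5, 1, 3, seed = 31)
  p <- tempfile(fileext = ".rds")
  writeModelCheckpoint(m, p)
  m2 <- readModelCheckpoint(p)
  expect_identical(predictProb(m, x), predictProb(m2, x))
})

test_that("backpropagation matches finite differences through all blocks", {
  set.seed(40)
  mc <- tinyModelConfig(dense_units = c(16L, 8L))
  m <- buildModel(mc, seed = 41)
  x <- randomTensor(6, 5, 1, 4, seed = 42)
  y <- c(0, 1, 1, 1)
  lossAt <- function(model) {
    f <- sepnet:::forwardPass(model, x, training = TRUE)
    bceLoss(pmin(pmax(f$prob, 1e-12), 1 - 1e-12), y)
  }
  fw <- sepnet:::forwardPass(m, x, training = TRUE)
  p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  dz <- matrix(((1 - y) * p - y * (1 - p)) / length(y), ncol = 1)
  gr <- sepnet:::backwardPass(m, fw$caches, dz)
  flat <- function(l, pre = "") {
    out <- list()
    for (nm in names(l)) {
      v <- l[[nm]]
      if (is.numeric(v)) out[[paste0(pre, nm)]] <- v
      else out <- c(out, flat(v, paste0(pre, nm, ".")))
    }
    out
  }
  fp <- flat(m$params); fg <- flat(gr)
  expect_setequal(names(fp), names(fg))
  modify <- function(pl, path, i, d) {
    if (length(path) == 1) { pl[[path]][i] <- pl[[path]][i] + d; pl }
    else { pl[[path[1]]] <- modify(pl[[path[1]]], path[-1], i, d); pl }
  }
  rels <- c()
  for (k in 1:50) {
    leaf <- sample(names(fp), 1)
    i <- sample(length(fp[[leaf]]), 1)
    path <- strsplit(leaf, ".", fixed = TRUE)[[1]]
    eps <- 1e-5
    m2 <- m
    m2$params <- modify(m$params, path, i, eps);  l1 <- lossAt(m2)
    m2$params <- modify(m$params, path, i, -eps); l2 <- lossAt(m2)
    num <- (l1 - l2) / (2 * eps)
    ana <- fg[[leaf]][i]
    if (abs(num) + abs(ana) > 1e-8)
      rels <- c(rels, abs(num - ana) / (abs(num) + abs(ana)))
  }
  expect_gt(length(rels), 25)
  ## almost all sampled derivatives agree to high precision; a rare larger
  ## deviation is possible when the perturbation crosses a ReLU/pool kink
  expect_gte(mean(rels < 1e-4), 0.9)
  expect_lt(median(rels), 1e-6)
})
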