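## Training loop: Adam, binary cross-entropy, early stopping on validation
## loss with best-weight restoration.

#' Training configuration
#'
#' @param lr initial Adam learning rate, default 0.001.
#' @param batch_size minibatch size, default 128.
#' @param max_epochs cap on training epochs, default 100.
#' @param patience early-stopping patience in epochs on validation loss,
#'   default 10, with best-weight restoration.
#' @param threshold decision threshold on the sigmoid output, default 0.5.
#' @param pos_weight positive-class weight in the cross-entropy (1 = none);
#'   exposed because sepsis-positive timesteps are about 1.8% of records.
#' @param balanced if `TRUE`, minibatches are drawn half from positive and
#'   half from negative windows (with replacement from the smaller class) —
#'   a standard undersampling scheme for rare-event cohorts.
#' @param steps_per_epoch optional cap on gradient steps per epoch (an
#'   epoch is then that many minibatches); `NULL` sweeps the whole training
#'   set.
#' @param seed RNG seed for shuffling, sampling and dropout.
#' @return A list of class `trainConfig`.
#' @export
trainConfig <- function(lr = 0.001, batch_size = 128L, max_epochs = 100L,
                        patience = 10L, threshold = 0.5, pos_weight = 1,
                        balanced = FALSE, steps_per_epoch = NULL,
                        seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1,
            threshold > 0, threshold < 1, pos_weight > 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), threshold = threshold,
                 pos_weight = pos_weight, balanced = isTRUE(balanced),
                 steps_per_epoch = if (is.null(steps_per_epoch)) NULL
                                   else as.integer(steps_per_epoch),
                 seed = as.integer(seed)),
            class = "trainConfig")
}

## Recursive helpers over nested parameter lists -----------------------------

.pMap <- function(f, a, b = NULL, c = NULL) {
  if (is.numeric(a))
    return(if (is.null(b)) f(a) else if (is.null(c)) f(a, b) else f(a, b, c))
  out <- a
  for (nm in names(a))
    out[[nm]] <- .pMap(f, a[[nm]],
                       if (!is.null(b)) b[[nm]], if (!is.null(c)) c[[nm]])
  out
}

.adamInit <- function(params) {
  list(m = .pMap(function(x) x * 0, params),
       v = .pMap(function(x) x * 0, params), t = 0L)
}

.adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- .pMap(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- .pMap(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  params <- .pMap(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                  params, opt$m, opt$v)
  list(params = params, opt = opt)
}

#' Binary cross-entropy of sigmoid probabilities
#'
#' @param prob predicted probabilities in (0, 1).
#' @param y 0/1 labels.
#' @param posWeight weight on the positive-class term.
#' @return Mean loss (scalar).
#' @export
bceLoss <- function(prob, y, posWeight = 1) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(posWeight * y * log(p) + (1 - y) * log(1 - p))
}

.evalSplit <- function(model, x, y, threshold, posWeight, batchSize = 512L) {
  prob <- predictProb(model, x, batchSize)
  list(loss = bceLoss(prob, y, posWeight),
       acc = mean((prob >= threshold) == (y == 1)),
       prob = prob)
}

#' Train the classifier
#'
#' Minibatch Adam on binary cross-entropy with early stopping: training
#' stops once the validation loss has not improved for `patience`
#' consecutive epochs (or at `max_epochs`) and the best-validation-loss
#' weights are restored.  With `balanced = TRUE` each minibatch is drawn
#' half from each class.  NaN loss aborts with a diagnostic.
#'
#' @param model a freshly built `sepnetModel`.
#' @param xTrain,yTrain training windows `(T, F, 1, N)` and 0/1 labels.
#' @param xVal,yVal validation windows and labels.
#' @param config a [trainConfig()].
#' @return List with `model` (trained, best weights restored), `history`
#'   (data frame: epoch, train/validation loss and accuracy) and
#'   `bestEpoch`.
#' @export
trainModel <- function(model, xTrain, yTrain, xVal, yVal,
                       config = trainConfig()) {
  n <- dim(xTrain)[4]
  if (is.null(n) || n < 1L)
    sepnetStop("empty training partition", "sepnetValidationError")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  opt <- .adamInit(model$params)
  hist <- data.frame()
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = 0L)
  bad <- 0L
  posIdx <- which(yTrain == 1); negIdx <- which(yTrain == 0)

  for (epoch in seq_len(config$max_epochs)) {
    if (config$balanced && length(posIdx) && length(negIdx)) {
      steps <- if (is.null(config$steps_per_epoch))
        max(1L, ceiling(2 * min(length(posIdx), length(negIdx)) /
                          config$batch_size))
      else config$steps_per_epoch
      half <- max(1L, config$batch_size %/% 2L)
      batches <- lapply(seq_len(steps), function(s)
        c(sample(posIdx, half, replace = length(posIdx) < half),
          sample(negIdx, half, replace = length(negIdx) < half)))
    } else {
      ord <- sample.int(n)
      if (!is.null(config$steps_per_epoch))
        ord <- ord[seq_len(min(n, config$steps_per_epoch * config$batch_size))]
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    }
    runLoss <- 0; runAcc <- 0; runN <- 0L
    for (b in batches) {
      xb <- xTrain[, , , b, drop = FALSE]
      yb <- yTrain[b]
      fw <- forwardPass(model, xb, training = TRUE)
      model$state <- fw$state
      p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      loss <- bceLoss(p, yb, config$pos_weight)
      if (!is.finite(loss))
        sepnetStop(sprintf("NaN/Inf loss at epoch %d; aborting", epoch),
                   "sepnetNumericsError")
      ## d(mean BCE)/d(logit)
      dz <- matrix(((1 - yb) * p - config$pos_weight * yb * (1 - p)) /
                     length(yb), ncol = 1)
      grads <- backwardPass(model, fw$caches, dz)
      stepped <- .adamStep(model$params, grads, opt, config$lr)
      model$params <- stepped$params
      opt <- stepped$opt
      runLoss <- runLoss + loss * length(yb)
      runAcc <- runAcc + sum((p >= config$threshold) == (yb == 1))
      runN <- runN + length(yb)
    }
    val <- .evalSplit(model, xVal, yVal, config$threshold, config$pos_weight)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = runLoss / runN, train_acc = runAcc / runN,
      val_loss = val$loss, val_acc = val$acc))
    if (val$loss < best$loss - 1e-12) {
      best <- list(loss = val$loss, params = model$params,
                   state = model$state, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = hist, bestEpoch = best$epoch)
}
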