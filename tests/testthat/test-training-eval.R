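test_that("split sizes reproduce the study partition and always sum to total", {
  expect_identical(computeSplitSizes(1552210, c(0.8, 0.1, 0.1)),
                   c(1241768L, 155221L, 155221L))
  expect_identical(computeSplitSizes(10, c(0.8, 0.1, 0.1)), c(8L, 1L, 1L))
  ## exhaustive conservation check over small totals
  for (tot in 1:1000) {
    cs <- computeSplitSizes(tot, c(0.8, 0.1, 0.1))
    expect_identical(sum(cs), as.integer(tot))
  }
})

test_that("patient-wise splits are disjoint, complete and deterministic", {
  co <- simulateCohort(simConfig(nPatients = 60, seed = 14))
  for (s in 1:50) {
    a <- patientWiseSplit(co, seed = s)
    parts <- split(names(a$partition), a$partition)
    ids <- unname(unlist(parts))
    expect_equal(sort(ids), sort(patientIds(co)))
    expect_equal(anyDuplicated(ids), 0L)
  }
  a1 <- patientWiseSplit(co, seed = 7)
  a2 <- patientWiseSplit(co, seed = 7)
  expect_identical(a1$partition, a2$partition)
})

test_that("greedy assignment keeps realized record fractions near target", {
  co <- simulateCohort(simConfig(nPatients = 5000, seed = 15))
  a <- patientWiseSplit(co, seed = 1)
  frac <- a$recordCounts / ncol(co)
  expect_gte(frac[["train"]], 0.78)
  expect_lte(frac[["train"]], 0.82)
  expect_lt(abs(frac[["val"]] - 0.1), 0.02)
  expect_lt(abs(frac[["test"]] - 0.1), 0.02)
})

test_that("confusion counts match a manual tally", {
  prob <- c(0.9, 0.8, 0.4, 0.6, 0.2, 0.3, 0.7, 0.1)
  lab <-  c(1,   1,   1,   0,   0,   1,   0,   0)
  cc <- confusionCounts(prob, lab, 0.5)
  ## manual tally: pred = prob >= 0.5 -> T T F T F F T F
  expect_equal(cc@tp, 2L); expect_equal(cc@fn, 2L)
  expect_equal(cc@fp, 2L); expect_equal(cc@tn, 2L)
  ## perfect separation: no errors
  cc2 <- confusionCounts(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(cc2@fp + cc2@fn, 0L)
  ## all-positive predictor on balanced labels: TN = 0, FPR = 100
  cc3 <- confusionCounts(rep(0.9, 6), c(1, 0, 1, 0, 1, 0), 0.5)
  expect_equal(cc3@tn, 0L)
  m3 <- computeMetrics(cc3)
  expect_equal(m3@metrics[["fpr"]], 100)
})

test_that("the metric suite honours its identities and the percent scale", {
  cc <- methods::new("ConfusionCounts", tp = 50L, fp = 0L, tn = 50L, fn = 0L)
  m <- computeMetrics(cc, auc = 1)
  for (k in c("accuracy", "precision", "recall", "f1", "specificity"))
    expect_equal(m@metrics[[k]], 100)
  ## complement identities at machine precision on a generic report
  cc2 <- methods::new("ConfusionCounts", tp = 37L, fp = 11L, tn = 95L, fn = 4L)
  m2 <- computeMetrics(cc2, auc = 0.9)@metrics
  expect_equal(m2[["specificity"]] + m2[["fpr"]], 100, tolerance = 1e-12)
  expect_equal(m2[["recall"]] + m2[["fnr"]], 100, tolerance = 1e-12)
  expect_equal(m2[["f1"]],
               2 * m2[["precision"]] * m2[["recall"]] /
                 (m2[["precision"]] + m2[["recall"]]),
               tolerance = 1e-12)
  ## a 0.7% false positive rate is a 99.3% specificity (and vice versa)
  ccS <- methods::new("ConfusionCounts", tp = 0L, fp = 7L, tn = 993L, fn = 0L)
  mS <- suppressWarnings(computeMetrics(ccS))@metrics
  expect_equal(mS[["specificity"]], 99.3, tolerance = 1e-9)
  expect_equal(mS[["fpr"]], 0.7, tolerance = 1e-9)
  ## a 0.8% false negative rate is a 99.2% recall
  ccR <- methods::new("ConfusionCounts", tp = 992L, fp = 0L, tn = 0L, fn = 8L)
  mR <- suppressWarnings(computeMetrics(ccR))@metrics
  expect_equal(mR[["recall"]], 99.2, tolerance = 1e-9)
  expect_equal(mR[["fnr"]], 0.8, tolerance = 1e-9)
  ## undefined ratios surface as NA with warnings, never silent zero
  ccU <- methods::new("ConfusionCounts", tp = 0L, fp = 0L, tn = 5L, fn = 0L)
  ws <- capture_warnings(mU <- computeMetrics(ccU))
  expect_true(any(grepl("undefined", ws)))
  expect_true(is.na(mU@metrics[["precision"]]))
  expect_true(is.na(mU@metrics[["recall"]]))
})

test_that("the normalized confusion matrix is row-stochastic in percent", {
  cc <- methods::new("ConfusionCounts", tp = 163L, fp = 7L, tn = 993L, fn = 1L)
  nm <- normalizedConfusion(cc)
  expect_equal(unname(rowSums(nm)), c(100, 100), tolerance = 1e-9)
  expect_equal(nm["non-sepsis", "pred non-sepsis"], 99.3, tolerance = 1e-9)
  expect_equal(nm["non-sepsis", "pred sepsis"], 0.7, tolerance = 1e-9)
  ## diagonal 99.39 over the sepsis row implies 0.61 off-diagonal
  cc2 <- methods::new("ConfusionCounts", tp = 9939L, fp = 0L, tn = 0L,
                      fn = 61L)
  nm2 <- normalizedConfusion(cc2)
  expect_equal(nm2["sepsis", "pred sepsis"], 99.39, tolerance = 1e-9)
  expect_equal(nm2["sepsis", "pred non-sepsis"], 0.61, tolerance = 1e-9)
})

test_that("rank-based AUC equals the exhaustive pairwise oracle", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    prob <- round(runif(n), 2)          # rounded scores force ties
    expect_equal(rocAuc(prob, lab), pairwiseAuc(prob, lab),
                 tolerance = 1e-12)
  }
  ## independent library cross-check on one fixture
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(24)
    lab <- rbinom(80, 1, 0.5); prob <- round(runif(80), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(lab, prob, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(prob, lab), ref, tolerance = 1e-12)
  }
  expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), class = "sepnetError")
})

test_that("early stopping halts after patience epochs without improvement", {
  co <- simulateCohort(simConfig(nPatients = 12, seed = 33))
  tw <- tensorizeWindows(transformCohort(co, fitPreprocessor(co)), 6)
  ## all blocks bypassed (head only, no batch norm) + a vanishing learning
  ## rate plants a run whose validation loss cannot improve after epoch 1
  mc <- tinyModelConfig(features = dim(tw$x)[2], window = 6,
                        use_eclf = FALSE, use_scan = FALSE,
                        use_hdcb = FALSE, use_rpcc = FALSE)
  m <- buildModel(mc, seed = 1)
  tc <- trainConfig(lr = 1e-15, batch_size = 32L, max_epochs = 10L,
                    patience = 1L, seed = 2)
  out <- trainModel(m, tw$x, tw$y, tw$x, tw$y, tc)
  expect_equal(nrow(out$history), 2L)
  expect_equal(out$bestEpoch, 1L)
  ## history arrays stay aligned
  expect_false(anyNA(out$history$train_loss))
  expect_equal(length(out$history$train_loss), length(out$history$val_loss))
})

test_that("training rejects an empty partition", {
  mc <- tinyModelConfig()
  m <- buildModel(mc, seed = 1)
  empty <- array(0, c(6, 5, 1, 0))
  expect_error(trainModel(m, empty, integer(0), empty, integer(0),
                          trainConfig()),
               class = "sepnetValidationError")
})

test_that("six patient-wise folds partition sixty patients evenly", {
  co <- simulateCohort(simConfig(nPatients = 60, seed = 44))
  mc <- tinyModelConfig(features = 14, window = 6)
  tc <- trainConfig(max_epochs = 1L, steps_per_epoch = 2L, batch_size = 16L,
                    balanced = TRUE, seed = 1)
  ## tiny folds can yield degenerate confusion cells, whose NA warnings are
  ## part of the metric contract and not of interest here
  cv <- suppressWarnings(kfoldCv(co, k = 6L, mConfig = mc, tConfig = tc,
                                 seed = 3))
  expect_length(cv$folds, 6L)
  sizes <- table(cv$assignment)
  expect_true(all(sizes == 10L))
  expect_equal(sort(names(cv$assignment)), sort(patientIds(co)))
  ## summary mean/sd equals the arithmetic over per-fold metrics
  accs <- vapply(cv$folds, function(r) r@metrics[["accuracy"]], numeric(1))
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"], mean(accs))
  expect_equal(cv$summary$sd[cv$summary$metric == "accuracy"],
               sqrt(mean((accs - mean(accs))^2)))
})

test_that("fold summary statistics match hand arithmetic on planted values", {
  vals <- c(99.1, 99.5, 99.3, 99.2, 99.6, 99.3)
  m <- mean(vals)
  s <- sqrt(mean((vals - m)^2))
  expect_equal(m, 99.33333333, tolerance = 1e-7)
  expect_equal(s, sqrt(sum((vals - m)^2) / 6), tolerance = 1e-12)
})

test_that("metric reports serialize to CSV and key-value files", {
  cc <- methods::new("ConfusionCounts", tp = 10L, fp = 2L, tn = 30L, fn = 1L)
  rep <- computeMetrics(cc, auc = 0.97)
  base <- tempfile()
  writeMetricsReport(rep, base)
  csv <- read.csv(paste0(base, ".csv"))
  expect_true("accuracy" %in% csv$metric)
  yml <- yaml::read_yaml(paste0(base, ".yaml"))
  expect_equal(yml$tp, 10L)
  expect_equal(yml$auc, 0.97)
})
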