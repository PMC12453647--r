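## Patient-wise splitting, the metric suite, cross-validation and the
## ablation runner.

#' Partition record counts for given fractions
#'
#' Round-to-nearest of `fraction * total` per partition, with the remainder
#' assigned to the first (training) partition so the counts sum to the
#' total.
#'
#' @param total total record count.
#' @param fractions numeric fractions summing to 1 (train first).
#' @return Integer vector of per-partition counts summing to `total`.
#' @examples
#' computeSplitSizes(1552210, c(0.8, 0.1, 0.1))  # 1241768 155221 155221
#' @export
computeSplitSizes <- function(total, fractions = c(0.8, 0.1, 0.1)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, total >= 0)
  counts <- round(fractions * total)
  counts[1] <- counts[1] + (total - sum(counts))
  as.integer(counts)
}

#' Patient-wise train/validation/test split
#'
#' Patients are shuffled by the seed and assigned greedily: each patient
#' goes to the partition whose record-count deficit (target minus assigned)
#' is largest, so realized record fractions track the targets while no
#' patient ever spans two partitions.
#'
#' @param cohort a [SepsisCohort-class].
#' @param fractions train/validation/test record fractions.
#' @param seed shuffle seed.
#' @return A list of class `splitAssignment`: `partition` (named character
#'   vector per patient with values `"train"`, `"val"`, `"test"`),
#'   `fractions`, `seed` and `recordCounts`.
#' @export
patientWiseSplit <- function(cohort, fractions = c(0.8, 0.1, 0.1),
                             seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  pid <- patientOf(cohort)
  counts <- table(factor(pid, levels = unique(pid)))
  ids <- names(counts)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ord <- sample.int(length(ids))
  total <- sum(counts)
  target <- fractions * total
  assigned <- c(train = 0, val = 0, test = 0)
  part <- setNames(character(length(ids)), ids)
  for (i in ord) {
    deficit <- target - assigned
    k <- which.max(deficit)
    part[ids[i]] <- names(assigned)[k]
    assigned[k] <- assigned[k] + counts[[i]]
  }
  structure(list(partition = part, fractions = fractions, seed = seed,
                 recordCounts = assigned),
            class = "splitAssignment")
}

#' Subset a cohort by split partition
#'
#' @param cohort a [SepsisCohort-class].
#' @param assignment a [patientWiseSplit()] result.
#' @param which `"train"`, `"val"` or `"test"`.
#' @return The partition's [SepsisCohort-class].
#' @export
splitCohort <- function(cohort, assignment, which = c("train", "val", "test")) {
  which <- match.arg(which)
  subsetPatients(cohort, names(assignment$partition)[
    assignment$partition == which])
}

#' Confusion counts at a decision threshold
#'
#' @param prob predicted probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (prediction positive when
#'   `prob >= threshold`), default 0.5.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(prob, labels, threshold = 0.5) {
  stopifnot(length(prob) == length(labels), all(labels %in% c(0, 1)))
  pred <- prob >= threshold
  methods::new("ConfusionCounts",
               tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
               tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1))
}

#' Metric suite from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), F1 (exact harmonic mean of
#' precision and recall), specificity, FPR = 100 - specificity and
#' FNR = 100 - recall, all in percent at full precision, plus the supplied
#' AUC.  Ratios with zero denominators are `NA` with a warning, never
#' silently zero.
#'
#' @param counts a [ConfusionCounts-class].
#' @param auc AUC in [0, 1] (e.g. from [rocAuc()]); `NA` if not available.
#' @return A [MetricsReport-class].
#' @export
computeMetrics <- function(counts, auc = NA_real_) {
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  total <- tp + fp + tn + fn
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA", what))
      return(NA_real_)
    }
    100 * num / den
  }
  acc <- ratio(tp + tn, total, "accuracy")
  prec <- ratio(tp, tp + fp, "precision")
  rec <- ratio(tp, tp + fn, "recall")
  spec <- ratio(tn, tn + fp, "specificity")
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) {
    warning("F1 undefined; reported as NA")
    NA_real_
  } else 2 * prec * rec / (prec + rec)
  m <- c(accuracy = acc, precision = prec, recall = rec, f1 = f1,
         specificity = spec, fpr = if (is.na(spec)) NA_real_ else 100 - spec,
         fnr = if (is.na(rec)) NA_real_ else 100 - rec, auc = auc)
  methods::new("MetricsReport", metrics = m, counts = counts)
}

#' Row-normalized confusion matrix in percent
#'
#' Each true-class row is normalized to sum to 100%; off-diagonals are the
#' row complements of the diagonals.
#'
#' @param counts a [ConfusionCounts-class].
#' @return 2x2 numeric matrix (rows: true non-sepsis, true sepsis).
#' @export
normalizedConfusion <- function(counts) {
  m <- matrix(c(counts@tn, counts@fp, counts@fn, counts@tp), 2, 2,
              byrow = TRUE,
              dimnames = list(c("non-sepsis", "sepsis"),
                              c("pred non-sepsis", "pred sepsis")))
  sweep(m, 1, rowSums(m), "/") * 100
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random
#' positive outscores a random negative, counting ties as one half.
#'
#' @param prob predicted scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(prob, labels) {
  stopifnot(length(prob) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    sepnetStop("AUC needs both classes present", "sepnetValidationError")
  r <- rank(prob, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

## Shared pipeline: preprocess (fit on train only), tensorize, train,
## evaluate on the held-out cohort.
.runPipeline <- function(trainCohort, evalCohort, mConfig, tConfig,
                         ppConfig = preprocessConfig(), seed = 1L) {
  fitted <- fitPreprocessor(trainCohort, ppConfig)
  trT <- transformCohort(trainCohort, fitted)
  evT <- transformCohort(evalCohort, fitted)
  trW <- tensorizeWindows(trT, mConfig$window)
  evW <- tensorizeWindows(evT, mConfig$window)
  mdl <- buildModel(mConfig, seed = seed)
  fit <- trainModel(mdl, trW$x, trW$y, evW$x, evW$y, tConfig)
  prob <- predictProb(fit$model, evW$x)
  auc <- if (length(unique(evW$y)) == 2L) rocAuc(prob, evW$y) else NA_real_
  report <- computeMetrics(confusionCounts(prob, evW$y, tConfig$threshold),
                           auc)
  list(model = fit$model, history = fit$history, prob = prob, y = evW$y,
       report = report, fitted = fitted)
}

#' Patient-wise stratified k-fold cross-validation
#'
#' Patients are stratified by patient-level sepsis occurrence and dealt
#' into k near-equal folds; each fold serves as the validation set exactly
#' once while the model is trained on the remaining folds (preprocessing
#' statistics are refitted on each training portion).  The summary reports
#' the per-metric mean and population standard deviation across folds.
#'
#' @param cohort a raw [SepsisCohort-class].
#' @param k number of folds, default 6.
#' @param mConfig a [modelConfig()] (its `features` must match the
#'   preprocessed feature count).
#' @param tConfig a [trainConfig()].
#' @param seed fold-assignment seed.
#' @return List with `folds` (per-fold [MetricsReport-class]), `summary`
#'   (data frame: metric, mean, sd) and `assignment` (patient -> fold).
#' @export
kfoldCv <- function(cohort, k = 6L, mConfig, tConfig, seed = 1L) {
  pid <- patientOf(cohort); lab <- sepsisLabels(cohort)
  ids <- unique(pid)
  septic <- vapply(split(lab, factor(pid, levels = ids)), function(v)
    any(v == 1L), logical(1))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ## shuffled septic patients first, then shuffled non-septic, dealt
  ## round-robin: fold sizes differ by at most one and each stratum is
  ## spread as evenly as possible
  shuf <- function(v) if (length(v) <= 1L) v else sample(v)
  ordered <- c(shuf(ids[septic]), shuf(ids[!septic]))
  fold <- setNames(rep_len(seq_len(k), length(ordered)), ordered)
  fold <- fold[ids]
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    trainIds <- ids[fold[ids] != f]
    valIds <- ids[fold[ids] == f]
    out <- .runPipeline(subsetPatients(cohort, trainIds),
                        subsetPatients(cohort, valIds),
                        mConfig, tConfig, seed = seed + f)
    reports[[f]] <- out$report
  }
  mat <- do.call(rbind, lapply(reports, function(r) r@metrics))
  summ <- data.frame(metric = colnames(mat),
                     mean = colMeans(mat),
                     sd = apply(mat, 2, function(v)
                       sqrt(mean((v - mean(v))^2))),
                     row.names = NULL)
  list(folds = reports, summary = summ, assignment = fold)
}

#' Architecture ablation runner
#'
#' Trains and evaluates the model variants in which one block is replaced
#' by an identity bypass (downstream 1x1 adapters handle any channel
#' mismatch), under identical data, seed and training budget, and reports
#' the metric suite per variant.
#'
#' @param cohort a raw [SepsisCohort-class].
#' @param variants character subset of `c("full", "without_SCAN",
#'   "without_HDCB", "without_RPCC", "without_ECLF")`.
#' @param mConfig,tConfig model and training configuration shared by all
#'   variants.
#' @param seed split/init seed shared by all variants.
#' @return List with `reports` (named [MetricsReport-class] per variant)
#'   and `table` (data frame shaped like an ablation summary: variant,
#'   accuracy, precision, recall, F1, AUC, parameters).
#' @export
runAblation <- function(cohort,
                        variants = c("full", "without_SCAN", "without_HDCB",
                                     "without_RPCC", "without_ECLF"),
                        mConfig, tConfig, seed = 1L) {
  variants <- match.arg(variants, several.ok = TRUE)
  split <- patientWiseSplit(cohort, seed = seed)
  trainC <- splitCohort(cohort, split, "train")
  valC <- splitCohort(cohort, split, "val")
  reports <- list(); pars <- integer()
  for (v in variants) {
    mc <- mConfig
    if (v == "without_SCAN") mc$use_scan <- FALSE
    if (v == "without_HDCB") mc$use_hdcb <- FALSE
    if (v == "without_RPCC") mc$use_rpcc <- FALSE
    if (v == "without_ECLF") mc$use_eclf <- FALSE
    out <- .runPipeline(trainC, valC, mc, tConfig, seed = seed)
    reports[[v]] <- out$report
    pars[v] <- countParameters(out$model)
  }
  tab <- do.call(rbind, lapply(names(reports), function(v) {
    m <- reports[[v]]@metrics
    data.frame(variant = v, accuracy = m[["accuracy"]],
               precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], auc = m[["auc"]], parameters = pars[[v]])
  }))
  list(reports = reports, table = tab)
}
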