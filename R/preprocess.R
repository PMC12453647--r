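## Column-level preprocessing primitives and the fit/transform pipeline.
## Statistics are always learned on the training split only and reused
## verbatim on held-out data; the execution order within the pipeline is
## impute -> outlier policy -> scale.

.spread <- function(x, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  m <- mean(x)
  if (convention == "population") sqrt(mean((x - m)^2)) else stats::sd(x)
}

#' Mean imputation of a column
#'
#' Missing entries are replaced by the mean of the observed entries;
#' observed entries are untouched.
#'
#' @param x numeric vector.
#' @param observed logical mask, `TRUE` where measured (default: non-`NA`).
#' @param feature feature name used in error messages.
#' @return The filled numeric vector.
#' @export
imputeMean <- function(x, observed = !is.na(x), feature = "feature") {
  if (!any(observed))
    sepnetStop(sprintf("cannot impute feature '%s': no observed values", feature),
               "sepnetImputationError")
  x[!observed] <- mean(x[observed])
  x
}

#' Forward/backward-fill imputation for time series
#'
#' Interior and trailing gaps take the previous observed value; leading gaps
#' take the next observed value.
#'
#' @inheritParams imputeMean
#' @return The filled numeric vector.
#' @export
imputeTimeSeries <- function(x, observed = !is.na(x), feature = "feature") {
  if (!any(observed))
    sepnetStop(sprintf("cannot impute feature '%s': no observed values", feature),
               "sepnetImputationError")
  n <- length(x)
  idx <- ifelse(observed, seq_len(n), 0L)
  last <- cummax(idx)                       # index of previous observed value
  first <- idx
  first[first == 0L] <- NA_integer_
  nxt <- rev(cummin(replace(rev(first), is.na(rev(first)), n + 1L)))
  pick <- ifelse(last > 0L, last, nxt)      # previous if any, else next
  x[pick]
}

#' Min-max scaling with fitted statistics
#'
#' `x' = (x - min) / (max - min)` with the minimum and maximum learned on
#' the training split; a constant feature (max equal to min) maps to 0.
#' Held-out values may fall outside `[0, 1]`.
#'
#' @param x numeric vector.
#' @param fitted list with elements `min` and `max`.
#' @return Scaled numeric vector.
#' @export
minmaxScale <- function(x, fitted) {
  rng <- fitted$max - fitted$min
  if (rng == 0) return(rep(0, length(x)))
  (x - fitted$min) / rng
}

#' Z-score standardization with fitted statistics
#'
#' `x' = (x - mean) / sd` with training-split moments; a constant feature
#' (zero spread) maps to all zeros.
#'
#' @param x numeric vector.
#' @param fitted list with elements `mean` and `sd`.
#' @return Standardized numeric vector.
#' @export
zscoreStandardize <- function(x, fitted) {
  if (fitted$sd == 0) return(rep(0, length(x)))
  (x - fitted$mean) / fitted$sd
}

#' One-hot encode a categorical value
#'
#' @param value character value(s) to encode.
#' @param declaredOrder category order; the encoding follows this order, not
#'   alphabetical order.
#' @param strict if `TRUE` an unseen category is an error; otherwise it maps
#'   to an all-zero vector with a warning.
#' @return A 0/1 vector (or matrix, one row per input value) with a single 1
#'   at the declared index for each seen category.
#' @examples
#' oneHotEncode("Male", c("Male", "Female", "Other"))  # 1 0 0
#' @export
oneHotEncode <- function(value, declaredOrder, strict = TRUE) {
  idx <- match(value, declaredOrder)
  if (anyNA(idx)) {
    if (strict)
      sepnetStop(sprintf("unseen category '%s'", value[is.na(idx)][1]),
                 "sepnetEncodingError")
    warning("unseen category encoded as all-zeros vector")
  }
  out <- matrix(0, length(value), length(declaredOrder),
                dimnames = list(NULL, declaredOrder))
  seen <- !is.na(idx)
  out[cbind(which(seen), idx[seen])] <- 1
  if (length(value) == 1L) drop(out) else out
}

#' Integer (label) encode a categorical value
#'
#' Categories are assigned consecutive integers starting at 0 in declared
#' order.
#'
#' @inheritParams oneHotEncode
#' @return Integer code(s), 0-based.
#' @examples
#' labelEncode("Female", c("Male", "Female", "Other"))  # 1
#' @export
labelEncode <- function(value, declaredOrder, strict = TRUE) {
  idx <- match(value, declaredOrder) - 1L
  if (anyNA(idx) && strict)
    sepnetStop(sprintf("unseen category '%s'", value[is.na(idx)][1]),
               "sepnetEncodingError")
  idx
}

#' Z-score outlier handling
#'
#' Computes `Z = (x - mean) / sd` with fitted statistics and flags entries
#' with `|Z|` above the threshold.  Policy `"cap"` replaces flagged entries
#' by `mean +/- threshold * sd` (matching the sign of the excursion),
#' `"remove"` marks them missing (`NA`), `"flag"` leaves values untouched.
#'
#' @param x numeric vector.
#' @param fitted list with `mean` and `sd` (sd > 0).
#' @param threshold z-score threshold, default 3.
#' @param policy one of `"cap"`, `"remove"`, `"flag"`.
#' @return List with `values` (transformed column) and `flags` (logical).
#' @export
outlierTransform <- function(x, fitted, threshold = 3,
                             policy = c("cap", "remove", "flag")) {
  policy <- match.arg(policy)
  stopifnot(threshold > 0, fitted$sd > 0)
  z <- (x - fitted$mean) / fitted$sd
  flags <- !is.na(z) & abs(z) > threshold
  values <- x
  if (policy == "cap")
    values[flags] <- fitted$mean + sign(z[flags]) * threshold * fitted$sd
  else if (policy == "remove")
    values[flags] <- NA_real_
  list(values = values, flags = flags)
}

#' Preprocessing configuration
#'
#' @param impute named character: imputation mode per feature group, each
#'   `"forward_fill"` (per-patient forward/backward fill, then the training
#'   mean for patients with no observations) or `"mean"`.
#' @param scaling `"zscore"` or `"minmax"`.
#' @param outlierThreshold z-score threshold (> 0), default 3.
#' @param outlierPolicy `"cap"` (default), `"remove"` or `"flag"`.
#' @param sdConvention `"population"` (divide by N, default) or `"sample"`.
#' @param encoding `"one_hot"` (default) or `"label"` for categoricals.
#' @return A list of class `preprocessConfig`.
#' @export
preprocessConfig <- function(impute = c(vital = "forward_fill",
                                        lab = "forward_fill",
                                        demographic = "mean"),
                             scaling = c("zscore", "minmax"),
                             outlierThreshold = 3,
                             outlierPolicy = c("cap", "remove", "flag"),
                             sdConvention = c("population", "sample"),
                             encoding = c("one_hot", "label")) {
  stopifnot(outlierThreshold > 0,
            all(impute %in% c("mean", "forward_fill")),
            all(c("vital", "lab", "demographic") %in% names(impute)))
  structure(list(impute = impute, scaling = match.arg(scaling),
                 outlierThreshold = outlierThreshold,
                 outlierPolicy = match.arg(outlierPolicy),
                 sdConvention = match.arg(sdConvention),
                 encoding = match.arg(encoding)),
            class = "preprocessConfig")
}

## Impute one feature row across the cohort given per-patient index blocks.
.imputeRow <- function(v, obs, blocks, mode, center, feature) {
  v[!obs] <- NA_real_
  if (mode == "forward_fill") {
    for (b in blocks) {
      if (any(obs[b])) v[b] <- imputeTimeSeries(v[b], obs[b], feature)
    }
  }
  v[is.na(v)] <- center
  v
}

#' Fit preprocessing statistics on a training cohort
#'
#' Learns, from observed training values only: per-feature imputation means
#' (and modal categories), outlier mean/spread, category maps, and scaling
#' statistics computed on the imputed, outlier-handled training columns so
#' that the transformed training split satisfies the scaling contract
#' exactly.
#'
#' @param cohort a [SepsisCohort-class] (the training split).
#' @param config a [preprocessConfig()].
#' @return A [FittedPreprocessor-class].
#' @export
fitPreprocessor <- function(cohort, config = preprocessConfig()) {
  sch <- cohortSchema(cohort)
  vals <- cohortValues(cohort); obs <- observedMask(cohort)
  pid <- patientOf(cohort)
  blocks <- split(seq_len(ncol(vals)), factor(pid, levels = unique(pid)))
  fn <- sch@featureNames

  imputeCenter <- setNames(rep(NA_real_, length(fn)), fn)
  imputeMode <- list()
  outlierCenter <- outlierSpread <- imputeCenter
  catMaps <- list()
  outFeat <- character(); outGroup <- character()
  outCols <- list()

  for (i in seq_along(fn)) {
    f <- fn[i]; grp <- sch@featureGroup[i]
    v <- vals[i, ]; o <- obs[i, ]
    if (!any(o))
      sepnetStop(sprintf("cannot fit feature '%s': no observed values", f),
                 "sepnetImputationError")
    if (sch@isCategorical[i]) {
      lv <- sch@categoryLevels[[f]]
      catMaps[[f]] <- setNames(seq_along(lv) - 1L, lv)
      tab <- tabulate(v[o] + 1L, nbins = length(lv))
      imputeMode[[f]] <- lv[which.max(tab)]
      code <- v
      code[!o] <- catMaps[[f]][[imputeMode[[f]]]]
      if (config$encoding == "one_hot") {
        for (l in seq_along(lv)) {
          outFeat <- c(outFeat, paste(f, lv[l], sep = "_"))
          outGroup <- c(outGroup, grp)
          outCols[[length(outCols) + 1L]] <- as.numeric(code == l - 1L)
        }
      } else {
        outFeat <- c(outFeat, f); outGroup <- c(outGroup, grp)
        outCols[[length(outCols) + 1L]] <- as.numeric(code)
      }
    } else {
      imputeCenter[f] <- mean(v[o])
      filled <- .imputeRow(v, o, blocks, config$impute[[grp]],
                           imputeCenter[f], f)
      outlierCenter[f] <- mean(filled)
      outlierSpread[f] <- .spread(filled, config$sdConvention)
      if (outlierSpread[f] > 0) {
        ot <- outlierTransform(filled,
                               list(mean = outlierCenter[f],
                                    sd = outlierSpread[f]),
                               config$outlierThreshold, config$outlierPolicy)
        filled <- ot$values
        if (config$outlierPolicy == "remove" && anyNA(filled)) {
          oo <- !is.na(filled)
          filled <- .imputeRow(filled, oo, blocks, config$impute[[grp]],
                               mean(filled[oo]), f)
        }
      }
      outFeat <- c(outFeat, f); outGroup <- c(outGroup, grp)
      outCols[[length(outCols) + 1L]] <- filled
    }
  }

  isEnc <- !(outFeat %in% fn[!sch@isCategorical])
  scaleCenter <- scaleSpread <- scaleMin <- scaleMax <-
    setNames(rep(NA_real_, length(outFeat)), outFeat)
  for (j in seq_along(outFeat)) {
    if (isEnc[j]) next                       # encoded columns pass through
    col <- outCols[[j]]
    scaleCenter[j] <- mean(col)
    scaleSpread[j] <- .spread(col, config$sdConvention)
    scaleMin[j] <- min(col); scaleMax[j] <- max(col)
  }

  methods::new("FittedPreprocessor",
    imputeCenter = imputeCenter, imputeMode = imputeMode,
    outlierCenter = outlierCenter, outlierSpread = outlierSpread,
    scaleCenter = scaleCenter, scaleSpread = scaleSpread,
    scaleMin = scaleMin, scaleMax = scaleMax,
    categoryMaps = catMaps, config = unclass(config),
    inputSchema = sch, outputFeatures = outFeat, outputGroup = outGroup)
}

#' Transform a cohort with fitted preprocessing statistics
#'
#' Applies, in order: imputation (per-patient forward/backward fill for
#' time-varying groups with the training mean as fallback, training mean or
#' modal category otherwise), the fitted outlier policy, categorical
#' encoding, and scaling with the training statistics.  The result has no
#' unobserved entries and a fully numeric schema.
#'
#' @param cohort a [SepsisCohort-class].
#' @param fitted a [FittedPreprocessor-class] from [fitPreprocessor()].
#' @return A [SepsisCohort-class] with expanded numeric features and an
#'   all-`TRUE` measurement mask.
#' @export
transformCohort <- function(cohort, fitted) {
  sch <- fitted@inputSchema
  cfg <- fitted@config
  stopifnot(identical(rownames(cohort), sch@featureNames))
  vals <- cohortValues(cohort); obs <- observedMask(cohort)
  pid <- patientOf(cohort)
  blocks <- split(seq_len(ncol(vals)), factor(pid, levels = unique(pid)))
  fn <- sch@featureNames
  outFeat <- fitted@outputFeatures
  out <- matrix(0, length(outFeat), ncol(vals),
                dimnames = list(outFeat, NULL))
  j <- 1L
  for (i in seq_along(fn)) {
    f <- fn[i]; grp <- sch@featureGroup[i]
    v <- vals[i, ]; o <- obs[i, ]
    if (sch@isCategorical[i]) {
      lv <- sch@categoryLevels[[f]]
      code <- v
      code[!o] <- fitted@categoryMaps[[f]][[fitted@imputeMode[[f]]]]
      if (cfg$encoding == "one_hot") {
        for (l in seq_along(lv)) {
          out[j, ] <- as.numeric(code == l - 1L); j <- j + 1L
        }
      } else {
        out[j, ] <- as.numeric(code); j <- j + 1L
      }
    } else {
      filled <- .imputeRow(v, o, blocks, cfg$impute[[grp]],
                           fitted@imputeCenter[f], f)
      if (fitted@outlierSpread[f] > 0) {
        ot <- outlierTransform(filled,
                               list(mean = fitted@outlierCenter[f],
                                    sd = fitted@outlierSpread[f]),
                               cfg$outlierThreshold, cfg$outlierPolicy)
        filled <- ot$values
        if (cfg$outlierPolicy == "remove" && anyNA(filled)) {
          oo <- !is.na(filled)
          filled <- .imputeRow(filled, oo, blocks, cfg$impute[[grp]],
                               fitted@imputeCenter[f], f)
        }
      }
      sc <- if (cfg$scaling == "zscore")
        zscoreStandardize(filled, list(mean = fitted@scaleCenter[f],
                                       sd = fitted@scaleSpread[f]))
      else
        minmaxScale(filled, list(min = fitted@scaleMin[f],
                                 max = fitted@scaleMax[f]))
      out[j, ] <- sc; j <- j + 1L
    }
  }
  newSchema <- featureSchema(outFeat, fitted@outputGroup,
                             idColumn = sch@idColumn,
                             timeColumn = sch@timeColumn,
                             labelColumn = sch@labelColumn)
  sepsisCohort(out, matrix(TRUE, nrow(out), ncol(out)),
               pid, timeIndex(cohort), sepsisLabels(cohort), newSchema)
}

#' Serialize fitted preprocessing statistics to a text file
#'
#' @param fitted a [FittedPreprocessor-class].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
writePreprocessor <- function(fitted, path) {
  sch <- fitted@inputSchema
  yaml::write_yaml(list(
    imputeCenter = as.list(fitted@imputeCenter),
    imputeMode = fitted@imputeMode,
    outlierCenter = as.list(fitted@outlierCenter),
    outlierSpread = as.list(fitted@outlierSpread),
    scaleCenter = as.list(fitted@scaleCenter),
    scaleSpread = as.list(fitted@scaleSpread),
    scaleMin = as.list(fitted@scaleMin),
    scaleMax = as.list(fitted@scaleMax),
    categoryMaps = lapply(fitted@categoryMaps, as.list),
    config = utils::modifyList(fitted@config,
                               list(impute = as.list(fitted@config$impute))),
    outputFeatures = fitted@outputFeatures,
    outputGroup = fitted@outputGroup,
    schema = list(featureNames = sch@featureNames,
                  featureGroup = sch@featureGroup,
                  categoryLevels = sch@categoryLevels,
                  idColumn = sch@idColumn, timeColumn = sch@timeColumn,
                  labelColumn = sch@labelColumn)), path, precision = 17L)
  invisible(path)
}

#' Read fitted preprocessing statistics back from a text file
#'
#' @param path YAML file written by [writePreprocessor()].
#' @return A [FittedPreprocessor-class] equal to the one serialized.
#' @export
readPreprocessor <- function(path) {
  y <- yaml::read_yaml(path)
  sch <- featureSchema(y$schema$featureNames, y$schema$featureGroup,
                       categoryLevels = lapply(y$schema$categoryLevels,
                                               as.character),
                       idColumn = y$schema$idColumn,
                       timeColumn = y$schema$timeColumn,
                       labelColumn = y$schema$labelColumn)
  num <- function(l) unlist(lapply(l, function(v) if (is.null(v)) NA_real_ else v))
  cfg <- y$config
  cfg$impute <- unlist(cfg$impute)
  methods::new("FittedPreprocessor",
    imputeCenter = num(y$imputeCenter), imputeMode = y$imputeMode,
    outlierCenter = num(y$outlierCenter), outlierSpread = num(y$outlierSpread),
    scaleCenter = num(y$scaleCenter), scaleSpread = num(y$scaleSpread),
    scaleMin = num(y$scaleMin), scaleMax = num(y$scaleMax),
    categoryMaps = lapply(y$categoryMaps, unlist),
    config = cfg, inputSchema = sch,
    outputFeatures = y$outputFeatures, outputGroup = y$outputGroup)
}
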