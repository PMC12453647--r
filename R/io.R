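#' Read a per-patient hourly clinical table into a SepsisCohort
#'
#' Reads a delimited text table (one row = one patient-hour, single header
#' row) in the layout described by a [FeatureSchema-class]: a patient
#' identifier column, an in-stay hour column, feature columns, and a binary
#' per-timestep sepsis label column.  Cells matching a missing token become
#' unobserved in the measurement mask.  Categorical features are stored as
#' 0-based codes in their declared category order.
#'
#' Rows with a duplicated (patient, hour) pair keep the first occurrence
#' with a warning.  Extra columns not named by the schema are ignored.
#'
#' @param path file to read.
#' @param schema a [FeatureSchema-class].
#' @param delimiter field separator; `","` (CSV) and `"|"` (PSV) are the
#'   dialects the source data circulates in.
#' @param missingTokens character values treated as unobserved.
#' @return A [SepsisCohort-class].
#' @export
readCohort <- function(path, schema, delimiter = ",",
                       missingTokens = c("", "NA", "NaN")) {
  if (!file.exists(path))
    sepnetStop(sprintf("file '%s' does not exist", path), "sepnetIOError")
  methods::validObject(schema)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "\"",
                          stringsAsFactors = FALSE)
  need <- c(schema@idColumn, schema@timeColumn, schema@labelColumn,
            schema@featureNames)
  absent <- setdiff(need, colnames(df))
  if (length(absent))
    sepnetStop(sprintf("required column(s) missing from header: %s",
                       paste(absent, collapse = ", ")), "sepnetSchemaError")

  n <- nrow(df)
  pid <- df[[schema@idColumn]]
  tm <- suppressWarnings(as.numeric(df[[schema@timeColumn]]))
  if (n && anyNA(tm))
    sepnetStop(sprintf("non-numeric time value at row %d",
                       which(is.na(tm))[1]), "sepnetValidationError")
  labRaw <- trimws(df[[schema@labelColumn]])
  lab <- suppressWarnings(as.numeric(labRaw))
  bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
  if (length(bad))
    sepnetStop(sprintf("non-binary label value '%s' at row %d",
                       labRaw[bad[1]], bad[1]), "sepnetValidationError")

  nf <- length(schema@featureNames)
  vals <- matrix(NA_real_, nf, n, dimnames = list(schema@featureNames, NULL))
  obs <- matrix(FALSE, nf, n, dimnames = list(schema@featureNames, NULL))
  for (i in seq_len(nf)) {
    f <- schema@featureNames[i]
    raw <- trimws(df[[f]])
    miss <- raw %in% missingTokens
    obs[i, ] <- !miss
    if (schema@isCategorical[i]) {
      lv <- schema@categoryLevels[[f]]
      code <- match(raw, lv) - 1L
      unseen <- which(!miss & is.na(code))
      if (length(unseen))
        sepnetStop(sprintf(
          "unknown category '%s' for feature '%s' at row %d",
          raw[unseen[1]], f, unseen[1]), "sepnetValidationError")
      vals[i, !miss] <- code[!miss]
    } else {
      num <- suppressWarnings(as.numeric(raw))
      badc <- which(!miss & is.na(num))
      if (length(badc))
        sepnetStop(sprintf(
          "non-numeric value '%s' in numeric column '%s' at row %d",
          raw[badc[1]], f, badc[1]), "sepnetValidationError")
      vals[i, !miss] <- num[!miss]
    }
  }

  dup <- duplicated(data.frame(pid, tm))
  if (any(dup)) {
    warning(sprintf("dropping %d duplicate (id, time) row(s); keeping first",
                    sum(dup)))
    keep <- !dup
    vals <- vals[, keep, drop = FALSE]; obs <- obs[, keep, drop = FALSE]
    pid <- pid[keep]; tm <- tm[keep]; lab <- lab[keep]
  }
  sepsisCohort(vals, obs, pid, tm, as.integer(lab), schema)
}

#' Write a SepsisCohort back to a delimited table
#'
#' Inverse of [readCohort()]: one row per patient-hour, header row, empty
#' cells for unobserved entries, categorical codes decoded back to their
#' declared category names.  `readCohort(writeCohort(x))` reproduces `x` up
#' to numeric formatting (masks, labels, ids and times round-trip exactly).
#'
#' @param cohort a [SepsisCohort-class].
#' @param path output file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, delimiter = ",") {
  sch <- cohortSchema(cohort)
  vals <- cohortValues(cohort); obs <- observedMask(cohort)
  out <- data.frame(row.names = seq_len(ncol(cohort)))
  out[[sch@idColumn]] <- patientOf(cohort)
  out[[sch@timeColumn]] <- format(timeIndex(cohort), trim = TRUE, digits = 15)
  for (i in seq_along(sch@featureNames)) {
    f <- sch@featureNames[i]
    v <- vals[i, ]
    cell <- rep("", length(v))
    if (sch@isCategorical[i]) {
      lv <- sch@categoryLevels[[f]]
      cell[obs[i, ]] <- lv[v[obs[i, ]] + 1L]
    } else {
      cell[obs[i, ]] <- format(v[obs[i, ]], trim = TRUE, digits = 15)
    }
    out[[f]] <- cell
  }
  out[[sch@labelColumn]] <- sepsisLabels(cohort)
  ok <- tryCatch({
    utils::write.table(out, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    sepnetStop(sprintf("cannot write '%s': %s", path,
                       conditionMessage(ok)), "sepnetIOError")
  invisible(path)
}

## Recognised configuration keys and the bundle section they feed.
.configKeys <- list(
  learning_rate = "train", batch_size = "train", max_epochs = "train",
  patience = "train", threshold = "train", pos_weight = "train",
  seed = "train",
  dropout = "model", window = "model", features = "model",
  kernel_sizes = "model", dilation_rates = "model",
  entry_filters = "model", branch_filters = "model", hdcb_filters = "model",
  fuse_filters = "model", rpcc_filters = "model", residual_blocks = "model",
  dense_units = "model", bn_form = "model", hdcb_fusion = "model",
  spatial_kernel = "model", channel_bottleneck = "model"
)

#' Load a validated configuration bundle
#'
#' Reads a flat `key: value` text file (YAML syntax, documented keys only)
#' and returns model and training configurations with unstated keys filled
#' from the defaults (learning rate 0.001, batch size 128, dropout 0.5, at
#' most 100 epochs).  Unknown keys are rejected by name.
#'
#' @param path config file; missing/`NULL` gives all defaults.
#' @return A list with elements `model` (see [modelConfig()]) and `train`
#'   (see [trainConfig()]).
#' @export
loadConfig <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.configKeys))
  if (length(unknown))
    sepnetStop(sprintf("unknown configuration key(s): %s",
                       paste(unknown, collapse = ", ")), "sepnetConfigError")
  sect <- unlist(.configKeys[names(raw)])
  args <- split(raw, factor(sect, levels = c("model", "train")))
  modelArgs <- as.list(args[["model"]])
  trainArgs <- as.list(args[["train"]])
  names(trainArgs)[names(trainArgs) == "learning_rate"] <- "lr"
  if (is.null(modelArgs$features)) modelArgs$features <- 14L
  list(model = do.call(modelConfig, modelArgs),
       train = do.call(trainConfig, trainArgs))
}

#' Write a metrics report to CSV and a structured key-value file
#'
#' @param report a [MetricsReport-class].
#' @param path base path; writes `<path>.csv` (one row per metric) and
#'   `<path>.yaml`.
#' @return The two paths, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  m <- report@metrics
  df <- data.frame(metric = names(m), value = unname(m))
  cnt <- report@counts
  csv <- paste0(path, ".csv"); yml <- paste0(path, ".yaml")
  utils::write.table(df, csv, sep = ",", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(c(as.list(m),
                     list(tp = cnt@tp, fp = cnt@fp, tn = cnt@tn, fn = cnt@fn)),
                   yml)
  invisible(c(csv, yml))
}
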