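#' @import methods
#' @importFrom stats rnorm runif rbinom sd quantile setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @useDynLib sepnet, .registration = TRUE
NULL

## Error helper: classed conditions so callers can distinguish schema,
## validation and imputation failures.
sepnetStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sepnetError", "error")))
}

#' Feature schema for a clinical cohort
#'
#' Describes the column layout of an hourly per-patient clinical table:
#' which columns are features, how each feature is grouped (vital sign,
#' laboratory value, or demographic), which features are categorical with
#' which declared category order, and which columns hold the patient
#' identifier, the in-stay hour, and the per-timestep sepsis label.
#'
#' @slot featureNames character vector of unique feature column names.
#' @slot featureGroup character vector, one of `"vital"`, `"lab"`,
#'   `"demographic"` per feature.
#' @slot isCategorical logical vector per feature.
#' @slot categoryLevels named list mapping each categorical feature to its
#'   declared category order (at least two categories).
#' @slot idColumn,timeColumn,labelColumn single column names for the patient
#'   identifier, the in-stay hour and the binary sepsis label.
#' @export
setClass("FeatureSchema",
  representation(
    featureNames  = "character",
    featureGroup  = "character",
    isCategorical = "logical",
    categoryLevels = "list",
    idColumn      = "character",
    timeColumn    = "character",
    labelColumn   = "character"
  )
)

setValidity("FeatureSchema", function(object) {
  fn <- object@featureNames
  if (anyDuplicated(fn)) return("feature names must be unique")
  if (length(object@featureGroup) != length(fn))
    return("featureGroup length must match featureNames")
  if (!all(object@featureGroup %in% c("vital", "lab", "demographic")))
    return("featureGroup values must be 'vital', 'lab' or 'demographic'")
  if (length(object@isCategorical) != length(fn))
    return("isCategorical length must match featureNames")
  catf <- fn[object@isCategorical]
  if (!all(catf %in% names(object@categoryLevels)))
    return("every categorical feature needs declared categoryLevels")
  for (f in catf) {
    lv <- object@categoryLevels[[f]]
    if (length(lv) < 2L || anyDuplicated(lv))
      return(sprintf("categorical feature '%s' needs >= 2 distinct categories", f))
  }
  meta <- c(object@idColumn, object@timeColumn, object@labelColumn)
  if (length(meta) != 3L || any(!nzchar(meta)))
    return("idColumn, timeColumn and labelColumn must be single non-empty names")
  if (any(meta %in% fn))
    return("id, time and label columns must not be feature columns")
  TRUE
})

#' Construct a FeatureSchema
#'
#' @param featureNames character vector of feature column names.
#' @param featureGroup character vector of groups (`"vital"`, `"lab"`,
#'   `"demographic"`), recycled if length one.
#' @param categoryLevels named list of declared category orders; features
#'   named here are treated as categorical.
#' @param idColumn,timeColumn,labelColumn metadata column names.
#' @return A [FeatureSchema-class] object.
#' @examples
#' featureSchema(c("HR", "Temp"), c("vital", "vital"))
#' @export
featureSchema <- function(featureNames, featureGroup,
                          categoryLevels = list(),
                          idColumn = "Patient_ID", timeColumn = "ICULOS",
                          labelColumn = "SepsisLabel") {
  if (length(featureGroup) == 1L)
    featureGroup <- rep(featureGroup, length(featureNames))
  new("FeatureSchema",
      featureNames = as.character(featureNames),
      featureGroup = as.character(featureGroup),
      isCategorical = featureNames %in% names(categoryLevels),
      categoryLevels = categoryLevels,
      idColumn = idColumn, timeColumn = timeColumn, labelColumn = labelColumn)
}

#' Default synthetic cohort schema
#'
#' Thirteen clinically named features: seven hourly vital signs (HR, O2Sat,
#' Temp, SBP, MAP, DBP, Resp), four sparsely sampled laboratory values (WBC,
#' Lactate, Creatinine, Platelets), and two demographics (Age, and Gender as
#' a categorical with declared order Male, Female).
#'
#' @return A [FeatureSchema-class].
#' @export
defaultSchema <- function() {
  featureSchema(
    featureNames = c("HR", "O2Sat", "Temp", "SBP", "MAP", "DBP", "Resp",
                     "WBC", "Lactate", "Creatinine", "Platelets",
                     "Age", "Gender"),
    featureGroup = c(rep("vital", 7), rep("lab", 4), rep("demographic", 2)),
    categoryLevels = list(Gender = c("Male", "Female"))
  )
}

#' Cohort of per-patient hourly clinical records
#'
#' A `SepsisCohort` is a [SummarizedExperiment::SummarizedExperiment] whose
#' rows are clinical features and whose columns are patient-hour records,
#' ordered by patient and strictly increasing in-stay hour within patient.
#' Two assays are carried: `values` (observed magnitudes; unobserved cells
#' are `NA`) and `observed` (logical measurement mask).  `colData` holds the
#' patient identifier, the in-stay hour and the binary per-timestep sepsis
#' label; `metadata(x)$schema` holds the [FeatureSchema-class].
#'
#' @export
setClass("SepsisCohort", contains = "SummarizedExperiment")

setValidity("SepsisCohort", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("values", "observed") %in% a))
    return("assays 'values' and 'observed' are required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("patient_id", "time", "label") %in% colnames(cd)))
    return("colData must have patient_id, time and label")
  lab <- cd$label
  if (length(lab) && !all(lab %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  obs <- SummarizedExperiment::assay(object, "observed")
  if (!is.logical(obs))
    return("'observed' assay must be logical")
  sch <- S4Vectors::metadata(object)$schema
  if (is.null(sch) || !methods::is(sch, "FeatureSchema"))
    return("metadata(x)$schema must be a FeatureSchema")
  if (!identical(rownames(object), sch@featureNames))
    return("rownames must equal the schema's feature names")
  pid <- as.character(cd$patient_id)
  if (length(pid)) {
    ## records of one patient must be contiguous and strictly increasing in time
    r <- rle(pid)
    if (anyDuplicated(r$values))
      return("records of a patient must be contiguous")
    tt <- split(cd$time, factor(pid, levels = r$values))
    bad <- vapply(tt, function(v) any(diff(v) <= 0), logical(1))
    if (any(bad))
      return(sprintf("times must be strictly increasing within patient (e.g. '%s')",
                     names(tt)[bad][1]))
  }
  TRUE
})

#' Fitted preprocessing statistics
#'
#' Per-feature imputation, outlier and scaling statistics learned from the
#' training split only, together with category-to-index maps for categorical
#' features and the configuration they were fitted under.  Applying
#' [transformCohort()] with a `FittedPreprocessor` guarantees the training
#' statistics are reused on validation and test data.
#'
#' @slot imputeCenter named numeric; per-feature mean of observed training
#'   values (fallback fill for patients with no observations).
#' @slot imputeMode named list; per-categorical modal category.
#' @slot outlierCenter,outlierSpread named numerics (mean and population or
#'   sample standard deviation) driving the z-score outlier rule.
#' @slot scaleCenter,scaleSpread,scaleMin,scaleMax named numerics over output
#'   (encoded) numeric features used by z-score or min-max scaling.
#' @slot categoryMaps named list of category -> 0-based index maps.
#' @slot config the preprocessing configuration list.
#' @slot inputSchema the [FeatureSchema-class] of the raw cohort.
#' @slot outputFeatures,outputGroup character vectors describing the encoded
#'   output columns.
#' @export
setClass("FittedPreprocessor",
  representation(
    imputeCenter  = "numeric",
    imputeMode    = "list",
    outlierCenter = "numeric",
    outlierSpread = "numeric",
    scaleCenter   = "numeric",
    scaleSpread   = "numeric",
    scaleMin      = "numeric",
    scaleMax      = "numeric",
    categoryMaps  = "list",
    config        = "list",
    inputSchema   = "FeatureSchema",
    outputFeatures = "character",
    outputGroup   = "character"
  )
)

setValidity("FittedPreprocessor", function(object) {
  if (any(object@scaleSpread < 0, na.rm = TRUE)) return("sigma must be >= 0")
  if (any(object@scaleMin > object@scaleMax, na.rm = TRUE))
    return("min must be <= max")
  TRUE
})

#' Binary confusion counts
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4L || any(v < 0L)) return("counts must be non-negative scalars")
  TRUE
})

#' Classification metrics report
#'
#' Accuracy, precision, recall, F1, specificity, false positive rate and
#' false negative rate, all in percent (full precision retained; display is
#' rounded to one decimal), plus AUC in [0, 1] and the underlying
#' [ConfusionCounts-class].  Undefined ratios are `NA` with a warning at
#' construction, never silently zero.
#'
#' @slot metrics named numeric vector (percent scale except `auc`).
#' @slot counts the [ConfusionCounts-class] behind the report.
#' @export
setClass("MetricsReport",
  representation(metrics = "numeric", counts = "ConfusionCounts"))

setMethod("show", "FeatureSchema", function(object) {
  cat(sprintf("FeatureSchema: %d features (%d vital, %d lab, %d demographic)\n",
              length(object@featureNames),
              sum(object@featureGroup == "vital"),
              sum(object@featureGroup == "lab"),
              sum(object@featureGroup == "demographic")))
  cat("  id/time/label:", object@idColumn, object@timeColumn,
      object@labelColumn, "\n")
  if (any(object@isCategorical))
    cat("  categorical:",
        paste(object@featureNames[object@isCategorical], collapse = ", "), "\n")
})

setMethod("show", "SepsisCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  np <- length(unique(cd$patient_id))
  prev <- if (ncol(object)) mean(cd$label) else NA_real_
  cat(sprintf("SepsisCohort: %d features x %d records, %d patients\n",
              nrow(object), ncol(object), np))
  cat(sprintf("  timestep prevalence: %.3f%%; observed cells: %.1f%%\n",
              100 * prev,
              100 * mean(SummarizedExperiment::assay(object, "observed"))))
})

setMethod("show", "ConfusionCounts", function(object) {
  m <- matrix(c(object@tn, object@fp, object@fn, object@tp), 2, 2, byrow = TRUE,
              dimnames = list(c("true 0", "true 1"), c("pred 0", "pred 1")))
  cat("ConfusionCounts\n"); print(m)
})

setMethod("show", "MetricsReport", function(object) {
  m <- object@metrics
  cat("MetricsReport\n")
  for (k in names(m)) {
    if (k == "auc") cat(sprintf("  %-12s %.3f\n", "AUC", m[[k]]))
    else cat(sprintf("  %-12s %.1f%%\n", k, m[[k]]))
  }
})
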