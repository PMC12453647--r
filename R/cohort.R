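#' Construct a SepsisCohort from record-level matrices
#'
#' @param values numeric matrix, features x records (unobserved cells `NA`).
#' @param observed logical matrix of the same shape (`TRUE` = measured).
#' @param patientId character/record patient identifiers.
#' @param time numeric in-stay hours per record.
#' @param label integer 0/1 sepsis label per record.
#' @param schema a [FeatureSchema-class] whose features match `rownames(values)`.
#' @return A [SepsisCohort-class].  Records are reordered by patient (first
#'   appearance) and time.
#' @export
sepsisCohort <- function(values, observed, patientId, time, label, schema) {
  methods::validObject(schema)
  patientId <- as.character(patientId)
  if (is.null(rownames(values))) rownames(values) <- schema@featureNames
  ord <- order(match(patientId, unique(patientId)), time)
  values <- values[, ord, drop = FALSE]
  observed <- observed[, ord, drop = FALSE]
  rownames(observed) <- rownames(values)
  cd <- S4Vectors::DataFrame(patient_id = patientId[ord],
                             time = as.numeric(time)[ord],
                             label = as.integer(label)[ord])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values, observed = observed),
    colData = cd, metadata = list(schema = schema))
  methods::new("SepsisCohort", se)
}

#' @describeIn sepsisCohort Schema accessor.
#' @param x a [SepsisCohort-class].
#' @export
cohortSchema <- function(x) S4Vectors::metadata(x)$schema

#' @describeIn sepsisCohort Unique patient identifiers, in record order.
#' @export
patientIds <- function(x) unique(SummarizedExperiment::colData(x)$patient_id)

#' @describeIn sepsisCohort Number of distinct patients.
#' @export
nPatients <- function(x) length(patientIds(x))

#' @describeIn sepsisCohort Feature x record value matrix.
#' @export
cohortValues <- function(x) SummarizedExperiment::assay(x, "values")

#' @describeIn sepsisCohort Logical measurement mask.
#' @export
observedMask <- function(x) SummarizedExperiment::assay(x, "observed")

#' @describeIn sepsisCohort Per-record patient identifiers.
#' @export
patientOf <- function(x) SummarizedExperiment::colData(x)$patient_id

#' @describeIn sepsisCohort Per-record in-stay hours.
#' @export
timeIndex <- function(x) SummarizedExperiment::colData(x)$time

#' @describeIn sepsisCohort Per-record 0/1 sepsis labels.
#' @export
sepsisLabels <- function(x) SummarizedExperiment::colData(x)$label

#' Extract one patient's record
#'
#' @param x a [SepsisCohort-class].
#' @param id a patient identifier present in the cohort.
#' @return A list with `patient_id`, `times`, `values` (timesteps x
#'   features), `observed` (same shape) and `labels`, i.e. the per-patient
#'   view of the cohort with time running down the rows.
#' @export
getPatientRecord <- function(x, id) {
  sel <- patientOf(x) == id
  if (!any(sel)) sepnetStop(sprintf("no patient '%s' in cohort", id),
                            "sepnetValidationError")
  list(patient_id = id,
       times = timeIndex(x)[sel],
       values = t(cohortValues(x)[, sel, drop = FALSE]),
       observed = t(observedMask(x)[, sel, drop = FALSE]),
       labels = sepsisLabels(x)[sel])
}

#' Subset a cohort to a set of patients
#'
#' @param x a [SepsisCohort-class].
#' @param ids patient identifiers to keep.
#' @return A [SepsisCohort-class] with only those patients' records.
#' @export
subsetPatients <- function(x, ids) {
  keep <- patientOf(x) %in% ids
  methods::new("SepsisCohort", methods::as(x, "SummarizedExperiment")[, keep])
}
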