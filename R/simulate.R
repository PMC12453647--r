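## Synthetic sepsis cohort simulator.
##
## Emulates the structure of hourly ICU tables: autocorrelated vital signs,
## sparsely observed labs, static demographics, a per-patient sepsis onset
## with a linear pre-onset physiological drift, and a per-timestep label
## that switches to 1 at onset and stays 1 until discharge.  All baselines
## and drift magnitudes are package defaults chosen to make the task
## learnable but not trivial; they are configuration, not estimates.

.defaultBaselines <- function() {
  data.frame(
    feature = c("HR", "O2Sat", "Temp", "SBP", "MAP", "DBP", "Resp",
                "WBC", "Lactate", "Creatinine", "Platelets", "Age"),
    mean = c(85, 97, 36.8, 120, 82, 65, 18, 8, 1.2, 1.0, 250, 62),
    sd   = c(10, 2, 0.4, 12, 8, 8, 3, 2, 0.4, 0.3, 50, 15),
    stringsAsFactors = FALSE)
}

.defaultDrifts <- function() {
  c(HR = 20, Temp = 1.2, Resp = 8, MAP = -15, WBC = 6, Lactate = 2.5)
}

## Expected number of post-onset (label 1) hours per septic patient under
## stay length L ~ U{stayRange} and onset ~ U{floor(L/2)+1, ..., L}.
.expectedPositives <- function(stayRange) {
  L <- seq(stayRange[1], stayRange[2])
  mean((L - floor(L / 2) + 1) / 2)
}

#' Simulation configuration for synthetic sepsis cohorts
#'
#' @param nPatients number of patients to simulate.
#' @param stayRange integer range of stay lengths in hours (uniform),
#'   default 8 to 60.
#' @param prevalenceTarget target fraction of sepsis-positive timesteps;
#'   default 27916/1552210 (about 1.8%).  The patient-level sepsis
#'   probability is derived from it and the stay-length distribution.
#' @param sepsisProb patient-level sepsis probability; `NULL` (default)
#'   derives it from `prevalenceTarget`.
#' @param rho AR(1) autocorrelation of the hourly physiology, in [0, 1).
#' @param baselines data frame with columns `feature`, `mean`, `sd`.
#' @param driftWindow hours of linear pre-onset drift, default 12.
#' @param drifts named numeric drift magnitudes reached at onset (and held
#'   afterwards); defaults HR +20, Temp +1.2, Resp +8, MAP -15, WBC +6,
#'   Lactate +2.5.
#' @param labMissing,vitalMissing per-cell missingness rates for lab and
#'   vital features (demographics are always observed).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(nPatients = 100, stayRange = c(8L, 60L),
                      prevalenceTarget = 27916 / 1552210,
                      sepsisProb = NULL, rho = 0.9,
                      baselines = .defaultBaselines(),
                      driftWindow = 12, drifts = .defaultDrifts(),
                      labMissing = 0.85, vitalMissing = 0.05, seed = 1L) {
  if (is.null(sepsisProb)) {
    meanStay <- mean(seq(stayRange[1], stayRange[2]))
    sepsisProb <- prevalenceTarget * meanStay / .expectedPositives(stayRange)
  }
  cfg <- structure(list(
    nPatients = as.integer(nPatients), stayRange = as.integer(stayRange),
    prevalenceTarget = prevalenceTarget, sepsisProb = sepsisProb,
    rho = rho, baselines = baselines, driftWindow = driftWindow,
    drifts = drifts, labMissing = labMissing, vitalMissing = vitalMissing,
    seed = as.integer(seed)), class = "simConfig")
  ok <- cfg$nPatients >= 1 && all(cfg$stayRange >= 2) &&
    cfg$stayRange[1] <= cfg$stayRange[2] &&
    cfg$sepsisProb >= 0 && cfg$sepsisProb <= 1 &&
    cfg$rho >= 0 && cfg$rho < 1 &&
    cfg$labMissing >= 0 && cfg$labMissing <= 1 &&
    cfg$vitalMissing >= 0 && cfg$vitalMissing <= 1 && cfg$driftWindow >= 1
  if (!ok) sepnetStop("invalid simulation configuration", "sepnetConfigError")
  cfg
}

#' Simulate a synthetic sepsis cohort
#'
#' Per patient, each physiological feature follows a stationary AR(1)
#' process `x_t = mu + rho (x_{t-1} - mu) + noise` around its baseline (the
#' innovation variance is set so the stationary standard deviation equals
#' the configured `sd`).  Septic patients draw an onset hour uniformly in
#' the second half of the stay, receive a linear drift over the
#' `driftWindow` hours before onset (held at full magnitude from onset to
#' discharge), and labels that are 0 before onset and 1 afterwards.  The
#' measurement mask is Bernoulli per cell at the configured missingness
#' rates; demographics are static and always observed.
#'
#' @param config a [simConfig()].
#' @return A [SepsisCohort-class] using [defaultSchema()].
#' @export
simulateCohort <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  sch <- defaultSchema()
  bl <- config$baselines
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  n <- config$nPatients
  stayChoices <- seq(config$stayRange[1], config$stayRange[2])
  stays <- stayChoices[sample.int(length(stayChoices), n, replace = TRUE)]
  septic <- stats::runif(n) < config$sepsisProb
  total <- sum(stays)
  fn <- sch@featureNames
  nf <- length(fn)
  vals <- matrix(NA_real_, nf, total, dimnames = list(fn, NULL))
  obs <- matrix(TRUE, nf, total, dimnames = list(fn, NULL))
  labs <- integer(total)
  pid <- character(total); tim <- numeric(total)

  dyn <- bl$feature                     # AR(1) features (vitals + labs)
  grpOf <- setNames(sch@featureGroup, fn)
  pos <- 0L
  ids <- sprintf("P%05d", seq_len(n))
  for (p in seq_len(n)) {
    L <- stays[p]
    idx <- pos + seq_len(L)
    pos <- pos + L
    pid[idx] <- ids[p]
    tim[idx] <- seq_len(L)
    onset <- NA_integer_
    if (septic[p]) {
      oc <- seq(floor(L / 2) + 1L, L)
      onset <- oc[sample.int(length(oc), 1L)]
      labs[idx[onset:L]] <- 1L
    }
    for (r in seq_len(nrow(bl))) {
      f <- bl$feature[r]
      if (f == "Age") next
      mu <- rep(bl$mean[r], L)
      if (!is.na(onset) && !is.null(config$drifts[f]) &&
          !is.na(config$drifts[f])) {
        d <- config$drifts[[f]]
        w <- config$driftWindow
        t0 <- onset - w                  # drift starts here (may be < 1)
        ramp <- pmin(pmax((seq_len(L) - t0) / w, 0), 1)
        mu <- mu + d * ramp
      }
      innovSd <- bl$sd[r] * sqrt(1 - config$rho^2)
      e <- stats::rnorm(L, 0, innovSd)
      x <- as.numeric(stats::filter(e, config$rho, method = "recursive",
                                    init = stats::rnorm(1, 0, bl$sd[r])))
      vals[f, idx] <- mu + x
      g <- grpOf[[f]]
      mrate <- if (g == "lab") config$labMissing else config$vitalMissing
      if (mrate > 0) obs[f, idx] <- stats::runif(L) >= mrate
    }
    vals["Age", idx] <- round(stats::rnorm(1, bl$mean[bl$feature == "Age"],
                                           bl$sd[bl$feature == "Age"]))
    vals["Gender", idx] <- stats::rbinom(1, 1, 0.45)  # 0 = Male, 1 = Female
  }
  vals[!obs] <- NA_real_
  sepsisCohort(vals, obs, pid, tim, labs, sch)
}

#' Simulate a cohort shaped like the full study population
#'
#' At `scaleFraction = 1` the expected cohort matches the study scale:
#' about 1,552,210 patient-hour records from 40,336 patients with 27,916
#' positive timesteps.  Stay lengths are drawn uniform 8-69 h so the mean
#' stay matches the records-per-patient ratio of that population.
#'
#' @param scaleFraction fraction of the full population size, in (0, 1].
#' @param seed integer RNG seed.
#' @return A list with `cohort` (a [SepsisCohort-class]) and `report`
#'   (realized and expected record/positive counts).
#' @export
simulatePaperScale <- function(scaleFraction, seed = 1L) {
  if (!is.numeric(scaleFraction) || length(scaleFraction) != 1L ||
      scaleFraction <= 0 || scaleFraction > 1)
    sepnetStop("scaleFraction must be in (0, 1]", "sepnetConfigError")
  totalRecords <- 1552210; totalPatients <- 40336; totalPositives <- 27916
  cfg <- simConfig(nPatients = max(1L, round(scaleFraction * totalPatients)),
                   stayRange = c(8L, 69L),
                   prevalenceTarget = totalPositives / totalRecords,
                   seed = seed)
  cohort <- simulateCohort(cfg)
  list(cohort = cohort,
       report = list(
         n_records = ncol(cohort),
         n_positive = sum(sepsisLabels(cohort)),
         n_patients = nPatients(cohort),
         expected_records = scaleFraction * totalRecords,
         expected_positive = scaleFraction * totalPositives))
}

#' Effect-size summary of the planted pre-onset signal
#'
#' For every feature, the standardized mean difference (SMD) between
#' observed values in the pre-onset drift windows of septic patients and
#' observed values from non-septic patients' stays, using the pooled
#' standard deviation.  Used to verify that the planted physiological drift
#' actually separates the classes before any model is trained.
#'
#' @param cohort a [SepsisCohort-class] with labels.
#' @param window hours before onset to treat as the septic window
#'   (default 12, the default drift window).
#' @return A data frame with one row per feature: group means, pooled sd,
#'   `smd` and the sample sizes.
#' @export
separabilityReport <- function(cohort, window = 12) {
  sch <- cohortSchema(cohort)
  vals <- cohortValues(cohort); obs <- observedMask(cohort)
  pid <- patientOf(cohort); lab <- sepsisLabels(cohort)
  blocks <- split(seq_len(ncol(cohort)), factor(pid, levels = unique(pid)))
  septicSel <- logical(ncol(cohort)); controlSel <- logical(ncol(cohort))
  for (b in blocks) {
    onset <- which(lab[b] == 1L)[1]
    if (is.na(onset)) controlSel[b] <- TRUE
    else {
      w <- b[seq(max(1L, onset - window), max(1L, onset - 1L))]
      if (onset > 1L) septicSel[w] <- TRUE
    }
  }
  out <- lapply(seq_along(sch@featureNames), function(i) {
    s <- vals[i, septicSel & obs[i, ]]
    c0 <- vals[i, controlSel & obs[i, ]]
    if (length(s) < 2 || length(c0) < 2)
      return(data.frame(feature = sch@featureNames[i], meanSeptic = NA,
                        meanControl = NA, pooledSd = NA, smd = NA,
                        nSeptic = length(s), nControl = length(c0)))
    sp <- sqrt(((length(s) - 1) * stats::var(s) +
                (length(c0) - 1) * stats::var(c0)) /
               (length(s) + length(c0) - 2))
    data.frame(feature = sch@featureNames[i], meanSeptic = mean(s),
               meanControl = mean(c0), pooledSd = sp,
               smd = if (sp > 0) (mean(s) - mean(c0)) / sp else 0,
               nSeptic = length(s), nControl = length(c0))
  })
  do.call(rbind, out)
}
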