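test_that("mean imputation fills gaps with the observed mean only", {
  expect_equal(imputeMean(c(1, NA, 3)), c(1, 2, 3))
  x <- c(2.5, 3.5, 4.5)
  expect_identical(imputeMean(x), x)
  expect_error(imputeMean(c(NA_real_, NA_real_), feature = "WBC"),
               "WBC", class = "sepnetImputationError")
})

test_that("time-series imputation forward-fills and back-fills leading gaps", {
  expect_equal(imputeTimeSeries(c(5, NA, NA, 7)), c(5, 5, 5, 7))
  expect_equal(imputeTimeSeries(c(NA, 4)), c(4, 4))
  expect_equal(imputeTimeSeries(c(NA, NA, 2, NA)), c(2, 2, 2, 2))
  x <- c(1, 2, 3)
  expect_identical(imputeTimeSeries(x), x)
  expect_error(imputeTimeSeries(c(NA_real_, NA_real_)),
               class = "sepnetImputationError")
})

test_that("min-max scaling honours fitted bounds and the constant convention", {
  f <- list(min = 0, max = 10)
  expect_equal(minmaxScale(c(0, 5, 10), f), c(0, 0.5, 1))
  expect_equal(minmaxScale(c(7, 7), list(min = 7, max = 7)), c(0, 0))
  ## held-out values may leave [0, 1]
  expect_equal(minmaxScale(12, f), 1.2)
})

test_that("z-score standardization matches hand arithmetic", {
  ## population sigma of (2, 4, 6): sqrt(8/3)
  f <- list(mean = 4, sd = sqrt(8 / 3))
  got <- zscoreStandardize(c(2, 4, 6), f)
  expect_equal(got, c(-1.224744871391589, 0, 1.224744871391589),
               tolerance = 1e-12)
  z <- c(-1.2, 0.3, 0.9)
  expect_equal(zscoreStandardize(z, list(mean = 0, sd = 1)), z,
               tolerance = 1e-9)
  expect_equal(zscoreStandardize(c(5, 5), list(mean = 5, sd = 0)), c(0, 0))
})

test_that("one-hot and label encoding follow the declared order", {
  ord <- c("Male", "Female", "Other")
  expect_equal(unname(oneHotEncode("Male", ord)), c(1, 0, 0))
  expect_equal(unname(oneHotEncode("Other", ord)), c(0, 0, 1))
  expect_error(oneHotEncode("Unknown", ord), class = "sepnetEncodingError")
  expect_warning(v <- oneHotEncode("Unknown", ord, strict = FALSE))
  expect_equal(unname(v), c(0, 0, 0))
  ## strict one-hot vectors sum to exactly 1
  m <- oneHotEncode(c("Female", "Male", "Other", "Female"), ord)
  expect_equal(unname(rowSums(m)), rep(1, 4))

  expect_equal(labelEncode("Male", ord), 0L)
  expect_equal(labelEncode("Female", ord), 1L)
  expect_equal(labelEncode("Other", ord), 2L)
  expect_equal(labelEncode("Solo", "Solo"), 0L)
  expect_error(labelEncode("Unknown", ord), class = "sepnetEncodingError")
})

test_that("outlier handling caps, removes or flags beyond the z threshold", {
  f <- list(mean = 0, sd = 1)
  capd <- outlierTransform(c(0, 5, -4), f, 3, "cap")
  expect_equal(capd$values, c(0, 3, -3))
  expect_equal(capd$flags, c(FALSE, TRUE, TRUE))
  ## all inside threshold: identity, no flags
  ok <- outlierTransform(c(-2.9, 0, 2.9), f, 3, "cap")
  expect_equal(ok$values, c(-2.9, 0, 2.9))
  expect_false(any(ok$flags))
  rem <- outlierTransform(c(0, 5), f, 3, "remove")
  expect_true(is.na(rem$values[2]))
  flg <- outlierTransform(c(0, 5), f, 3, "flag")
  expect_equal(flg$values, c(0, 5))
  expect_true(flg$flags[2])
  ## capping never increases |Z|
  set.seed(1)
  x <- rnorm(500, 0, 2)
  capped <- outlierTransform(x, f, 3, "cap")$values
  expect_lte(max(abs(capped - f$mean) / f$sd), 3 + 1e-9)
})

test_that("transform uses training statistics on held-out data", {
  ## plant a distribution shift: validation HR is much higher, so using
  ## validation's own statistics would re-centre it near zero
  sch <- featureSchema("HR", "vital")
  mk <- function(vals, ids) {
    sepsisCohort(matrix(vals, 1, dimnames = list("HR", NULL)),
                 matrix(TRUE, 1, length(vals)),
                 rep(ids, each = length(vals) / length(ids)),
                 rep(seq_len(length(vals) / length(ids)), length(ids)),
                 integer(length(vals)), sch)
  }
  train <- mk(c(78, 80, 82, 84, 79, 81, 83, 85), c("A", "B"))
  val <- mk(c(118, 120, 122, 124), "C")
  fit <- fitPreprocessor(train)
  valT <- transformCohort(val, fit)
  ## under train statistics the shifted validation is a flagrant outlier and
  ## is capped at the +3 SD boundary; with its own statistics it would sit
  ## near zero
  expect_equal(mean(cohortValues(valT)["HR", ]), 3, tolerance = 1e-6)
  trainT <- transformCohort(train, fit)
  expect_equal(mean(cohortValues(trainT)["HR", ]), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(cohortValues(trainT)["HR", ]^2)), 1,
               tolerance = 1e-9)
})

test_that("fit/transform pipeline leaves no missing values and is deterministic", {
  co <- simulateCohort(simConfig(nPatients = 25, seed = 3))
  fit <- fitPreprocessor(co)
  t1 <- transformCohort(co, fit)
  t2 <- transformCohort(co, fit)
  expect_false(anyNA(cohortValues(t1)))
  expect_identical(cohortValues(t1), cohortValues(t2))
  expect_true(all(observedMask(t1)))
  ## labs are ~85% missing yet fully observed after transform
  expect_gt(mean(!observedMask(co)["WBC", ]), 0.5)
  ## z-scored training output satisfies the moment contract per feature
  v <- cohortValues(t1)
  numeric_rows <- setdiff(rownames(v), c("Gender_Male", "Gender_Female"))
  for (f in numeric_rows) {
    expect_equal(mean(v[f, ]), 0, tolerance = 1e-9)
    sdv <- sqrt(mean(v[f, ]^2))
    expect_true(abs(sdv - 1) < 1e-9 || sdv == 0)
  }
})

test_that("re-fitting on z-scored training output recovers mean 0, sd 1", {
  co <- simulateCohort(simConfig(nPatients = 20, seed = 8))
  fit <- fitPreprocessor(co)
  tc <- transformCohort(co, fit)
  fit2 <- fitPreprocessor(tc, preprocessConfig(outlierThreshold = 100))
  ## one-hot indicator columns are numeric features on the second pass and
  ## legitimately have non-zero means; the refit contract concerns the
  ## z-scored clinical features
  num <- !is.na(fit2@scaleCenter) &
    !startsWith(names(fit2@scaleCenter), "Gender")
  expect_lt(max(abs(fit2@scaleCenter[num])), 1e-9)
  sds <- fit2@scaleSpread[num]
  expect_true(all(abs(sds - 1) < 1e-6 | sds == 0))
})

test_that("the remove policy composes with re-imputation in the pipeline", {
  sch <- featureSchema("HR", "vital")
  vals <- matrix(c(80, 81, 500, 82, 83), 1, dimnames = list("HR", NULL))
  co <- sepsisCohort(vals, matrix(TRUE, 1, 5), rep("A", 5), 1:5,
                     integer(5), sch)
  fit <- fitPreprocessor(co, preprocessConfig(outlierPolicy = "remove",
                                              outlierThreshold = 1.5))
  tc <- transformCohort(co, fit)
  expect_false(anyNA(cohortValues(tc)))
})

test_that("fitted statistics survive a serialization round trip", {
  co <- simulateCohort(simConfig(nPatients = 10, seed = 12))
  fit <- fitPreprocessor(co)
  p <- tempfile(fileext = ".yaml")
  writePreprocessor(fit, p)
  back <- readPreprocessor(p)
  expect_equal(back@scaleCenter, fit@scaleCenter, tolerance = 1e-12)
  expect_equal(back@scaleSpread, fit@scaleSpread, tolerance = 1e-12)
  expect_equal(back@imputeCenter, fit@imputeCenter, tolerance = 1e-12)
  t1 <- transformCohort(co, fit)
  t2 <- transformCohort(co, back)
  expect_equal(cohortValues(t1), cohortValues(t2), tolerance = 1e-9)
})
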