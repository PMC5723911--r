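test_that("age restriction keeps only bands above each outcome cutoff", {
  rec <- makeRecords(age_group = c("19-24", "30-34", "50-54", "80+"))
  expect_identical(ageRestrict(rec, "stroke")$age_group, c("50-54", "80+"))
  expect_identical(nrow(ageRestrict(rec, "hypertension")), 3L)
  expect_identical(nrow(ageRestrict(rec, "angina")), 2L)

  r30 <- makeRecords(age_group = c("30-34", "45-49", "60-64"))
  expect_identical(ageRestrict(r30, "hypertension"), r30)

  bad <- makeRecords(age_group = c("35-44", "45-54"))
  expect_error(ageRestrict(bad, "myocardial_infarction"), "straddles")
})

test_that("direct standardization is the weighted sum of stratum rates", {
  rec <- makeRecords(sex = rep(c("M", "F"), each = 10),
                     age_group = "30-34",
                     current_smoker = c(rep(1, 1), rep(0, 9),   # 10%
                                        rep(1, 3), rep(0, 7)))  # 30%
  std <- standardPopulation(data.frame(sex = c("M", "F"),
                                       age_group = "30-34",
                                       weight = c(0.5, 0.5)))
  expect_equal(directStandardize(rec, "current_smoker", std), 20)

  # three strata, hand-computed weighted sum: 100*(0.2*0.1+0.3*0.2+0.5*0.4)
  rec3 <- makeRecords(sex = "M", age_group = rep(c("30-34", "40-44", "50-54"),
                                                 each = 10),
                      current_smoker = c(rep(1, 1), rep(0, 9),
                                         rep(1, 2), rep(0, 8),
                                         rep(1, 4), rep(0, 6)))
  std3 <- standardPopulation(data.frame(sex = "M",
                                        age_group = c("30-34", "40-44", "50-54"),
                                        weight = c(0.2, 0.3, 0.5)))
  expect_equal(directStandardize(rec3, "current_smoker", std3), 28)

  # constant rate is invariant to the weights
  recc <- makeRecords(sex = "M", age_group = rep(c("30-34", "40-44"), each = 4),
                      current_smoker = rep(c(1, 0, 0, 0), 2))
  stdw <- standardPopulation(data.frame(sex = "M",
                                        age_group = c("30-34", "40-44"),
                                        weight = c(0.9, 0.1)))
  expect_equal(directStandardize(recc, "current_smoker", stdw), 25)
})

test_that("standardizing with the sample's own demography gives the crude rate", {
  set.seed(11)
  rec <- makeRecords(sex = sample(c("M", "F"), 200, TRUE),
                     age_group = sample(defaultAgeBands()[3:8], 200, TRUE),
                     current_smoker = rbinom(200, 1, 0.3))
  expect_equal(directStandardize(rec, "current_smoker", pooledStandard(rec)),
               100 * mean(rec$current_smoker), tolerance = 1e-12)
  # replication invariance
  rec3x <- rbind(rec, rec, rec)
  expect_equal(directStandardize(rec3x, "current_smoker", pooledStandard(rec)),
               directStandardize(rec, "current_smoker", pooledStandard(rec)))
})

test_that("missing values and empty strata are handled as documented", {
  rec <- makeRecords(sex = "M", age_group = c("30-34", "30-34"),
                     current_smoker = c(NA, NA))
  std <- standardPopulation(data.frame(sex = "M", age_group = "30-34",
                                       weight = 1))
  expect_error(directStandardize(rec, "current_smoker", std), "all records missing")
  expect_error(directStandardize(rec[0, ], "current_smoker", std), "empty")

  # weight of an unobserved stratum is renormalized over observed ones
  rec2 <- makeRecords(sex = "M", age_group = rep("30-34", 4),
                      current_smoker = c(1, 1, 0, 0))
  std2 <- standardPopulation(data.frame(sex = "M",
                                        age_group = c("30-34", "40-44"),
                                        weight = c(0.4, 0.6)))
  expect_equal(directStandardize(rec2, "current_smoker", std2), 50)
  expect_equal(directStandardize(rec2, "current_smoker", std2,
                                 redistribute = FALSE), 20)  # 0.4 * 50%

  # stratum in the records but absent from the standard is an error
  std3 <- standardPopulation(data.frame(sex = "F", age_group = "30-34",
                                        weight = 1))
  expect_error(directStandardize(rec2, "current_smoker", std3), "absent")
})

test_that("buildPanel reproduces hand-computed cell summaries", {
  rec <- rbind(
    makeRecords(sex = "M", age_group = "30-34",
                hypertension = c(1, 0, 0, 1), current_smoker = c(1, 1, 0, 0),
                bmi = c(22, 24, 23, 25), drinks_monthly = c(1, 1, 1, 0)),
    makeRecords(sex = "F", age_group = "60-64",
                hypertension = c(1, 1, 1, 0), stroke = c(1, 0, 0, 0),
                current_smoker = 0, bmi = c(21, 22, 23, 26),
                drinks_monthly = c(0, 0, 1, 0)))
  suppressWarnings(pan <- buildPanel(rec))
  o <- panelOutcomes(pan)
  # hypertension: equal-weight strata (4 + 4 records) -> (0.5 + 0.75)/2
  expect_equal(o$prevalence[o$outcome == "hypertension"], 62.5)
  # stroke restricted to >= 50: only the F/60-64 stratum, rate 25%
  expect_equal(o$prevalence[o$outcome == "stroke"], 25)
  # myocardial infarction >= 40: only F/60-64, zero cases -> flagged
  expect_equal(o$prevalence[o$outcome == "myocardial_infarction"], 0)
  expect_true(o$nonpositive[o$outcome == "myocardial_infarction"])
  cv <- panelCovariates(pan)
  expect_equal(cv$smoking_rate, 25)        # (50% + 0%)/2
  expect_equal(cv$mean_bmi, mean(rec$bmi)) # arithmetic mean
  expect_equal(cv$drinking_rate, 50)       # (75% + 25%)/2
  expect_identical(cv$n, 8L)

  # duplicating every record leaves all rates unchanged
  suppressWarnings(pan2 <- buildPanel(rbind(rec, rec)))
  expect_equal(panelOutcomes(pan2)$prevalence, o$prevalence)
})

test_that("buildPanel requires a standard population for every year", {
  rec <- makeRecords(year = c(2010L, 2011L), age_group = "60-64")
  std <- list(`2010` = pooledStandard(rec))
  expect_error(suppressWarnings(buildPanel(rec, std)), "2011")
})

test_that("normality screen distinguishes skewed from Gaussian prevalence", {
  set.seed(7)
  mkpanel <- function(vals) {
    n <- length(vals)
    tinyPanel(sprintf("R%03d", 1:n), 2010L, vals, 25, outcome = "stroke")
  }
  skew <- mkpanel(rgamma(500, shape = 2, rate = 0.5))
  r1 <- normalityScreen(skew, "stroke")
  expect_identical(r1$verdict, "non-normal")
  norm <- mkpanel(rnorm(500, 50, 5))
  r2 <- normalityScreen(norm, "stroke")
  expect_identical(r2$verdict, "normal")
  expect_true(r2$statistic > 0.98)

  expect_error(normalityScreen(mkpanel(c(1, 2)), "stroke"), "at least 3")
  expect_error(normalityScreen(mkpanel(rep(5, 5)), "stroke"), "degenerate")
})

test_that("survey records and panels round-trip through CSV", {
  rec <- makeRecords(sex = c("M", "F"), age_group = "60-64",
                     stroke = c(1, 0), bmi = c(24.2, 21.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, f, row.names = FALSE)
  rec2 <- readSurveyRecords(f)
  expect_equal(rec2$bmi, rec$bmi)
  expect_error(readSurveyRecords(f, columnMap = c(bmi = "nope")), "not in file")

  suppressWarnings(pan <- buildPanel(rec))
  fo <- withr::local_tempfile(fileext = ".csv")
  fc <- withr::local_tempfile(fileext = ".csv")
  writePanel(pan, fo, fc)
  pan2 <- readPanel(fo, fc)
  expect_equal(panelOutcomes(pan2)$prevalence, panelOutcomes(pan)$prevalence)
})
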