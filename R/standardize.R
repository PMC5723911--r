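# Direct sex/age standardization of survey records into the region-year panel.

.OUTCOMES <- c("hypertension", "stroke", "myocardial_infarction", "angina")

# Minimum age (years) at which each outcome's prevalence is defined.
.AGE_CUTOFFS <- c(hypertension = 30, stroke = 50,
                  myocardial_infarction = 40, angina = 40)

# survey-record column -> panel covariate column
.EXPOSURE_MAP <- c(current_smoker = "smoking_rate",
                   passive_home = "passive_home_rate",
                   passive_work = "passive_work_rate",
                   drinks_monthly = "drinking_rate")

.RECORD_COLUMNS <- c("region_id", "year", "sex", "age_group", .OUTCOMES,
                     names(.EXPOSURE_MAP)[1:3], "bmi", "drinks_monthly")

#' Default adult age bands
#'
#' Five-year bands from 19-24 up to 75-79 plus an open 80+ band, mirroring
#' the granularity of community health survey microdata.
#' @return character vector of band labels.
#' @export
defaultAgeBands <- function() {
  c("19-24", paste(seq(25, 75, by = 5), seq(29, 79, by = 5), sep = "-"), "80+")
}

#' Parse age-band labels into lower/upper bounds
#' @noRd
.parseBands <- function(labels) {
  lower <- suppressWarnings(as.numeric(sub("[-+].*$", "", labels)))
  upper <- ifelse(grepl("\\+$", labels), Inf,
                  suppressWarnings(as.numeric(sub("^.*-", "", labels))))
  if (any(is.na(lower)) || any(is.na(upper)))
    stop("unparseable age band label: ",
         labels[which(is.na(lower) | is.na(upper))[1L]])
  data.frame(label = labels, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

#' Restrict survey records to an outcome's age range
#'
#' Each outcome's prevalence is defined from a minimum age upwards:
#' hypertension 30, stroke 50, myocardial infarction 40, angina 40. A band
#' that straddles the cutoff (lower bound below it, upper bound at or above
#' it) makes the restriction ambiguous and is rejected.
#'
#' @param records survey-record data.frame (see [readSurveyRecords()]).
#' @param outcome one of `"hypertension"`, `"stroke"`,
#'   `"myocardial_infarction"`, `"angina"`.
#' @param cutoffs named numeric of minimum ages, by outcome.
#' @return the subset of `records` in bands wholly at or above the cutoff.
#' @export
ageRestrict <- function(records, outcome, cutoffs = .AGE_CUTOFFS) {
  outcome <- match.arg(outcome, names(cutoffs))
  cut <- cutoffs[[outcome]]
  bands <- .parseBands(unique(as.character(records$age_group)))
  straddle <- bands$lower < cut & bands$upper >= cut
  if (any(straddle))
    stop("age band '", bands$label[straddle][1L], "' straddles the ", outcome,
         " cutoff of ", cut, " years; re-band the records")
  keep <- bands$label[bands$lower >= cut]
  records[records$age_group %in% keep, , drop = FALSE]
}

#' Standard population constructor
#'
#' @param df data.frame with columns `sex`, `age_group`, `weight`
#'   (nonnegative; normalized to sum to 1).
#' @return normalized standard-population data.frame.
#' @export
standardPopulation <- function(df) {
  stopifnot(all(c("sex", "age_group", "weight") %in% names(df)))
  if (any(df$weight < 0)) stop("standard-population weights must be nonnegative")
  tot <- sum(df$weight)
  if (tot <= 0) stop("at least one stratum must have positive weight")
  df$weight <- df$weight / tot
  if (anyDuplicated(paste(df$sex, df$age_group)))
    stop("duplicate (sex, age_group) stratum in standard population")
  df[order(df$sex, df$age_group), c("sex", "age_group", "weight")]
}

#' Empirical sex-by-age distribution of a record set
#'
#' The pooled sample's own demography, the default standard population when
#' none is supplied ("standardize to the study year's respondents").
#'
#' @param records survey-record data.frame.
#' @return a standard-population data.frame.
#' @export
pooledStandard <- function(records) {
  tab <- as.data.frame(table(sex = records$sex, age_group = records$age_group),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  standardPopulation(data.frame(sex = tab$sex, age_group = tab$age_group,
                                weight = tab$Freq, stringsAsFactors = FALSE))
}

#' Directly standardized rate of a binary survey variable
#'
#' Computes `100 * sum_s(w_s * r_s)` where `r_s` is the stratum-specific mean
#' of the (0/1) variable among non-missing responses and `w_s` the standard
#' population's normalized weight for sex-age stratum s. Strata present in
#' the standard but unobserved in the records contribute no rate; by default
#' their weight is redistributed proportionally over the observed strata
#' (equivalently, weights are renormalized over observed strata), keeping the
#' weights summing to one.
#'
#' @param records survey-record data.frame (already age-restricted if the
#'   variable is an outcome with an age cutoff).
#' @param variable column name of the 0/1 variable to standardize.
#' @param standard a standard-population data.frame ([standardPopulation()]);
#'   every stratum observed in `records` must appear in it.
#' @param redistribute redistribute the weight of empty strata over observed
#'   ones (default `TRUE`); `FALSE` drops that weight instead.
#' @return standardized rate in percent, in `[0, 100]`.
#' @export
directStandardize <- function(records, variable, standard,
                              redistribute = TRUE) {
  if (!nrow(records)) stop("empty record set")
  if (!variable %in% names(records)) stop("no column '", variable, "' in records")
  v <- records[[variable]]
  ok <- !is.na(v)
  if (!any(ok)) stop("all records missing on '", variable, "'")
  rec <- records[ok, , drop = FALSE]
  v <- v[ok]
  key <- paste(rec$sex, rec$age_group, sep = "\r")
  skey <- paste(standard$sex, standard$age_group, sep = "\r")
  miss <- setdiff(unique(key), skey)
  if (length(miss))
    stop("stratum observed in records but absent from standard population: ",
         gsub("\r", "/", miss[1L]))
  rates <- tapply(v, key, mean)
  w <- standard$weight[match(names(rates), skey)]
  wsum <- sum(w)
  if (wsum <= 0) stop("observed strata carry zero standard weight")
  if (redistribute) w <- w / wsum
  100 * sum(w * rates)
}

#' Build the region-year observation panel from survey records
#'
#' For each region-year cell: the directly standardized prevalence of each
#' cardiovascular outcome on its age-restricted subset, the standardized
#' smoking, passive-smoking and monthly-drinking rates over all adults, and
#' the arithmetic mean BMI. Standardization uses the supplied per-year
#' standard populations, defaulting to the pooled study sample's sex-age
#' distribution of each year.
#'
#' @param records survey-record data.frame.
#' @param standardByYear named list (by year, as character) of
#'   standard-population data.frames, or `NULL` for the pooled per-year
#'   default.
#' @param minN cells whose eligible respondent count falls below this are
#'   still computed but carry `n` for downstream screening (default 10).
#' @param redistribute passed to [directStandardize()].
#' @param outcomes outcome columns to standardize.
#' @return a [RegionYearPanel-class]; cells with zero or missing prevalence
#'   are flagged `nonpositive` for the gamma model's positivity policy.
#' @export
buildPanel <- function(records, standardByYear = NULL, minN = 10,
                       redistribute = TRUE, outcomes = .OUTCOMES) {
  stopifnot(nrow(records) > 0)
  years <- sort(unique(records$year))
  if (is.null(standardByYear)) {
    standardByYear <- lapply(years, function(y)
      pooledStandard(records[records$year == y, , drop = FALSE]))
    names(standardByYear) <- as.character(years)
  }
  missing_std <- setdiff(as.character(years), names(standardByYear))
  if (length(missing_std))
    stop("no standard population for year ", missing_std[1L])

  cellkey <- paste(records$region_id, records$year, sep = "\r")
  cells <- unique(cellkey)
  orows <- vector("list", length(cells) * length(outcomes))
  crows <- vector("list", length(cells))
  oi <- 0L
  for (ci in seq_along(cells)) {
    rec <- records[cellkey == cells[ci], , drop = FALSE]
    reg <- rec$region_id[1L]; yr <- rec$year[1L]
    std <- standardPopulation(standardByYear[[as.character(yr)]])
    for (oc in outcomes) {
      sub <- ageRestrict(rec, oc)
      n_ok <- sum(!is.na(sub[[oc]]))
      prev <- if (n_ok > 0)
        directStandardize(sub, oc, std, redistribute) else NA_real_
      oi <- oi + 1L
      orows[[oi]] <- data.frame(
        region_id = reg, year = yr, outcome = oc, prevalence = prev,
        expected = NA_real_, n = n_ok,
        nonpositive = is.na(prev) || prev <= 0, stringsAsFactors = FALSE)
    }
    rate <- function(col) {
      if (sum(!is.na(rec[[col]])) == 0) return(NA_real_)
      directStandardize(rec, col, std, redistribute)
    }
    crows[[ci]] <- data.frame(
      region_id = reg, year = yr,
      smoking_rate = rate("current_smoker"),
      passive_home_rate = rate("passive_home"),
      passive_work_rate = rate("passive_work"),
      mean_bmi = mean(rec$bmi, na.rm = TRUE),
      drinking_rate = rate("drinks_monthly"),
      n = nrow(rec), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, orows[seq_len(oi)])
  cov <- do.call(rbind, crows)
  small <- cov$n < minN
  if (any(small))
    warning(sum(small), " region-year cell(s) below the minimum of ", minN,
            " respondents")
  ord <- order(out$region_id, out$year, out$outcome)
  cord <- order(cov$region_id, cov$year)
  new("RegionYearPanel", outcomes = out[ord, , drop = FALSE],
      covariates = cov[cord, , drop = FALSE])
}

#' Shapiro-Wilk normality screen of a prevalence series
#'
#' Informational screen on the pooled standardized prevalence of one outcome
#' (the motivation for a gamma rather than Gaussian response); it does not
#' gate model fitting.
#'
#' @param panel a [RegionYearPanel-class].
#' @param outcome outcome name.
#' @param alpha significance level for the verdict (default 0.05).
#' @return list with `statistic`, `p_value`, `verdict` (`"normal"` /
#'   `"non-normal"`) and `n`.
#' @export
normalityScreen <- function(panel, outcome, alpha = 0.05) {
  stopifnot(is(panel, "RegionYearPanel"))
  o <- panel@outcomes
  x <- o$prevalence[o$outcome == outcome & !is.na(o$prevalence)]
  if (length(x) < 3) stop("need at least 3 prevalence values, have ", length(x))
  if (length(x) > 5000) x <- x[seq_len(5000)]
  if (sd(x) == 0)
    stop("degenerate input: all ", length(x), " prevalence values identical")
  sw <- shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       verdict = if (sw$p.value < alpha) "non-normal" else "normal",
       n = length(x))
}

#' Read survey records from a delimited file
#'
#' @param path CSV path with a header.
#' @param columnMap optional named character vector mapping canonical column
#'   names (names) to the file's column names (values).
#' @return validated survey-record data.frame with columns `region_id`,
#'   `year`, `sex`, `age_group`, the four outcome flags, `current_smoker`,
#'   `passive_home`, `passive_work`, `bmi`, `drinks_monthly`.
#' @export
readSurveyRecords <- function(path, columnMap = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      have <- columnMap[[canon]]
      if (!have %in% names(df)) stop("mapped column '", have, "' not in file")
      names(df)[names(df) == have] <- canon
    }
  }
  miss <- setdiff(.RECORD_COLUMNS, names(df))
  if (length(miss))
    stop("survey records missing column(s): ", paste(miss, collapse = ", "))
  if (any(!df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(!is.na(df$bmi) & df$bmi <= 0)) stop("bmi must be positive when present")
  df
}

#' Read a standard population CSV (`sex, age_group, weight`)
#' @param path CSV path.
#' @return normalized standard-population data.frame.
#' @export
readStandardPopulation <- function(path) {
  standardPopulation(read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a panel as a pair of tidy CSV files
#'
#' @param panel a [RegionYearPanel-class].
#' @param outcomesPath,covariatesPath file paths.
#' @return paths (write) or a [RegionYearPanel-class] (read).
#' @export
writePanel <- function(panel, outcomesPath, covariatesPath) {
  stopifnot(is(panel, "RegionYearPanel"))
  write.csv(panel@outcomes, outcomesPath, row.names = FALSE)
  write.csv(panel@covariates, covariatesPath, row.names = FALSE)
  invisible(c(outcomesPath, covariatesPath))
}

#' @rdname writePanel
#' @export
readPanel <- function(outcomesPath, covariatesPath) {
  o <- read.csv(outcomesPath, stringsAsFactors = FALSE)
  o$nonpositive <- as.logical(o$nonpositive)
  new("RegionYearPanel", outcomes = o,
      covariates = read.csv(covariatesPath, stringsAsFactors = FALSE))
}

setMethod("panelOutcomes", "RegionYearPanel", function(x) x@outcomes)
setMethod("panelCovariates", "RegionYearPanel", function(x) x@covariates)
setMethod("regionIds", "RegionYearPanel",
          function(x) sort(unique(x@covariates$region_id)))
setMethod("nRegions", "RegionYearPanel",
          function(x) length(unique(x@covariates$region_id)))

setMethod("show", "RegionYearPanel", function(object) {
  o <- object@outcomes
  cat("RegionYearPanel:", length(unique(o$region_id)), "regions x",
      length(unique(o$year)), "years,",
      length(unique(o$outcome)), "outcome(s),",
      nrow(o), "prevalence cells (", sum(o$nonpositive), "nonpositive )\n")
})
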