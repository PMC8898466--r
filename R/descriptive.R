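defaultYearBins <- function() {
  list("2005-2010" = 2005:2010, "2011-2015" = 2011:2015,
       "2016-2020" = 2016:2020)
}

countStratum <- function(maskEvent, maskOther) {
  c(n_event = sum(maskEvent), n_other = sum(maskOther))
}

#' Summarise the clinical characteristics of a cohort
#'
#' Builds the stratified clinical-characteristics table for a target-drug
#' cohort, split into the cases flagged for one event group (the "event"
#' arm) and the remaining cases of the same drug (the "other-AE" arm).
#' Counts are case level.  Sex, age, reporter and year stratifications
#' partition each arm; outcome rows are not mutually exclusive (one case
#' can carry several outcome codes, and a case with none falls in the
#' `missing` row); dose-regimen rows are likewise non-exclusive
#' (loading/non-loading and standard/high maintenance are two different
#' dichotomies, and unclassifiable cases belong to neither).  All
#' percentages use the arm size as denominator.
#'
#' @param cohort A [Cohort-class] from [buildCohort()].
#' @param group Event group defining the event arm (must be a column of
#'   `eventFlags(cohort)`).
#' @param yearBins Named list of receipt-year vectors for the year rows.
#' @param elderlyCutoff Age (years) splitting the age rows.
#' @return A [CohortSummary-class] object.
#' @export
summarizeCohort <- function(cohort, group = "coagulation_dysfunction",
                            yearBins = defaultYearBins(),
                            elderlyCutoff = 65) {
  stopifnot(is(cohort, "Cohort"))
  rep <- cohort@reports@reports
  if (!nrow(rep)) stopEmpty("cohort is empty")
  if (!group %in% colnames(cohort@flags))
    stopConfig(sprintf("event group '%s' not flagged in this cohort", group))
  inEvent <- cohort@flags[, group]
  arms <- list(event = inEvent, other = !inEvent)
  rows <- list()
  addRow <- function(stratification, stratum, maskAll) {
    n <- countStratum(maskAll & arms$event, maskAll & arms$other)
    rows[[length(rows) + 1L]] <<- data.frame(
      stratification = stratification, stratum = stratum,
      n_event = unname(n["n_event"]), n_other = unname(n["n_other"]),
      stringsAsFactors = FALSE)
  }

  addRow("sex", "male", rep$sex == "M")
  addRow("sex", "female", rep$sex == "F")
  addRow("sex", "missing", rep$sex == "missing")

  age <- rep$age_years
  addRow("age", sprintf("<%g", elderlyCutoff), !is.na(age) & age < elderlyCutoff)
  addRow("age", sprintf(">=%g", elderlyCutoff), !is.na(age) & age >= elderlyCutoff)
  addRow("age", "missing", is.na(age))

  addRow("reporter", "healthcare", rep$reporter_class == "healthcare")
  addRow("reporter", "non_healthcare", rep$reporter_class == "non_healthcare")
  addRow("reporter", "unknown", rep$reporter_class == "unknown")

  binned <- rep(FALSE, nrow(rep))
  for (bin in names(yearBins)) {
    m <- !is.na(rep$receipt_year) & rep$receipt_year %in% yearBins[[bin]]
    binned <- binned | m
    addRow("year", bin, m)
  }
  if (any(!binned)) addRow("year", "other", !binned)

  withOutcome <- rep$primaryid %in% cohort@reports@outcomes$primaryid
  for (oc in unname(OUTCOME_CODES)) {
    ids <- cohort@reports@outcomes$primaryid[
      cohort@reports@outcomes$outcome == oc]
    addRow("outcome", oc, rep$primaryid %in% ids)
  }
  addRow("outcome", "missing", !withOutcome)

  loading <- rep$loading %||% rep(NA, nrow(rep))
  maint <- rep$maintenance %||% rep(NA_character_, nrow(rep))
  addRow("dose_regimen", "loading", !is.na(loading) & loading)
  addRow("dose_regimen", "non_loading", !is.na(loading) & !loading)
  addRow("dose_regimen", "standard_maintenance",
         !is.na(maint) & maint == "standard")
  addRow("dose_regimen", "high_maintenance", !is.na(maint) & maint == "high")

  strata <- do.call(rbind, rows)
  nEvent <- sum(arms$event)
  nOther <- sum(arms$other)
  strata$pct_event <- if (nEvent) 100 * strata$n_event / nEvent else NA_real_
  strata$pct_other <- if (nOther) 100 * strata$n_other / nOther else NA_real_
  strata <- strata[, c("stratification", "stratum", "n_event", "pct_event",
                       "n_other", "pct_other")]
  new("CohortSummary", strata = strata, nEvent = as.integer(nEvent),
      nOther = as.integer(nOther), group = group)
}

#' Case-fatality rate of the event arm
#'
#' Percentage of event-arm cases reported with a death outcome.
#'
#' @param summary A [CohortSummary-class].
#' @return Percentage in `[0, 100]`.
#' @export
caseFatality <- function(summary) {
  stopifnot(is(summary, "CohortSummary"))
  if (summary@nEvent == 0L) stopEmpty("event arm is empty")
  s <- summary@strata
  deaths <- s$n_event[s$stratification == "outcome" & s$stratum == "death"]
  100 * deaths / summary@nEvent
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square with 1 degree of freedom and no continuity
#' correction, the form whose p-values the stratified subgroup
#' comparisons report.
#'
#' @param m 2x2 numeric matrix of counts.
#' @return list with `statistic` and `p_value`.
#' @export
#' @examples
#' chisqTest2x2(matrix(c(28, 121, 86, 305), 2))  # p = 0.415
chisqTest2x2 <- function(m) {
  m <- as.matrix(m)
  stopifnot(identical(dim(m), c(2L, 2L)))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stopCondition("faersignalDegenerateTable",
                  "degenerate 2x2 table: zero marginal")
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Time to onset of the flagged events
#'
#' For every event-arm case with day-precision dates, the onset interval
#' is the event date minus the EARLIEST day-precision therapy start of
#' the target drug, in whole days.  Cases with partial (month/year) or
#' missing dates and negative intervals (event recorded before therapy
#' start: data-entry noise) are excluded and tallied.  Median and IQR use
#' linear interpolation between order statistics (type-7 quantiles).
#'
#' @param cohort A [Cohort-class] (its reports carry the target-drug
#'   therapy start computed by [buildCohort()]).
#' @param group Event group whose onset is analysed.
#' @return A list: `records` (data.frame `caseid`, `onset_days`),
#'   `median`, `iqr` (length-2), `fraction_within` (function: days ->
#'   cumulative percentage), `curve` (data.frame `day`,
#'   `cumulative_pct` on the integer grid), `excluded` (named exclusion
#'   counts).
#' @export
timeToEvent <- function(cohort, group = "coagulation_dysfunction") {
  stopifnot(is(cohort, "Cohort"))
  rep <- cohort@reports@reports
  if (!group %in% colnames(cohort@flags))
    stopConfig(sprintf("event group '%s' not flagged in this cohort", group))
  flagged <- rep[cohort@flags[, group], , drop = FALSE]
  if (!nrow(flagged)) stopEmpty("no cases flagged for this event group")
  start <- flagged$target_start_date
  noStart <- is.na(start)
  noEvent <- flagged$event_precision != "day"
  eligible <- !noStart & !noEvent
  onset <- as.integer(flagged$event_date[eligible] - start[eligible])
  negative <- onset < 0
  excluded <- c(missing_therapy_start = sum(noStart),
                partial_or_missing_event_date = sum(noEvent & !noStart),
                negative_interval = sum(negative))
  if (!any(!negative) || !length(onset))
    stopEmpty(paste0("no usable time-to-onset records (",
                     paste(names(excluded), excluded, sep = "=",
                           collapse = ", "), ")"))
  records <- data.frame(caseid = flagged$caseid[eligible][!negative],
                        onset_days = onset[!negative],
                        stringsAsFactors = FALSE)
  q <- unname(stats::quantile(records$onset_days, c(0.25, 0.5, 0.75),
                              type = 7))
  fractionWithin <- function(d)
    100 * vapply(d, function(dd) mean(records$onset_days <= dd), numeric(1))
  grid <- 0:max(records$onset_days)
  curve <- data.frame(day = grid, cumulative_pct = fractionWithin(grid))
  list(records = records, median = q[2L], iqr = q[c(1L, 3L)],
       fraction_within = fractionWithin, curve = curve, excluded = excluded)
}
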