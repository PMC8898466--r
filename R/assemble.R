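#' @importFrom data.table as.data.table setkey setnames :=
NULL

# FAERS code books used at assembly.  Unknown codes are logged (warning)
# and skipped, never fatal: spontaneous-report data are dirty.
OUTCOME_CODES <- c(DE = "death", LT = "life_threatening", DS = "disability",
                   HO = "hospitalization", RI = "required_intervention",
                   OT = "other_serious")
ROLE_CODES <- c(PS = "primary_suspect", SS = "secondary_suspect",
                C = "concomitant", I = "interacting")
REPORTER_CODES <- c(MD = "healthcare", PH = "healthcare", HP = "healthcare",
                    OT = "healthcare", CN = "non_healthcare",
                    LW = "non_healthcare")
# Divisors/multipliers taking the age field to years.
AGE_UNIT_TO_YEARS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                       DY = 1 / 365.25, HR = 1 / 8766)

decodeAgeYears <- function(age, age_cod) {
  age_cod <- toupper(trimws(age_cod))
  num <- suppressWarnings(as.numeric(trimws(age)))
  factor <- AGE_UNIT_TO_YEARS[age_cod]
  unknown <- !is.na(num) & nzchar(age_cod) & is.na(factor)
  if (any(unknown))
    warning(sprintf("ignoring %d age value(s) with unknown age_cod: %s",
                    sum(unknown),
                    paste(unique(age_cod[unknown]), collapse = ", ")),
            call. = FALSE)
  out <- num * as.numeric(factor)
  bad <- !is.na(out) & (out < 0 | out > 150)
  if (any(bad)) {
    warning(sprintf("ignoring %d implausible age value(s) outside [0, 150] years",
                    sum(bad)), call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

#' Assemble case-level reports from raw FAERS tables
#'
#' Joins the five FAERS tables into one [FaersReports-class] with a row
#' per report version (`primaryid`): drug entries are linked to therapy
#' start dates on (`primaryid`, `drug_seq`), reactions collected from
#' REAC, outcome codes decoded (`DE` death, `LT` life-threatening, `DS`
#' disability, `HO` hospitalization, `RI` required intervention, `OT`
#' other serious), reporter class decoded from `occp_cod` (MD/PH/HP/OT
#' healthcare; CN/LW non-healthcare; blank unknown) and age converted to
#' years from `age_cod`.  DEMO rows with no reaction PT are dropped with a
#' warning (a safety report without a reaction is not analysable).
#'
#' @param tables A [FaersTables-class] object.
#' @return A [FaersReports-class] object (not yet deduplicated).
#' @export
assembleReports <- function(tables) {
  stopifnot(is(tables, "FaersTables"))
  validObject(tables)
  demo <- tables@demo

  event <- parseFaersDate(demo$event_dt)
  receipt <- parseFaersDate(demo$fda_dt)
  sex <- toupper(trimws(demo$sex))
  sex[!sex %in% c("M", "F")] <- "missing"

  occp <- toupper(trimws(demo$occp_cod))
  reporter <- unname(REPORTER_CODES[occp])
  unknownOccp <- nzchar(occp) & is.na(reporter)
  if (any(unknownOccp))
    warning(sprintf("unknown occp_cod value(s): %s (treated as unknown)",
                    paste(unique(occp[unknownOccp]), collapse = ", ")),
            call. = FALSE)
  reporter[is.na(reporter)] <- "unknown"

  reportsDf <- data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    receipt_date = receipt$raw,
    receipt_year = receipt$year,
    event_raw = event$raw,
    event_precision = event$precision,
    event_date = event$date,
    sex = sex,
    age_years = decodeAgeYears(demo$age, demo$age_cod),
    reporter_class = reporter,
    stringsAsFactors = FALSE
  )

  # drug entries + therapy start via (primaryid, drug_seq) <- THER dsg_seq
  drug <- as.data.table(tables@drug)
  ther <- as.data.table(tables@ther)[, c("primaryid", "dsg_seq", "start_dt")]
  setnames(ther, "dsg_seq", "drug_seq")
  # one start date per (primaryid, drug_seq): keep the earliest parseable
  start <- parseFaersDate(ther$start_dt)
  ther[, `:=`(start_raw = start$raw, start_precision = start$precision,
              start_date = start$date)]
  ther <- ther[order(primaryid, drug_seq, is.na(start_date), start_date)]
  ther <- ther[!duplicated(ther[, c("primaryid", "drug_seq")])]
  drug <- merge(drug, ther[, c("primaryid", "drug_seq", "start_raw",
                               "start_precision", "start_date")],
                by = c("primaryid", "drug_seq"), all.x = TRUE, sort = FALSE)

  role <- unname(ROLE_CODES[toupper(trimws(drug$role_cod))])
  unknownRole <- is.na(role)
  if (any(unknownRole))
    warning(sprintf("dropping %d drug entr(ies) with unknown role_cod",
                    sum(unknownRole)), call. = FALSE)
  drugsDf <- data.frame(
    primaryid = drug$primaryid,
    drug_seq = drug$drug_seq,
    name_raw = drug$drugname,
    ai_raw = drug$prod_ai,
    role = role,
    dose_amt = suppressWarnings(as.numeric(drug$dose_amt)),
    dose_unit = toupper(trimws(drug$dose_unit)),
    dose_freq = toupper(trimws(drug$dose_freq)),
    start_raw = drug$start_raw %||% NA_character_,
    start_precision = drug$start_precision,
    start_date = drug$start_date,
    stringsAsFactors = FALSE
  )[!unknownRole, , drop = FALSE]
  drugsDf$start_raw[is.na(drugsDf$start_raw)] <- ""
  drugsDf$start_precision[is.na(drugsDf$start_precision)] <- "missing"

  reactionsDf <- data.frame(primaryid = tables@reac$primaryid,
                            pt = trimws(tables@reac$pt),
                            stringsAsFactors = FALSE)
  reactionsDf <- reactionsDf[nzchar(reactionsDf$pt), , drop = FALSE]

  outc <- toupper(trimws(tables@outc$outc_cod))
  outcome <- unname(OUTCOME_CODES[outc])
  unknownOutc <- nzchar(outc) & is.na(outcome)
  if (any(unknownOutc))
    warning(sprintf("ignoring %d outcome row(s) with unknown outc_cod: %s",
                    sum(unknownOutc),
                    paste(unique(outc[unknownOutc]), collapse = ", ")),
            call. = FALSE)
  keepOutc <- !is.na(outcome)
  outcomesDf <- unique(data.frame(primaryid = tables@outc$primaryid[keepOutc],
                                  outcome = outcome[keepOutc],
                                  stringsAsFactors = FALSE))

  noReac <- !reportsDf$primaryid %in% reactionsDf$primaryid
  if (any(noReac)) {
    warning(sprintf("dropping %d report(s) with no reaction PT", sum(noReac)),
            call. = FALSE)
    keep <- reportsDf$primaryid[!noReac]
    reportsDf <- reportsDf[!noReac, , drop = FALSE]
    drugsDf <- drugsDf[drugsDf$primaryid %in% keep, , drop = FALSE]
    outcomesDf <- outcomesDf[outcomesDf$primaryid %in% keep, , drop = FALSE]
  }
  reactionsDf <- reactionsDf[reactionsDf$primaryid %in% reportsDf$primaryid, ,
                             drop = FALSE]
  rownames(reportsDf) <- rownames(drugsDf) <- rownames(reactionsDf) <-
    rownames(outcomesDf) <- NULL

  new("FaersReports", reports = reportsDf, drugs = drugsDf,
      reactions = reactionsDf, outcomes = outcomesDf, deduplicated = FALSE)
}
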