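#' @import methods
NULL

# Column contracts for the five FAERS quarterly ASCII tables (modern,
# primaryid/caseid-keyed dialect).  Extra columns are carried verbatim;
# these are the mandatory ones.
FAERS_REQUIRED_COLUMNS <- list(
  demo = c("primaryid", "caseid", "event_dt", "sex", "age", "age_cod",
           "occp_cod", "fda_dt"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "prod_ai", "dose_amt", "dose_unit", "dose_freq"),
  reac = c("primaryid", "caseid", "pt"),
  ther = c("primaryid", "caseid", "dsg_seq", "start_dt"),
  outc = c("primaryid", "caseid", "outc_cod")
)

#' FaersTables: one quarter (or window) of raw FAERS tables
#'
#' Container for the five FAERS quarterly ASCII tables (DEMO, DRUG, REAC,
#' THER, OUTC) with all fields preserved verbatim as character columns.
#' `primaryid` identifies one report version; `caseid` identifies a case,
#' which may carry several versions (hence deduplication downstream).
#'
#' @slot demo,drug,reac,ther,outc data.frames of character columns, one
#'   per FAERS table, each containing at least the mandatory columns of
#'   that table.
#' @seealso [readQuarter()], [writeQuarter()], [assembleReports()]
#' @export
setClass("FaersTables", representation(
  demo = "data.frame",
  drug = "data.frame",
  reac = "data.frame",
  ther = "data.frame",
  outc = "data.frame"
))

setValidity("FaersTables", function(object) {
  msgs <- character()
  for (tab in names(FAERS_REQUIRED_COLUMNS)) {
    df <- slot(object, tab)
    missing <- setdiff(FAERS_REQUIRED_COLUMNS[[tab]], names(df))
    if (length(missing))
      msgs <- c(msgs, sprintf("%s table lacks column(s): %s",
                              toupper(tab), paste(missing, collapse = ", ")))
  }
  if (length(msgs)) return(msgs)
  if (anyDuplicated(object@demo$primaryid))
    msgs <- c(msgs, "duplicated primaryid in DEMO")
  for (tab in c("drug", "reac", "ther", "outc")) {
    ids <- slot(object, tab)$primaryid
    if (!all(ids %in% object@demo$primaryid))
      msgs <- c(msgs, sprintf("%s has primaryid values absent from DEMO",
                              toupper(tab)))
  }
  if (length(msgs)) msgs else TRUE
})

#' FaersReports: case-level safety reports assembled from raw tables
#'
#' Normalised, case-report-level view of a FAERS extract: one row of
#' `reports` per report version (pre-deduplication) or per case (after
#' [deduplicateReports()]), with drug entries, reactions (MedDRA PTs) and
#' outcome codes in linked child tables keyed by `primaryid`.
#'
#' @slot reports data.frame: `primaryid`, `caseid`, `receipt_date` (raw
#'   digit string), `receipt_year`, `event_raw`/`event_precision`/
#'   `event_date`, `sex` (`"M"`, `"F"`, `"missing"`), `age_years`,
#'   `reporter_class` (`"healthcare"`, `"non_healthcare"`, `"unknown"`).
#' @slot drugs data.frame: `primaryid`, `drug_seq`, `name_raw`, `ai_raw`,
#'   `role` (`"primary_suspect"`, `"secondary_suspect"`, `"concomitant"`,
#'   `"interacting"`), `dose_amt` (numeric mg), `dose_unit`, `dose_freq`,
#'   `start_raw`/`start_precision`/`start_date`.
#' @slot reactions data.frame: `primaryid`, `pt`.
#' @slot outcomes data.frame: `primaryid`, `outcome` (decoded labels).
#' @slot deduplicated logical flag; TRUE once one report per case remains.
#' @export
setClass("FaersReports", representation(
  reports = "data.frame",
  drugs = "data.frame",
  reactions = "data.frame",
  outcomes = "data.frame",
  deduplicated = "logical"
))

setValidity("FaersReports", function(object) {
  msgs <- character()
  rep <- object@reports
  if (anyDuplicated(rep$primaryid))
    msgs <- c(msgs, "duplicated primaryid in reports")
  if (isTRUE(object@deduplicated) && anyDuplicated(rep$caseid))
    msgs <- c(msgs, "deduplicated object has repeated caseid")
  age <- rep$age_years
  if (any(!is.na(age) & (age < 0 | age > 150)))
    msgs <- c(msgs, "age_years outside [0, 150]")
  if (nrow(rep) && !all(rep$primaryid %in% object@reactions$primaryid))
    msgs <- c(msgs, "report without any reaction PT")
  if (length(msgs)) msgs else TRUE
})

#' Term dictionaries for drug and event matching
#'
#' `DrugDictionary` maps a drug label to its generic and brand name
#' patterns (matched case-insensitively on word boundaries against the
#' free-text `drugname` and `prod_ai` fields).  `EventDictionary` maps an
#' event-group label to a set of MedDRA preferred terms (matched by exact,
#' case-insensitive PT string).  When an `EventDictionary` contains the
#' umbrella group `"coagulation_dysfunction"` it must contain every PT of
#' the named subgroups.
#'
#' @slot entries named list of non-empty character vectors, one element
#'   per label.
#' @seealso [readDrugDictionary()], [defaultDrugDictionary()]
#' @name TermDictionary
#' @aliases DrugDictionary EventDictionary
#' @exportClass TermDictionary
setClass("TermDictionary", representation(entries = "list", "VIRTUAL"))

setValidity("TermDictionary", function(object) {
  msgs <- character()
  e <- object@entries
  if (is.null(names(e)) || any(!nzchar(names(e))))
    msgs <- c(msgs, "every entry must be named by its label")
  if (anyDuplicated(names(e)))
    msgs <- c(msgs, "labels must be unique")
  if (!all(vapply(e, function(v) is.character(v) && length(v) > 0 &&
                    all(nzchar(v)), logical(1))))
    msgs <- c(msgs, "each label needs a non-empty character pattern set")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TermDictionary
#' @export
setClass("DrugDictionary", contains = "TermDictionary")

#' @rdname TermDictionary
#' @export
setClass("EventDictionary", contains = "TermDictionary")

setValidity("EventDictionary", function(object) {
  e <- object@entries
  umbrella <- "coagulation_dysfunction"
  if (umbrella %in% names(e)) {
    sub <- unique(tolower(unlist(e[setdiff(names(e), umbrella)])))
    if (!all(sub %in% tolower(e[[umbrella]])))
      return(sprintf("umbrella group '%s' must contain every subgroup PT",
                     umbrella))
  }
  TRUE
})

#' Cohort: deduplicated target-drug reports with event-group flags
#'
#' The analysis unit for descriptive summaries: the reports whose primary
#' suspect drug matches one target label, together with a logical flag
#' matrix saying which event groups each case's reactions hit.
#'
#' @slot reports a deduplicated [FaersReports-class] restricted to the
#'   target drug.
#' @slot flags logical matrix, one row per report, one column per event
#'   group of the dictionary used to build the cohort.
#' @slot target character(1), the target drug label.
#' @seealso [buildCohort()], [summarizeCohort()], [timeToEvent()]
#' @export
setClass("Cohort", representation(
  reports = "FaersReports",
  flags = "matrix",
  target = "character"
))

setValidity("Cohort", function(object) {
  msgs <- character()
  if (!isTRUE(object@reports@deduplicated))
    msgs <- c(msgs, "cohort reports must be deduplicated")
  if (nrow(object@flags) != nrow(object@reports@reports))
    msgs <- c(msgs, "flags rows must match report rows")
  if (!is.logical(object@flags))
    msgs <- c(msgs, "flags must be a logical matrix")
  if (length(msgs)) msgs else TRUE
})

#' CohortSummary: stratified clinical-characteristics table
#'
#' Case-level counts and percentages across demographic, reporter, year,
#' outcome and dose-regimen strata, reported side by side for the cohort
#' flagged for one event group ("event" arm) and the remaining cohort
#' reports ("other-AE" arm).  Outcome rows are not mutually exclusive (a
#' FAERS case can carry several outcome codes); all other stratifications
#' partition their arm.
#'
#' @slot strata data.frame with columns `stratification`, `stratum`,
#'   `n_event`, `pct_event`, `n_other`, `pct_other`.
#' @slot nEvent,nOther integer arm sizes (the percentage denominators).
#' @slot group character(1): the event-group label defining the arms.
#' @seealso [summarizeCohort()], [caseFatality()]
#' @export
setClass("CohortSummary", representation(
  strata = "data.frame",
  nEvent = "integer",
  nOther = "integer",
  group = "character"
))

setValidity("CohortSummary", function(object) {
  need <- c("stratification", "stratum", "n_event", "pct_event",
            "n_other", "pct_other")
  if (!all(need %in% names(object@strata)))
    return("strata must have stratification/stratum/n/pct columns")
  TRUE
})
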