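#' Deduplicate FAERS reports to one record per case
#'
#' FAERS distributes every revision of a case as a separate report
#' version (`primaryid`); analyses count cases.  For each `caseid` the
#' report with the greatest receipt date survives; ties are broken by the
#' greatest `primaryid` (longer digit string wins, equal lengths compare
#' lexicographically, i.e. numerically).
#'
#' @param x A [FaersReports-class] object.
#' @return A [FaersReports-class] with one report per case and
#'   `isDeduplicated(x)` TRUE.  Idempotent.
#' @export
deduplicateReports <- function(x) {
  stopifnot(is(x, "FaersReports"))
  rep <- x@reports
  if (!nrow(rep)) {
    x@deduplicated <- TRUE
    return(x)
  }
  ord <- order(rep$caseid, rep$receipt_date, primaryidRank(rep$primaryid))
  rep <- rep[ord, , drop = FALSE]
  keep <- !duplicated(rep$caseid, fromLast = TRUE)
  kept <- rep[keep, , drop = FALSE]
  rownames(kept) <- NULL
  keepIds <- kept$primaryid
  sub <- function(df) {
    df <- df[df$primaryid %in% keepIds, , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  new("FaersReports", reports = kept, drugs = sub(x@drugs),
      reactions = sub(x@reactions), outcomes = sub(x@outcomes),
      deduplicated = TRUE)
}

normalizeName <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}

escapeRegex <- function(x)
  gsub("([\\[\\]{}().\\\\|^$*+?])", "\\\\\\1", x, perl = TRUE)

#' Match reports to a drug label by name pattern and role
#'
#' A report matches when at least one of its drug entries has a role in
#' `roles` and a drug name or active-ingredient field containing one of
#' the label's dictionary patterns as a whole word (case-insensitive,
#' whitespace-normalised).  Word-boundary substring matching keeps
#' dose/form suffixes ("TIGECYCLINE 50MG VIAL") from hiding cases without
#' letting "cefoperazone" match inside an unrelated token.
#'
#' @param x A [FaersReports-class] object.
#' @param dict A [DrugDictionary][TermDictionary].
#' @param label Drug label to match (must exist in `dict`).
#' @param roles Drug roles accepted; the pharmacovigilance default is
#'   primary suspect only.
#' @return Logical vector, one element per row of `reports(x)`.
#' @export
matchDrug <- function(x, dict, label, roles = "primary_suspect") {
  stopifnot(is(x, "FaersReports"), is(dict, "DrugDictionary"))
  patterns <- dictTerms(dict, label)
  drugs <- x@drugs
  drugs <- drugs[drugs$role %in% roles, , drop = FALSE]
  ids <- x@reports$primaryid
  if (!nrow(drugs)) return(setNames(rep(FALSE, length(ids)), ids))
  rx <- paste0("\\b(", paste(escapeRegex(normalizeName(patterns)),
                             collapse = "|"), ")\\b")
  fields <- unique(c(normalizeName(drugs$name_raw),
                     normalizeName(drugs$ai_raw)))
  hitField <- fields[grepl(rx, fields, perl = TRUE)]
  hit <- normalizeName(drugs$name_raw) %in% hitField |
    normalizeName(drugs$ai_raw) %in% hitField
  setNames(ids %in% drugs$primaryid[hit], ids)
}

#' Flag event-group membership per report
#'
#' A group flag is TRUE when the report's reactions intersect the group's
#' preferred-term set (case-insensitive exact PT match).  Counting is at
#' report level: several matching PTs in one group still yield one flag.
#'
#' @param x A [FaersReports-class] object.
#' @param dict An [EventDictionary][TermDictionary].
#' @return Logical matrix: one row per row of `reports(x)` (rownames =
#'   primaryid), one column per event group.
#' @export
flagEvents <- function(x, dict) {
  stopifnot(is(x, "FaersReports"), is(dict, "EventDictionary"))
  ids <- x@reports$primaryid
  pts <- tolower(trimws(x@reactions$pt))
  groups <- labels(dict)
  flags <- matrix(FALSE, nrow = length(ids), ncol = length(groups),
                  dimnames = list(ids, groups))
  for (g in groups) {
    hitIds <- unique(x@reactions$primaryid[pts %in%
                                             tolower(dictTerms(dict, g))])
    flags[, g] <- ids %in% hitIds
  }
  flags
}

# Dose-regimen classification for the descriptive strata.  Maintenance
# modal dose is taken over target-drug entries starting after the first
# therapy date (falling back to all entries when therapy is single-dated);
# "standard" < 200 mg/day, "high" >= 200 mg/day.  A loading dose is an
# earliest-date entry of >= 200 mg that is also at least twice the
# maintenance modal dose, so a high-maintenance regimen running at
# 200 mg/day from day one is not mistaken for a loading dose.  Reports
# whose target entries carry no usable dose stay unclassified (NA).
classifyDoseRegimen <- function(drugs, targetMask) {
  d <- drugs[targetMask & !is.na(drugs$dose_amt), , drop = FALSE]
  ids <- unique(drugs$primaryid)
  loading <- setNames(rep(NA, length(ids)), ids)
  maintenance <- setNames(rep(NA_character_, length(ids)), ids)
  if (!nrow(d)) return(list(loading = loading, maintenance = maintenance))
  for (id in unique(d$primaryid)) {
    e <- d[d$primaryid == id, , drop = FALSE]
    dated <- e[e$start_precision == "day", , drop = FALSE]
    if (nrow(dated)) {
      first <- min(dated$start_date)
      later <- dated[dated$start_date > first, , drop = FALSE]
      pool <- if (nrow(later)) later$dose_amt else e$dose_amt
    } else {
      first <- NULL
      pool <- e$dose_amt
    }
    tab <- table(pool)
    m <- max(as.numeric(names(tab)[tab == max(tab)]))
    maintenance[id] <- if (m >= 200) "high" else "standard"
    if (!is.null(first)) {
      firstDose <- dated$dose_amt[dated$start_date == first]
      loading[id] <- any(firstDose >= 200 & firstDose >= 2 * m)
    }
  }
  list(loading = loading, maintenance = maintenance)
}

#' Build the target-drug analysis cohort
#'
#' Restricts a deduplicated report set to the cases whose primary-suspect
#' drug matches `target`, attaches event-group flags and classifies each
#' case's dose regimen (columns `loading` and `maintenance` on
#' `reports(cohort)`).
#'
#' @param x A deduplicated [FaersReports-class] object.
#' @param drugDict A [DrugDictionary][TermDictionary].
#' @param eventDict An [EventDictionary][TermDictionary].
#' @param target Target drug label.
#' @param roles Drug roles defining cohort membership.
#' @return A [Cohort-class] object.
#' @export
buildCohort <- function(x, drugDict, eventDict, target,
                        roles = "primary_suspect") {
  stopifnot(is(x, "FaersReports"))
  if (!isTRUE(x@deduplicated))
    stopConfig("cohorts are built from deduplicated reports; run deduplicateReports() first")
  mask <- matchDrug(x, drugDict, target, roles = roles)
  keepIds <- x@reports$primaryid[mask]
  sub <- function(df) {
    df <- df[df$primaryid %in% keepIds, , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  repSub <- new("FaersReports", reports = sub(x@reports),
                drugs = sub(x@drugs), reactions = sub(x@reactions),
                outcomes = sub(x@outcomes), deduplicated = TRUE)
  # regimen classification against the target drug's own entries
  dMask <- rep(FALSE, nrow(repSub@drugs))
  if (nrow(repSub@drugs)) {
    rx <- paste0("\\b(",
                 paste(escapeRegex(normalizeName(dictTerms(drugDict, target))),
                       collapse = "|"), ")\\b")
    dMask <- (grepl(rx, normalizeName(repSub@drugs$name_raw), perl = TRUE) |
                grepl(rx, normalizeName(repSub@drugs$ai_raw), perl = TRUE)) &
      repSub@drugs$role %in% roles
  }
  regimen <- classifyDoseRegimen(repSub@drugs, dMask)
  ids <- repSub@reports$primaryid
  repSub@reports$loading <- unname(regimen$loading[ids])
  repSub@reports$maintenance <- unname(regimen$maintenance[ids])
  # earliest day-precision therapy start of the target drug, per case
  td <- repSub@drugs[dMask & repSub@drugs$start_precision == "day", ,
                     drop = FALSE]
  starts <- rep(as.Date(NA), length(ids))
  if (nrow(td)) {
    agg <- tapply(td$start_date, td$primaryid, min)
    starts <- as.Date(unname(agg[ids]),
                      origin = as.Date("1970-01-01"))
  }
  repSub@reports$target_start_date <- starts
  flags <- flagEvents(repSub, eventDict)
  new("Cohort", reports = repSub, flags = flags, target = target)
}

#' Define a comparison design
#'
#' A design names the comparator against which the target drug's event
#' reporting odds are contrasted: either the full database (every
#' non-target report) or a set of comparator drug labels, evaluated
#' per drug or pooled.
#'
#' @param label Design label (used in outputs).
#' @param target Target drug label.
#' @param comparator Either `"full_database"` or a character vector of
#'   comparator drug labels (must not contain the target).
#' @param pairing `"per_drug"` (one contingency table per comparator
#'   drug) or `"pooled"` (one table against the merged comparator set).
#' @return A list with class `"ComparisonDesign"`.
#' @export
comparisonDesign <- function(label, target, comparator = "full_database",
                             pairing = c("per_drug", "pooled")) {
  pairing <- match.arg(pairing)
  comparator <- as.character(comparator)
  if (!length(comparator)) stopConfig("comparator must be non-empty")
  if (target %in% comparator)
    stopConfig("target drug cannot be its own comparator")
  structure(list(label = label, target = target, comparator = comparator,
                 pairing = pairing), class = "ComparisonDesign")
}

#' Build contingency tables for a comparison design
#'
#' For every event group, counts the 2x2 cells behind the reporting odds
#' ratio: `a` target-drug cases flagged for the group, `b` target-drug
#' cases not flagged, and `c`/`d` the same for the comparator.  The full
#' database comparator is every deduplicated case whose primary suspect
#' is not the target drug; a case qualifying for both the target and a
#' comparator drug is assigned to the target only (and logged), so cells
#' never double-count.
#'
#' @param x A deduplicated [FaersReports-class] object (the full report
#'   universe, all drugs).
#' @param drugDict,eventDict Dictionaries covering every label used.
#' @param design A [comparisonDesign()] object.
#' @param groups Event groups to tabulate (default: all dictionary groups).
#' @param roles Drug roles defining drug membership.
#' @return data.frame with columns `design`, `target`, `comparator`,
#'   `event_group`, `a`, `b`, `c`, `d`.
#' @export
buildDesignTables <- function(x, drugDict, eventDict, design,
                              groups = labels(eventDict),
                              roles = "primary_suspect") {
  stopifnot(is(x, "FaersReports"), inherits(design, "ComparisonDesign"))
  if (!isTRUE(x@deduplicated))
    stopConfig("contingency tables are built from deduplicated reports")
  targetMask <- matchDrug(x, drugDict, design$target, roles = roles)
  if (!any(targetMask)) stopEmpty("no target reports")
  flags <- flagEvents(x, eventDict)

  if (identical(design$comparator, "full_database")) {
    compMasks <- list(full_database = !targetMask)
  } else {
    masks <- lapply(design$comparator, function(d) {
      m <- matchDrug(x, drugDict, d, roles = roles)
      overlap <- sum(m & targetMask)
      if (overlap)
        message(sprintf(
          "%d report(s) qualify for both '%s' and '%s'; assigned to target",
          overlap, design$target, d))
      m & !targetMask
    })
    names(masks) <- design$comparator
    compMasks <- if (design$pairing == "pooled")
      list(pooled = Reduce(`|`, masks)) else masks
  }

  rows <- list()
  for (comp in names(compMasks)) {
    cm <- compMasks[[comp]]
    for (g in groups) {
      f <- flags[, g]
      rows[[length(rows) + 1L]] <- data.frame(
        design = design$label, target = design$target, comparator = comp,
        event_group = g,
        a = sum(targetMask & f), b = sum(targetMask & !f),
        c = sum(cm & f), d = sum(cm & !f),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$design, out$comparator, out$event_group), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
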