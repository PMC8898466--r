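#' Accessors for faersignal containers
#'
#' `reports()`, `drugEntries()`, `reactions()` and `outcomes()` return the
#' underlying data.frames of a [FaersReports-class] (or of the reports
#' inside a [Cohort-class]); `labels()` and `dictTerms()` query a dictionary;
#' `eventFlags()` returns a cohort's event-group flag matrix; `strata()`
#' returns the stratified table of a [CohortSummary-class].
#'
#' @param object,x a faersignal S4 object.
#' @param label a dictionary label.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reports", function(object) standardGeneric("reports"))
#' @rdname accessors
#' @export
setGeneric("drugEntries", function(object) standardGeneric("drugEntries"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("outcomes", function(object) standardGeneric("outcomes"))
#' @rdname accessors
#' @export
setGeneric("isDeduplicated", function(object) standardGeneric("isDeduplicated"))
#' @rdname accessors
#' @export
setGeneric("dictTerms", function(object, label) standardGeneric("dictTerms"))
#' @rdname accessors
#' @export
setGeneric("eventFlags", function(object) standardGeneric("eventFlags"))
#' @rdname accessors
#' @export
setGeneric("strata", function(object) standardGeneric("strata"))

#' @rdname accessors
#' @export
setMethod("reports", "FaersReports", function(object) object@reports)
#' @rdname accessors
#' @export
setMethod("reports", "Cohort", function(object) object@reports@reports)
#' @rdname accessors
#' @export
setMethod("drugEntries", "FaersReports", function(object) object@drugs)
#' @rdname accessors
#' @export
setMethod("drugEntries", "Cohort", function(object) object@reports@drugs)
#' @rdname accessors
#' @export
setMethod("reactions", "FaersReports", function(object) object@reactions)
#' @rdname accessors
#' @export
setMethod("outcomes", "FaersReports", function(object) object@outcomes)
#' @rdname accessors
#' @export
setMethod("isDeduplicated", "FaersReports", function(object) object@deduplicated)
#' @rdname accessors
#' @export
setMethod("labels", "TermDictionary", function(object) names(object@entries))
#' @rdname accessors
#' @export
setMethod("dictTerms", "TermDictionary", function(object, label) {
  if (!label %in% names(object@entries))
    stopConfig(sprintf("label '%s' not in dictionary", label))
  object@entries[[label]]
})
#' @rdname accessors
#' @export
setMethod("eventFlags", "Cohort", function(object) object@flags)
#' @rdname accessors
#' @export
setMethod("strata", "CohortSummary", function(object) object@strata)

setMethod("show", "FaersTables", function(object) {
  cat("FaersTables (FAERS '$'-delimited dialect)\n")
  for (tab in c("demo", "drug", "reac", "ther", "outc"))
    cat(sprintf("  %s: %d rows, %d columns\n", toupper(tab),
                nrow(slot(object, tab)), ncol(slot(object, tab))))
})

setMethod("show", "FaersReports", function(object) {
  cat(sprintf("FaersReports: %d report(s), %d case(s)%s\n",
              nrow(object@reports), length(unique(object@reports$caseid)),
              if (isTRUE(object@deduplicated)) " [deduplicated]" else ""))
  cat(sprintf("  drug entries: %d | reaction PTs: %d | outcome codes: %d\n",
              nrow(object@drugs), nrow(object@reactions),
              nrow(object@outcomes)))
})

setMethod("show", "TermDictionary", function(object) {
  cat(sprintf("%s with %d label(s)\n", class(object),
              length(object@entries)))
  for (lab in names(object@entries))
    cat(sprintf("  %s (%d term%s)\n", lab, length(object@entries[[lab]]),
                if (length(object@entries[[lab]]) == 1L) "" else "s"))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort for target '%s': %d case(s)\n", object@target,
              nrow(object@reports@reports)))
  hits <- colSums(object@flags)
  for (g in colnames(object@flags))
    cat(sprintf("  %s: %d flagged\n", g, hits[[g]]))
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary ['%s']: %d event case(s), %d other-AE case(s)\n",
              object@group, object@nEvent, object@nOther))
  print(object@strata, row.names = FALSE)
})
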