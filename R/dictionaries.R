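.datatable.aware <- TRUE

parseDictionaryFile <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  heads <- grepl("^\\[.+\\]$", lines)
  if (!any(heads) || !heads[1L])
    stopFormat(sprintf("dictionary '%s': expected '[label]' block headers",
                       path))
  label <- cumsum(heads)
  labels <- sub("^\\[(.+)\\]$", "\\1", lines[heads])
  entries <- split(lines[!heads], factor(label[!heads], levels = seq_along(labels)))
  names(entries) <- labels
  lapply(entries, as.character)
}

#' Read drug / event dictionaries from plain-text config
#'
#' The file format is one block per label: a `[label]` header line
#' followed by one pattern (drug dictionary: generic or brand name) or
#' one MedDRA preferred term (event dictionary) per line.  Blank lines
#' and `#` comments are ignored.
#'
#' @param path Path to the dictionary file.
#' @return A [DrugDictionary][TermDictionary] or
#'   [EventDictionary][TermDictionary] object.
#' @seealso [defaultDrugDictionary()], [defaultEventDictionary()]
#' @export
readDrugDictionary <- function(path) {
  new("DrugDictionary", entries = parseDictionaryFile(path))
}

#' @rdname readDrugDictionary
#' @export
readEventDictionary <- function(path) {
  new("EventDictionary", entries = parseDictionaryFile(path))
}

#' Construct dictionaries from named lists
#'
#' @param entries Named list: label -> character vector of name patterns
#'   (drugs) or MedDRA preferred terms (events).
#' @return A dictionary object.
#' @export
#' @examples
#' drugDictionary(list(tigecycline = c("tigecycline", "tygacil")))
drugDictionary <- function(entries) new("DrugDictionary", entries = entries)

#' @rdname drugDictionary
#' @export
eventDictionary <- function(entries) new("EventDictionary", entries = entries)

#' Shipped default dictionaries
#'
#' Best-effort defaults for a tigecycline coagulation-dysfunction study:
#' the drug dictionary covers tigecycline and the comparator antibiotics
#' (anti-MRSA drugs vancomycin/linezolid/daptomycin, the carbapenems
#' meropenem and imipenem-cilastatin, and cefoperazone with the other
#' N-methylthiotetrazole side-chain cephalosporins) by generic and brand
#' name; the event dictionary maps MedDRA preferred terms to six named
#' coagulation event groups plus the umbrella group
#' `"coagulation_dysfunction"`.  They are starting points, not licensed
#' MedDRA content: replace them with study-specific files via
#' [readDrugDictionary()] for production use.
#'
#' @return A dictionary object.
#' @export
defaultDrugDictionary <- function() {
  readDrugDictionary(system.file("extdata", "drug_dictionary.txt",
                                 package = "faersignal", mustWork = TRUE))
}

#' @rdname defaultDrugDictionary
#' @export
defaultEventDictionary <- function() {
  readEventDictionary(system.file("extdata", "event_dictionary.txt",
                                  package = "faersignal", mustWork = TRUE))
}
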