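#' Construct a FaersTables object from data.frames
#'
#' All columns are coerced to character (FAERS fields are text; typing
#' happens at assembly).  Missing optional columns are not added; the
#' mandatory columns of each table must be present.
#'
#' @param demo,drug,reac,ther,outc data.frames with at least the mandatory
#'   columns of the corresponding FAERS table (see [FaersTables-class]).
#' @return A validated [FaersTables-class] object.
#' @export
#' @examples
#' ft <- FaersTables(
#'   demo = data.frame(primaryid = "11", caseid = "1", event_dt = "20190105",
#'                     sex = "M", age = "64", age_cod = "YR", occp_cod = "MD",
#'                     fda_dt = "20190201"),
#'   drug = data.frame(primaryid = "11", caseid = "1", drug_seq = "1",
#'                     role_cod = "PS", drugname = "TYGACIL",
#'                     prod_ai = "TIGECYCLINE", dose_amt = "100",
#'                     dose_unit = "MG", dose_freq = "QD"),
#'   reac = data.frame(primaryid = "11", caseid = "1", pt = "Hypofibrinogenaemia"),
#'   ther = data.frame(primaryid = "11", caseid = "1", dsg_seq = "1",
#'                     start_dt = "20190101"),
#'   outc = data.frame(primaryid = "11", caseid = "1", outc_cod = "HO"))
FaersTables <- function(demo, drug, reac, ther, outc) {
  asChar <- function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    df[] <- lapply(df, as.character)
    rownames(df) <- NULL
    df
  }
  new("FaersTables", demo = asChar(demo), drug = asChar(drug),
      reac = asChar(reac), ther = asChar(ther), outc = asChar(outc))
}

# Canonical file names used by writeQuarter and accepted by readQuarter
# when given a directory.
faersFileNames <- function() {
  c(demo = "DEMO.txt", drug = "DRUG.txt", reac = "REAC.txt",
    ther = "THER.txt", outc = "OUTC.txt")
}

parseDelimited <- function(path, table, sep = "$") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines))
    stopFormat(sprintf("%s: file '%s' is empty (header required)",
                       toupper(table), path))
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  header <- trimws(header)
  missing <- setdiff(FAERS_REQUIRED_COLUMNS[[table]], header)
  if (length(missing))
    stopFormat(sprintf("%s: missing mandatory column(s): %s",
                       toupper(table), paste(missing, collapse = ", ")))
  body <- lines[-1L]
  nfield <- length(header)
  if (!length(body)) {
    df <- as.data.frame(matrix(character(0), ncol = nfield,
                               dimnames = list(NULL, header)),
                        stringsAsFactors = FALSE)
    return(df)
  }
  parts <- strsplit(body, sep, fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad to the header width
  counts <- lengths(parts)
  short <- counts < nfield
  if (any(short)) {
    # only trailing-empty padding is legitimate: the raw line must contain
    # exactly nfield - 1 separators
    nsep <- lengths(gregexpr(sep, body[short], fixed = TRUE))
    nsep[!grepl(sep, body[short], fixed = TRUE)] <- 0L
    fixable <- nsep == nfield - 1L
    if (!all(fixable)) {
      bad <- which(short)[!fixable][1L]
      stopFormat(sprintf(
        "%s: line %d has %d field(s), expected %d",
        toupper(table), bad + 1L, nsep[!fixable][1L] + 1L, nfield))
    }
    parts[short] <- lapply(parts[short], function(p)
      c(p, rep("", nfield - length(p))))
  }
  if (any(counts > nfield)) {
    bad <- which(counts > nfield)[1L]
    stopFormat(sprintf("%s: line %d has %d field(s), expected %d",
                       toupper(table), bad + 1L, counts[bad], nfield))
  }
  mat <- matrix(unlist(parts, use.names = FALSE), ncol = nfield,
                byrow = TRUE, dimnames = list(NULL, header))
  as.data.frame(mat, stringsAsFactors = FALSE)
}

#' Read one FAERS quarter from '$'-delimited ASCII files
#'
#' Parses the five FAERS tables exactly as distributed: a header line of
#' column names, `'$'`-separated fields, no quoting or escaping.  Fields
#' are preserved verbatim as text (no type coercion); row counts equal
#' file line counts minus the header.
#'
#' @param paths Either a directory containing `DEMO.txt`, `DRUG.txt`,
#'   `REAC.txt`, `THER.txt`, `OUTC.txt` (as written by [writeQuarter()]),
#'   or a named character vector/list with elements `demo`, `drug`,
#'   `reac`, `ther`, `outc` giving the file of each table.
#' @param sep Field separator; FAERS uses `"$"`.
#' @return A [FaersTables-class] object.
#' @section Errors:
#' A missing mandatory column or an inconsistent field count raises a
#' format error (condition class `faersignalFormatError`) naming the
#' column or the offending line number.
#' @export
readQuarter <- function(paths, sep = "$") {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths))
    paths <- file.path(paths, faersFileNames())
  paths <- as.list(paths)
  if (is.null(names(paths)) || !all(names(FAERS_REQUIRED_COLUMNS) %in%
                                    names(paths)))
    names(paths) <- names(FAERS_REQUIRED_COLUMNS)[seq_along(paths)]
  tabs <- lapply(names(FAERS_REQUIRED_COLUMNS), function(tab) {
    path <- paths[[tab]]
    if (is.null(path) || !file.exists(path))
      stopFormat(sprintf("%s: file not found: %s", toupper(tab),
                         path %||% "<missing>"))
    parseDelimited(path, tab, sep = sep)
  })
  names(tabs) <- names(FAERS_REQUIRED_COLUMNS)
  new("FaersTables", demo = tabs$demo, drug = tabs$drug, reac = tabs$reac,
      ther = tabs$ther, outc = tabs$outc)
}

#' Write a FaersTables object as '$'-delimited ASCII files
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`, `OUTC.txt` under
#' `dir` in the FAERS quarterly dialect.  `readQuarter(writeQuarter(x))`
#' is the identity on field values.  FAERS does not escape its separator,
#' so a field value containing `'$'` is rejected rather than silently
#' corrupted.
#'
#' @param tables A [FaersTables-class] object.
#' @param dir Output directory (created if needed).
#' @param sep Field separator; FAERS uses `"$"`.
#' @return Invisibly, the named vector of files written.
#' @export
writeQuarter <- function(tables, dir, sep = "$") {
  stopifnot(is(tables, "FaersTables"))
  validObject(tables)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stopCondition("faersignalIOError", sprintf("cannot create '%s'", dir))
  files <- file.path(dir, faersFileNames())
  names(files) <- names(faersFileNames())
  for (tab in names(files)) {
    df <- slot(tables, tab)
    vals <- unlist(c(names(df), lapply(df, as.character)), use.names = FALSE)
    if (any(grepl(sep, vals, fixed = TRUE)))
      stopFormat(sprintf(
        "%s: field value contains the separator '%s'; FAERS has no escaping",
        toupper(tab), sep))
    lines <- c(paste(names(df), collapse = sep),
               if (nrow(df)) do.call(paste, c(df, sep = sep)))
    con <- file(files[[tab]], open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(lines, con, useBytes = TRUE)
    close(con)
    on.exit()
  }
  invisible(files)
}
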