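#' Read and validate a pipeline run configuration
#'
#' The YAML schema mirrors the pipeline stages: a seed, a target drug
#' label, drug/event dictionaries (`default` or a file path), exactly one
#' input source (`input: quarters: [dir, ...]` of FAERS ASCII quarters,
#' or `synthetic:` with generator settings), a list of comparison
#' designs, the zero-cell policy and an output directory.
#'
#' @param path Path to a YAML run configuration.
#' @return Validated list with class `"RunConfig"`.
#' @seealso [cmdSignal()], [cmdDescribe()], [cmdSimulate()]
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stopConfig(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  validateRunConfig(raw)
}

#' @rdname readRunConfig
#' @param config A raw configuration list (as parsed from YAML).
#' @export
validateRunConfig <- function(config) {
  if (is.null(config$target)) stopConfig("config needs a target drug label")
  hasInput <- !is.null(config$input)
  hasSynth <- !is.null(config$synthetic)
  if (hasInput == hasSynth)
    stopConfig("config needs exactly one of 'input' or 'synthetic'")
  config$seed <- as.integer(config$seed %||% 1L)
  config$zero_cell <- match.arg(config$zero_cell %||% "error",
                                c("error", "haldane"))
  config$output <- config$output %||% "faersignal-out"
  config$dictionaries <- config$dictionaries %||% list()
  if (is.null(config$designs) || !length(config$designs))
    stopConfig("config needs at least one comparison design")
  for (d in config$designs) {
    if (is.null(d$comparator)) stopConfig("each design needs a comparator")
  }
  structure(config, class = "RunConfig")
}

resolveDictionaries <- function(config) {
  dd <- config$dictionaries$drug %||% "default"
  ed <- config$dictionaries$event %||% "default"
  list(
    drug = if (identical(dd, "default")) defaultDrugDictionary()
           else readDrugDictionary(dd),
    event = if (identical(ed, "default")) defaultEventDictionary()
            else readEventDictionary(ed)
  )
}

resolveDesigns <- function(config) {
  lapply(config$designs, function(d) {
    comparator <- unlist(d$comparator)
    comparisonDesign(
      label = d$label %||% paste(comparator, collapse = "+"),
      target = config$target,
      comparator = comparator,
      pairing = d$pairing %||% "per_drug")
  })
}

simConfigFromRun <- function(config, eventDict) {
  s <- config$synthetic %||% list()
  args <- list(seed = config$seed, eventDict = eventDict)
  if (!is.null(s$n_background)) args$nBackground <- s$n_background
  if (!is.null(s$duplicate_fraction))
    args$duplicateFraction <- s$duplicate_fraction
  if (!is.null(s$partial_date_fraction))
    args$partialDateFraction <- s$partial_date_fraction
  if (!is.null(s$date_window)) args$dateWindow <- as.character(s$date_window)
  if (!is.null(s$background_event_prob))
    args$backgroundEventProb <- unlist(s$background_event_prob)
  if (!is.null(s$drugs))
    args$drugs <- lapply(s$drugs, function(d)
      drugSpec(label = d$label,
               nameVariants = unlist(d$name_variants) %||% toupper(d$label),
               nReports = d$n_reports,
               eventProb = unlist(d$event_prob),
               loadingFraction = d$loading_fraction %||% 0.21,
               maintenanceHighFraction = d$maintenance_high_fraction %||% 0.21,
               tteShape = d$tte_shape %||% 4.4885,
               tteScale = d$tte_scale %||% 2.3288))
  do.call(simConfig, args)
}

md5OfObject <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

loadReports <- function(config, dicts) {
  checksums <- list()
  if (!is.null(config$synthetic)) {
    sim <- simulateFaers(simConfigFromRun(config, dicts$event))
    tables <- sim$tables
  } else {
    dirs <- unlist(config$input$quarters)
    if (!length(dirs)) stopConfig("input.quarters must list directories")
    parts <- lapply(dirs, readQuarter)
    for (d in dirs) {
      fs <- file.path(d, faersFileNames())
      checksums[[d]] <- as.list(setNames(unname(tools::md5sum(fs)),
                                         basename(fs)))
    }
    tables <- if (length(parts) == 1L) parts[[1L]] else
      FaersTables(demo = do.call(rbind, lapply(parts, slot, "demo")),
                  drug = do.call(rbind, lapply(parts, slot, "drug")),
                  reac = do.call(rbind, lapply(parts, slot, "reac")),
                  ther = do.call(rbind, lapply(parts, slot, "ther")),
                  outc = do.call(rbind, lapply(parts, slot, "outc")))
  }
  list(tables = tables, checksums = checksums)
}

writeManifest <- function(config, outDir, checksums, counts) {
  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    seed = config$seed,
    config_hash = md5OfObject(unclass(config)),
    config = unclass(config),
    input_checksums = checksums,
    stage_counts = counts
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}

ensureOutDir <- function(outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stopCondition("faersignalIOError",
                  sprintf("cannot create output directory '%s'", outDir))
  outDir
}

#' Generate a synthetic quarter from a run configuration
#'
#' Writes the generated FAERS-format files under `<output>/quarter/`, the
#' planted ground truth as `truth.csv` and a reproducibility manifest.
#'
#' @param config A `"RunConfig"` (see [readRunConfig()]) with a
#'   `synthetic` section.
#' @return Invisibly, the output directory.
#' @export
cmdSimulate <- function(config) {
  config <- validateRunConfig(unclass(config))
  if (is.null(config$synthetic))
    stopConfig("cmdSimulate needs a 'synthetic' config section")
  dicts <- resolveDictionaries(config)
  sim <- simulateFaers(simConfigFromRun(config, dicts$event))
  outDir <- ensureOutDir(config$output)
  writeQuarter(sim$tables, file.path(outDir, "quarter"))
  utils::write.csv(sim$truth, file.path(outDir, "truth.csv"),
                   row.names = FALSE)
  counts <- list(reports = nrow(sim$tables@demo),
                 cases = length(unique(sim$tables@demo$caseid)))
  writeManifest(config, outDir, list(), counts)
  message(sprintf("simulate: %d report(s), %d case(s) -> %s",
                  counts$reports, counts$cases, outDir))
  invisible(outDir)
}

runPipelineCore <- function(config) {
  dicts <- resolveDictionaries(config)
  if (!config$target %in% labels(dicts$drug))
    stopConfig(sprintf("target '%s' not in the drug dictionary",
                       config$target))
  loaded <- loadReports(config, dicts)
  assembled <- assembleReports(loaded$tables)
  dedup <- deduplicateReports(assembled)
  counts <- list(reports_read = nrow(loaded$tables@demo),
                 reports_assembled = nrow(assembled@reports),
                 cases_after_dedup = nrow(dedup@reports))
  message(sprintf("pipeline: %d report(s) read, %d assembled, %d case(s) after deduplication",
                  counts$reports_read, counts$reports_assembled,
                  counts$cases_after_dedup))
  list(dicts = dicts, dedup = dedup, checksums = loaded$checksums,
       counts = counts)
}

#' Run the disproportionality pipeline
#'
#' Executes read (or simulate) -> assemble -> deduplicate -> contingency
#' tables per comparison design -> ROR/CI/signal evaluation, and writes
#' `signals.csv`, `signals.json` and a reproducibility manifest under the
#' configured output directory.
#'
#' @param config A `"RunConfig"` (see [readRunConfig()]).
#' @return Invisibly, the signal results data.frame.
#' @export
cmdSignal <- function(config) {
  config <- validateRunConfig(unclass(config))
  core <- runPipelineCore(config)
  designs <- resolveDesigns(config)
  tables <- do.call(rbind, lapply(designs, function(d)
    buildDesignTables(core$dedup, core$dicts$drug, core$dicts$event, d)))
  results <- evaluateDesigns(tables, zeroCell = config$zero_cell)
  counts <- c(core$counts,
              list(target_cohort = sum(results$a[1L] + results$b[1L]),
                   contingency_tables = nrow(results)))
  outDir <- ensureOutDir(config$output)
  utils::write.csv(results, file.path(outDir, "signals.csv"),
                   row.names = FALSE)
  jsonlite::write_json(results, file.path(outDir, "signals.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  writeManifest(config, outDir, core$checksums, counts)
  message(sprintf("signal: %d table(s) evaluated, %d signal(s) flagged",
                  nrow(results), sum(results$is_signal, na.rm = TRUE)))
  invisible(results)
}

#' Run the descriptive pipeline
#'
#' Builds the target cohort and writes the clinical-characteristics table
#' (`table1.csv`), the time-to-onset records and cumulative curve
#' (`tte_records.csv`, `tte_curve.csv`) and a manifest.  When no usable
#' time-to-onset record exists, an explicit `tte_warning.txt` is written
#' instead of the two files.
#'
#' @param config A `"RunConfig"` (see [readRunConfig()]).
#' @param group Event group summarised (default: the umbrella group).
#' @return Invisibly, the [CohortSummary-class].
#' @export
cmdDescribe <- function(config, group = "coagulation_dysfunction") {
  config <- validateRunConfig(unclass(config))
  core <- runPipelineCore(config)
  cohort <- buildCohort(core$dedup, core$dicts$drug, core$dicts$event,
                        config$target)
  if (!nrow(reports(cohort))) stopEmpty("no target reports")
  summary <- summarizeCohort(cohort, group = group)
  outDir <- ensureOutDir(config$output)
  tab <- strata(summary)
  utils::write.csv(tab, file.path(outDir, "table1.csv"), row.names = FALSE)
  tte <- tryCatch(timeToEvent(cohort, group = group),
                  faersignalEmptyError = function(e) e)
  if (inherits(tte, "condition")) {
    writeLines(conditionMessage(tte), file.path(outDir, "tte_warning.txt"))
  } else {
    utils::write.csv(tte$records, file.path(outDir, "tte_records.csv"),
                     row.names = FALSE)
    utils::write.csv(tte$curve, file.path(outDir, "tte_curve.csv"),
                     row.names = FALSE)
  }
  counts <- c(core$counts,
              list(target_cohort = nrow(reports(cohort)),
                   event_cases = summary@nEvent,
                   other_ae_cases = summary@nOther))
  writeManifest(config, outDir, core$checksums, counts)
  message(sprintf("describe: %d target case(s), %d with the event (case fatality %.2f%%)",
                  counts$target_cohort, summary@nEvent,
                  caseFatality(summary)))
  invisible(summary)
}
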