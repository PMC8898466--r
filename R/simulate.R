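# Background (non-coagulation) preferred terms padded onto every report,
# and the pool of invented background drug names.  Neither collides with
# the shipped dictionaries.
BACKGROUND_PTS <- c("Nausea", "Vomiting", "Headache", "Diarrhoea", "Rash",
                    "Pyrexia", "Dizziness", "Fatigue", "Pruritus",
                    "Dyspnoea", "Abdominal pain", "Insomnia")

checkProb <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopConfig(sprintf("%s must be probabilities in [0, 1]", what))
  invisible(p)
}

#' Specify one simulated drug arm
#'
#' @param label Drug label (should match a drug-dictionary label so the
#'   cohort builder can recover the arm).
#' @param nameVariants Character vector of names reported for the drug
#'   (generic + brands); the report draws one uniformly, and the first is
#'   used as the active-ingredient field.
#' @param nReports Number of reports with this drug as primary suspect.
#' @param eventProb Named probabilities of hitting each event group,
#'   independent across groups within a report.
#' @param loadingFraction Fraction of reports starting therapy with a
#'   loading dose (first-day dose = twice the maintenance daily dose).
#' @param maintenanceHighFraction Fraction on a high maintenance regimen
#'   (200 mg/day; the rest run at the standard 100 mg/day).
#' @param tteShape,tteScale Gamma parameters (days) of the onset-time
#'   distribution; the defaults give integer-day quartiles 7/10/13.
#' @return list with class `"DrugSpec"`.
#' @export
drugSpec <- function(label, nameVariants = toupper(label), nReports,
                     eventProb, loadingFraction = 0.21,
                     maintenanceHighFraction = 0.21,
                     tteShape = 4.4885, tteScale = 2.3288) {
  checkProb(eventProb, sprintf("eventProb[%s]", label))
  checkProb(c(loadingFraction, maintenanceHighFraction),
            "dose-regimen fractions")
  if (is.null(names(eventProb)) || any(!nzchar(names(eventProb))))
    stopConfig("eventProb must be named by event group")
  if (nReports < 0) stopConfig("nReports must be >= 0")
  structure(list(label = label, nameVariants = nameVariants,
                 nReports = as.integer(nReports), eventProb = eventProb,
                 loadingFraction = loadingFraction,
                 maintenanceHighFraction = maintenanceHighFraction,
                 tteShape = tteShape, tteScale = tteScale),
            class = "DrugSpec")
}

#' Simulation configuration
#'
#' Declares a synthetic FAERS-shaped dataset: background reports plus one
#' arm per drug of interest, with planted event-group probabilities (and
#' therefore known true reporting odds ratios), demographics, therapy and
#' onset date structure, case-version duplicates and partial dates.  The
#' defaults emulate a 2005-2020 tigecycline coagulation study: a target
#' arm of 1517 reports with ~14.7% coagulation events, comparator
#' antibiotic arms, gamma onset times with integer-day quartiles 7/10/13,
#' and Table-1-like demographic and outcome mixes.
#'
#' @param seed Integer seed; all generation flows from it.
#' @param nBackground Number of background (other-drug) reports.
#' @param drugs List of [drugSpec()] arms.
#' @param backgroundEventProb Named event-group probabilities for
#'   background reports.
#' @param demographics List: `maleFraction`, `femaleFraction` (remainder
#'   missing), `ageMissingFraction`, `ageMean`, `ageSD` (years),
#'   `reporterHealthcare`, `reporterNonHealthcare` (remainder unknown),
#'   `outcomeProb` (named per-outcome probabilities, independent).
#' @param dateWindow Character `c(start, end)` as `YYYYMMDD`; receipt
#'   dates fall inside it.
#' @param duplicateFraction Fraction of cases additionally emitted as a
#'   second report version (distinct `primaryid`, later receipt date,
#'   identical payload), exercising deduplication.
#' @param partialDateFraction Fraction of event dates truncated to month
#'   precision (`YYYYMM`), exercising the partial-date policy.
#' @param eventDict [EventDictionary][TermDictionary] whose subgroup PT
#'   sets the generator draws reported PTs from.
#' @return list with class `"SimulationConfig"`.
#' @seealso [simulateFaers()], [trueRor()]
#' @export
simConfig <- function(seed = 1L,
                      nBackground = 20000L,
                      drugs = defaultDrugArms(),
                      backgroundEventProb = c(
                        thrombocytopenia = 0.028, hypofibrinogenaemia = 5e-04,
                        coagulopathy = 0.004, aptt_prolonged = 0.002,
                        inr_increased = 0.004, pt_prolonged = 0.002),
                      demographics = list(
                        maleFraction = 0.42, femaleFraction = 0.38,
                        ageMissingFraction = 0.30, ageMean = 58, ageSD = 17,
                        reporterHealthcare = 0.60,
                        reporterNonHealthcare = 0.35,
                        outcomeProb = c(death = 0.25, life_threatening = 0.05,
                                        disability = 0.01,
                                        hospitalization = 0.22,
                                        required_intervention = 0.003,
                                        other_serious = 0.33)),
                      dateWindow = c("20050101", "20201231"),
                      duplicateFraction = 0.05,
                      partialDateFraction = 0.10,
                      eventDict = defaultEventDictionary()) {
  checkProb(backgroundEventProb, "backgroundEventProb")
  checkProb(c(demographics$maleFraction, demographics$femaleFraction,
              demographics$ageMissingFraction,
              demographics$reporterHealthcare,
              demographics$reporterNonHealthcare,
              demographics$outcomeProb),
            "demographic mix")
  if (demographics$maleFraction + demographics$femaleFraction > 1)
    stopConfig("sex fractions sum above 1")
  if (demographics$reporterHealthcare + demographics$reporterNonHealthcare > 1)
    stopConfig("reporter fractions sum above 1")
  checkProb(c(duplicateFraction, partialDateFraction),
            "duplicate/partial-date fractions")
  if (nBackground < 0) stopConfig("nBackground must be >= 0")
  if (!length(drugs)) stopConfig("at least one drug arm is required")
  if (inherits(drugs, "DrugSpec")) drugs <- list(drugs)
  labs <- vapply(drugs, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stopConfig("drug arm labels must be unique")
  names(drugs) <- labs
  structure(list(seed = as.integer(seed), nBackground = as.integer(nBackground),
                 drugs = drugs, backgroundEventProb = backgroundEventProb,
                 demographics = demographics, dateWindow = dateWindow,
                 duplicateFraction = duplicateFraction,
                 partialDateFraction = partialDateFraction,
                 eventDict = eventDict),
            class = "SimulationConfig")
}

#' Default drug arms of the shipped simulation
#'
#' One target arm (tigecycline, 1517 reports, overall coagulation event
#' probability ~0.147) and six comparator antibiotic arms whose planted
#' probabilities put their true RORs against the target in the ranges a
#' real spontaneous-report contrast would show (linezolid above the
#' target for thrombocytopenia, cefoperazone above it overall, the
#' others below).
#'
#' @return list of [drugSpec()] objects.
#' @export
defaultDrugArms <- function() {
  list(
    drugSpec("tigecycline", c("TIGECYCLINE", "TYGACIL"), 1517,
             eventProb = c(thrombocytopenia = 0.085,
                           hypofibrinogenaemia = 0.030,
                           coagulopathy = 0.020, aptt_prolonged = 0.008,
                           inr_increased = 0.006, pt_prolonged = 0.008)),
    drugSpec("vancomycin", c("VANCOMYCIN", "VANCOCIN"), 4000,
             eventProb = c(thrombocytopenia = 0.035,
                           hypofibrinogenaemia = 0.002,
                           coagulopathy = 0.010, aptt_prolonged = 0.003,
                           inr_increased = 0.004, pt_prolonged = 0.003)),
    drugSpec("linezolid", c("LINEZOLID", "ZYVOX"), 3000,
             eventProb = c(thrombocytopenia = 0.150,
                           hypofibrinogenaemia = 0.002,
                           coagulopathy = 0.010, aptt_prolonged = 0.003,
                           inr_increased = 0.004, pt_prolonged = 0.003)),
    drugSpec("daptomycin", c("DAPTOMYCIN", "CUBICIN"), 2500,
             eventProb = c(thrombocytopenia = 0.030,
                           hypofibrinogenaemia = 0.001,
                           coagulopathy = 0.008, aptt_prolonged = 0.004,
                           inr_increased = 0.006, pt_prolonged = 0.004)),
    drugSpec("meropenem", c("MEROPENEM", "MERREM"), 3000,
             eventProb = c(thrombocytopenia = 0.100,
                           hypofibrinogenaemia = 0.003,
                           coagulopathy = 0.020, aptt_prolonged = 0.004,
                           inr_increased = 0.006, pt_prolonged = 0.004)),
    drugSpec("imipenem-cilastatin", c("IMIPENEM", "PRIMAXIN"), 1500,
             eventProb = c(thrombocytopenia = 0.065,
                           hypofibrinogenaemia = 0.002,
                           coagulopathy = 0.015, aptt_prolonged = 0.003,
                           inr_increased = 0.005, pt_prolonged = 0.003)),
    drugSpec("cefoperazone", c("CEFOPERAZONE", "SULPERAZON"), 800,
             eventProb = c(thrombocytopenia = 0.090,
                           hypofibrinogenaemia = 0.004,
                           coagulopathy = 0.040, aptt_prolonged = 0.015,
                           inr_increased = 0.040, pt_prolonged = 0.040)))
}

# Probability that a report of an arm hits `group`: the configured
# per-group probability, or (for the umbrella group, whose flag is the
# union of subgroup hits drawn independently) 1 - prod(1 - p).
armGroupProb <- function(eventProb, group) {
  if (group %in% names(eventProb)) return(unname(eventProb[group]))
  if (identical(group, "coagulation_dysfunction"))
    return(1 - prod(1 - eventProb))
  0
}

#' True reporting odds ratio planted by a configuration
#'
#' The odds ratio implied by the configured event probabilities:
#' `[p_d/(1-p_d)] / [p_c/(1-p_c)]`, where `p_d` is the target arm's
#' event-group probability and `p_c` the comparator's.  The
#' `"full_database"` comparator uses the report-count-weighted mixture
#' probability over every non-target arm (background included);
#' `"background"` uses the background probabilities alone.
#'
#' @param config A [simConfig()] object.
#' @param drug Target arm label.
#' @param eventGroup Event-group label (a configured group, or
#'   `"coagulation_dysfunction"` for the union of the configured groups).
#' @param comparator `"full_database"`, `"background"`, or another
#'   configured arm label.
#' @return Positive real.
#' @export
#' @examples
#' cfg <- simConfig(drugs = list(
#'   drugSpec("a", "A", 100, eventProb = c(g = 0.2)),
#'   drugSpec("b", "B", 100, eventProb = c(g = 0.1))),
#'   backgroundEventProb = c(g = 0.1))
#' trueRor(cfg, "a", "g", "b")  # 2.25
trueRor <- function(config, drug, eventGroup, comparator = "full_database") {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!drug %in% names(config$drugs))
    stopConfig(sprintf("drug arm '%s' not configured", drug))
  pd <- armGroupProb(config$drugs[[drug]]$eventProb, eventGroup)
  if (identical(comparator, "full_database")) {
    others <- setdiff(names(config$drugs), drug)
    ns <- c(config$nBackground,
            vapply(config$drugs[others], `[[`, integer(1), "nReports"))
    ps <- c(armGroupProb(config$backgroundEventProb, eventGroup),
            vapply(others, function(o)
              armGroupProb(config$drugs[[o]]$eventProb, eventGroup),
              numeric(1)))
    if (sum(ns) == 0) stopConfig("full-database comparator is empty")
    pc <- sum(ns * ps) / sum(ns)
  } else if (identical(comparator, "background")) {
    pc <- armGroupProb(config$backgroundEventProb, eventGroup)
  } else {
    if (!comparator %in% names(config$drugs))
      stopConfig(sprintf("comparator arm '%s' not configured", comparator))
    pc <- armGroupProb(config$drugs[[comparator]]$eventProb, eventGroup)
  }
  if (pc <= 0 || pc >= 1 || pd >= 1)
    stopCondition("faersignalUndefinedROR",
                  "undefined odds: event probability at 0 or 1")
  (pd / (1 - pd)) / (pc / (1 - pc))
}

#' Generate a synthetic FAERS-shaped dataset
#'
#' Draws one report per configured arm slot: a primary-suspect drug
#' entry (with loading/maintenance dose structure and therapy start
#' dates), event-group hits per the planted probabilities (each hit
#' emits one uniformly chosen preferred term of that group plus 1-3
#' background PTs), demographics, outcome codes, and an event date equal
#' to therapy start plus a gamma onset time rounded to whole days.  A
#' configured fraction of cases is emitted twice (same `caseid`, new
#' `primaryid`, later receipt date, identical payload) and a fraction of
#' event dates is truncated to month precision.  Deterministic given the
#' config (which carries the seed).
#'
#' @param config A [simConfig()] object.
#' @return list with `tables` (a [FaersTables-class]), `truth` (data.frame
#'   `drug`, `event_group`, `comparator`, `true_ror` for every configured
#'   arm pair and the full-database comparator) and `cases` (per-case
#'   bookkeeping: arm, planted event-group flags, dose regimen, onset
#'   days) for oracle-style checks.
#' @export
simulateFaers <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  groups <- names(config$drugs[[1L]]$eventProb)
  for (spec in config$drugs)
    if (!identical(sort(names(spec$eventProb)), sort(groups)))
      stopConfig("all drug arms must configure the same event groups")
  if (!identical(sort(names(config$backgroundEventProb)), sort(groups)))
    stopConfig("backgroundEventProb must cover the configured event groups")
  dictGroups <- labels(config$eventDict)
  missingGroups <- setdiff(groups, dictGroups)
  if (length(missingGroups))
    stopConfig(sprintf("event group(s) not in the event dictionary: %s",
                       paste(missingGroups, collapse = ", ")))

  arms <- c("background", names(config$drugs))
  nPer <- c(config$nBackground,
            vapply(config$drugs, `[[`, integer(1), "nReports"))
  n <- sum(nPer)
  if (n == 0) stopConfig("configuration generates no reports")
  arm <- rep(arms, nPer)
  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  dem <- config$demographics
  sex <- sample(c("M", "F", ""), n, replace = TRUE,
                prob = c(dem$maleFraction, dem$femaleFraction,
                         1 - dem$maleFraction - dem$femaleFraction))
  ageVal <- pmin(pmax(round(stats::rnorm(n, dem$ageMean, dem$ageSD)), 18), 99)
  ageMissing <- stats::runif(n) < dem$ageMissingFraction
  age <- ifelse(ageMissing, "", as.character(ageVal))
  age_cod <- ifelse(ageMissing, "", "YR")
  occp <- sample(c("MD", "PH", "CN", "LW", ""), n, replace = TRUE,
                 prob = c(dem$reporterHealthcare / 2,
                          dem$reporterHealthcare / 2,
                          dem$reporterNonHealthcare / 2,
                          dem$reporterNonHealthcare / 2,
                          1 - dem$reporterHealthcare -
                            dem$reporterNonHealthcare))

  # event-group hits: per-arm probability matrix, independent groups
  probMat <- rbind(config$backgroundEventProb[groups],
                   do.call(rbind, lapply(config$drugs, function(s)
                     s$eventProb[groups])))
  rownames(probMat) <- arms
  armIdx <- match(arm, arms)
  hits <- matrix(stats::runif(n * length(groups)) <
                   probMat[armIdx, , drop = FALSE],
                 nrow = n, dimnames = list(NULL, groups))

  # therapy start, onset, event and receipt dates
  winStart <- as.Date(config$dateWindow[1L], "%Y%m%d")
  winEnd <- as.Date(config$dateWindow[2L], "%Y%m%d")
  if (is.na(winStart) || is.na(winEnd) || winStart >= winEnd)
    stopConfig("dateWindow must be two YYYYMMDD dates, start < end")
  start <- winStart + floor(stats::runif(n) *
                              (as.numeric(winEnd - winStart) - 120))
  shape <- c(4.4885, vapply(config$drugs, `[[`, numeric(1), "tteShape"))
  scale <- c(2.3288, vapply(config$drugs, `[[`, numeric(1), "tteScale"))
  onset <- as.integer(round(stats::rgamma(n, shape = shape[armIdx],
                                          scale = scale[armIdx])))
  eventDate <- start + onset
  receipt <- eventDate + 7L + floor(stats::runif(n) * 84)

  # reactions: one PT per group hit + 1-3 background PTs
  reacRows <- vector("list", length(groups) + 1L)
  for (gi in seq_along(groups)) {
    idx <- which(hits[, gi])
    pool <- dictTerms(config$eventDict, groups[gi])
    reacRows[[gi]] <- data.frame(
      primaryid = primaryid[idx],
      pt = pool[1L + floor(stats::runif(length(idx)) * length(pool))],
      stringsAsFactors = FALSE)
  }
  nBgPts <- 1L + floor(stats::runif(n) * 3)
  bgIdx <- rep(seq_len(n), nBgPts)
  reacRows[[length(groups) + 1L]] <- data.frame(
    primaryid = primaryid[bgIdx],
    pt = BACKGROUND_PTS[1L + floor(stats::runif(length(bgIdx)) *
                                     length(BACKGROUND_PTS))],
    stringsAsFactors = FALSE)
  reac <- unique(do.call(rbind, reacRows))

  # outcomes: independent per-outcome draws
  ocNames <- names(dem$outcomeProb)
  ocCode <- names(OUTCOME_CODES)[match(ocNames, OUTCOME_CODES)]
  outcRows <- lapply(seq_along(ocNames), function(oi) {
    idx <- which(stats::runif(n) < dem$outcomeProb[oi])
    data.frame(primaryid = primaryid[idx],
               outc_cod = rep(ocCode[oi], length(idx)),
               stringsAsFactors = FALSE)
  })
  outc <- do.call(rbind, outcRows)

  # drug entries: background = single 100 mg entry; configured arms carry
  # the planted loading/maintenance structure
  isBg <- arm == "background"
  nBgNames <- 200L
  bgNamePool <- sprintf("BACKGROUND AGENT %03d", seq_len(nBgNames))
  variantOf <- function(lab, k) {
    v <- config$drugs[[lab]]$nameVariants
    v[1L + floor(stats::runif(k) * length(v))]
  }
  drugname <- character(n)
  prod_ai <- character(n)
  drugname[isBg] <- bgNamePool[1L + floor(stats::runif(sum(isBg)) * nBgNames)]
  prod_ai[isBg] <- drugname[isBg]
  for (lab in names(config$drugs)) {
    idx <- which(arm == lab)
    drugname[idx] <- variantOf(lab, length(idx))
    prod_ai[idx] <- toupper(config$drugs[[lab]]$nameVariants[1L])
  }
  loadFrac <- c(0, vapply(config$drugs, `[[`, numeric(1), "loadingFraction"))
  highFrac <- c(0, vapply(config$drugs, `[[`, numeric(1),
                          "maintenanceHighFraction"))
  loading <- stats::runif(n) < loadFrac[armIdx]
  high <- stats::runif(n) < highFrac[armIdx]
  maintDose <- ifelse(high, 200, 100)
  firstDose <- ifelse(isBg, 100, ifelse(loading, 2 * maintDose, maintDose))
  loading[isBg] <- FALSE

  entry1 <- data.frame(primaryid = primaryid, drug_seq = "1",
                       role_cod = "PS", drugname = drugname,
                       prod_ai = prod_ai,
                       dose_amt = as.character(firstDose),
                       dose_unit = "MG", dose_freq = "QD",
                       start = start, stringsAsFactors = FALSE)
  li <- which(loading & !isBg)
  entry2 <- data.frame(primaryid = primaryid[li],
                       drug_seq = rep("2", length(li)),
                       role_cod = rep("PS", length(li)),
                       drugname = drugname[li],
                       prod_ai = prod_ai[li],
                       dose_amt = as.character(maintDose[li]),
                       dose_unit = rep("MG", length(li)),
                       dose_freq = rep("QD", length(li)),
                       start = start[li] + 1L, stringsAsFactors = FALSE)
  drugAll <- rbind(entry1, entry2)

  # partial event dates
  partial <- stats::runif(n) < config$partialDateFraction
  event_dt <- formatFaersDate(eventDate)
  event_dt[partial] <- substr(event_dt[partial], 1L, 6L)

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     event_dt = event_dt, sex = sex, age = age,
                     age_cod = age_cod, occp_cod = occp,
                     fda_dt = formatFaersDate(receipt),
                     stringsAsFactors = FALSE)
  drugTab <- data.frame(primaryid = drugAll$primaryid,
                        caseid = caseid[match(drugAll$primaryid, primaryid)],
                        drug_seq = drugAll$drug_seq,
                        role_cod = drugAll$role_cod,
                        drugname = drugAll$drugname,
                        prod_ai = drugAll$prod_ai,
                        dose_amt = drugAll$dose_amt,
                        dose_unit = drugAll$dose_unit,
                        dose_freq = drugAll$dose_freq,
                        stringsAsFactors = FALSE)
  reacTab <- data.frame(primaryid = reac$primaryid,
                        caseid = caseid[match(reac$primaryid, primaryid)],
                        pt = reac$pt, stringsAsFactors = FALSE)
  therTab <- data.frame(primaryid = drugAll$primaryid,
                        caseid = caseid[match(drugAll$primaryid, primaryid)],
                        dsg_seq = drugAll$drug_seq,
                        start_dt = formatFaersDate(drugAll$start),
                        stringsAsFactors = FALSE)
  outcTab <- data.frame(primaryid = outc$primaryid,
                        caseid = caseid[match(outc$primaryid, primaryid)],
                        outc_cod = outc$outc_cod, stringsAsFactors = FALSE)

  # duplicate versions: identical payload, new primaryid, later receipt
  nDup <- floor(config$duplicateFraction * n)
  if (nDup > 0) {
    dupIdx <- sort(sample.int(n, nDup))
    dupOld <- primaryid[dupIdx]
    dupNew <- paste0(caseid[dupIdx], "2")
    dupDemo <- demo[dupIdx, , drop = FALSE]
    dupDemo$primaryid <- dupNew
    dupDemo$fda_dt <- formatFaersDate(receipt[dupIdx] + 30L)
    demo <- rbind(demo, dupDemo)
    dupChild <- function(df) {
      d <- df[df$primaryid %in% dupOld, , drop = FALSE]
      d$primaryid <- dupNew[match(d$primaryid, dupOld)]
      rbind(df, d)
    }
    drugTab <- dupChild(drugTab)
    reacTab <- dupChild(reacTab)
    therTab <- dupChild(therTab)
    outcTab <- dupChild(outcTab)
  }

  tables <- FaersTables(demo = demo, drug = drugTab, reac = reacTab,
                        ther = therTab, outc = outcTab)

  truthGroups <- c(groups, "coagulation_dysfunction")
  truthRows <- list()
  for (lab in names(config$drugs)) {
    comps <- c("full_database", "background",
               setdiff(names(config$drugs), lab))
    for (comp in comps) for (g in truthGroups) {
      tr <- tryCatch(trueRor(config, lab, g, comp), error = function(e) NA_real_)
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        drug = lab, event_group = g, comparator = comp, true_ror = tr,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truthRows)

  cases <- data.frame(caseid = caseid, arm = arm, sex = sex,
                      loading = loading,
                      maintenance = ifelse(isBg, NA_character_,
                                           ifelse(high, "high", "standard")),
                      onset_days = onset,
                      event_date_partial = partial,
                      stringsAsFactors = FALSE)
  for (g in groups) cases[[g]] <- hits[, g]
  cases$coagulation_dysfunction <- rowSums(hits) > 0

  list(tables = tables, truth = truth, cases = cases)
}
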