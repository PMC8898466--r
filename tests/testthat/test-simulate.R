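test_that("true ROR follows the configured odds", {
  cfg <- function(pd, pc) simConfig(
    seed = 1, nBackground = 100,
    drugs = list(drugSpec("a", "A", 100, eventProb = c(g = pd)),
                 drugSpec("b", "B", 100, eventProb = c(g = pc))),
    backgroundEventProb = c(g = pc),
    eventDict = eventDictionary(list(g = "Coagulopathy")))
  expect_equal(trueRor(cfg(0.5, 0.5), "a", "g", "b"), 1, tolerance = 1e-12)
  expect_equal(trueRor(cfg(0.2, 0.1), "a", "g", "b"),
               (0.2 / 0.8) / (0.1 / 0.9), tolerance = 1e-12)  # 2.25
  expect_equal(trueRor(cfg(0.9, 0.1), "a", "g", "b"), 81, tolerance = 1e-12)
  expect_error(trueRor(cfg(0.5, 0), "a", "g", "b"),
               class = "faersignalUndefinedROR")
  # full-database comparator mixes the non-target arms by report count
  mix <- simConfig(seed = 1, nBackground = 300,
                   drugs = list(drugSpec("a", "A", 100, eventProb = c(g = 0.4)),
                                drugSpec("b", "B", 100, eventProb = c(g = 0.2))),
                   backgroundEventProb = c(g = 0.1),
                   eventDict = eventDictionary(list(g = "Coagulopathy")))
  pc <- (300 * 0.1 + 100 * 0.2) / 400
  expect_equal(trueRor(mix, "a", "g"), (0.4 / 0.6) / (pc / (1 - pc)),
               tolerance = 1e-12)
})

test_that("generation is deterministic and counts are exact", {
  cfg <- simConfig(seed = 99, nBackground = 60,
                   drugs = list(drugSpec("a", "AA", 40,
                                         eventProb = c(g = 0.3))),
                   backgroundEventProb = c(g = 0.1),
                   eventDict = eventDictionary(list(g = "Coagulopathy")),
                   duplicateFraction = 0, partialDateFraction = 0)
  s1 <- simulateFaers(cfg)
  s2 <- simulateFaers(cfg)
  expect_identical(s1$tables@demo, s2$tables@demo)
  expect_identical(s1$tables@drug, s2$tables@drug)
  expect_identical(s1$tables@reac, s2$tables@reac)
  expect_identical(s1$cases, s2$cases)
  # no duplicates, no partial dates: exact counts
  expect_identical(nrow(s1$tables@demo), 100L)
  expect_identical(length(unique(s1$tables@demo$caseid)), 100L)
  expect_true(all(nchar(s1$tables@demo$event_dt) == 8L))
  # different seeds diverge
  s3 <- simulateFaers(simConfig(seed = 100, nBackground = 60,
                                drugs = cfg$drugs,
                                backgroundEventProb = c(g = 0.1),
                                eventDict = cfg$eventDict,
                                duplicateFraction = 0,
                                partialDateFraction = 0))
  expect_false(identical(s1$tables@demo, s3$tables@demo))
})

test_that("duplicates differ only in primaryid and receipt date", {
  cfg <- recoveryConfig(8, nPerArm = 400, duplicateFraction = 0.2,
                        partialDateFraction = 0)
  sim <- simulateFaers(cfg)
  demo <- sim$tables@demo
  dupCases <- demo$caseid[duplicated(demo$caseid)]
  expect_identical(length(dupCases), as.integer(0.2 * 800))
  for (cid in dupCases[1:5]) {
    v <- demo[demo$caseid == cid, ]
    v <- v[order(v$primaryid), ]
    expect_identical(nrow(v), 2L)
    same <- setdiff(names(demo), c("primaryid", "fda_dt"))
    expect_identical(unname(unlist(v[1, same])), unname(unlist(v[2, same])))
    expect_true(v$fda_dt[2] > v$fda_dt[1])
  }
})

test_that("partial-date and probability configuration are enforced", {
  expect_error(simConfig(backgroundEventProb = c(g = 1.2),
                         drugs = list(drugSpec("a", "A", 10,
                                               eventProb = c(g = 0.1)))),
               class = "faersignalConfigError")
  expect_error(drugSpec("a", "A", 10, eventProb = c(g = -0.1)),
               class = "faersignalConfigError")
  expect_error(simConfig(demographics = list(
    maleFraction = 0.7, femaleFraction = 0.7, ageMissingFraction = 0,
    ageMean = 60, ageSD = 10, reporterHealthcare = 0.5,
    reporterNonHealthcare = 0.3,
    outcomeProb = c(death = 0.1))), class = "faersignalConfigError")

  cfg <- recoveryConfig(3, nPerArm = 500, duplicateFraction = 0,
                        partialDateFraction = 0.3)
  sim <- simulateFaers(cfg)
  frac <- mean(nchar(sim$tables@demo$event_dt) == 6L)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.4)
})

test_that("a null effect yields an empirical ROR near 1 at large n", {
  cfg <- simConfig(seed = 12, nBackground = 10000,
                   drugs = list(drugSpec("tigecycline", "TIGECYCLINE", 10000,
                                         eventProb = c(g = 0.5))),
                   backgroundEventProb = c(g = 0.5),
                   eventDict = eventDictionary(list(g = "Coagulopathy")),
                   duplicateFraction = 0, partialDateFraction = 0)
  sim <- simulateFaers(cfg)
  dd <- deduplicateReports(assembleReports(sim$tables))
  tab <- buildDesignTables(dd, recoveryDrugDict(), cfg$eventDict,
                           comparisonDesign("fd", "tigecycline",
                                            "full_database"), groups = "g")
  res <- evaluateDesigns(tab)
  # true ROR is 1; 20,000 reports keep the estimate within Monte-Carlo error
  expect_gt(res$ror, 0.9)
  expect_lt(res$ror, 1.1)
  expect_true(res$ci_low < 1 & 1 < res$ci_high)
})

test_that("planted onset distribution reaches the descriptive module intact", {
  cfg <- recoveryConfig(21, nPerArm = 2000, duplicateFraction = 0,
                        partialDateFraction = 0)
  sim <- simulateFaers(cfg)
  dd <- deduplicateReports(assembleReports(sim$tables))
  co <- buildCohort(dd, recoveryDrugDict(), cfg$eventDict, "tigecycline")
  tte <- timeToEvent(co, group = "coag")
  # configured gamma: integer-day median 10, quartiles near 7 and 13
  expect_gte(tte$median, 9)
  expect_lte(tte$median, 11)
  # onset days equal the generator's planted values case by case
  planted <- sim$cases$onset_days[match(tte$records$caseid, sim$cases$caseid)]
  expect_identical(tte$records$onset_days, as.integer(planted))
})
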