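test_that("deduplication keeps the latest receipt, ties to greatest primaryid", {
  rep <- assembleReports(tinyTables())
  dd <- deduplicateReports(rep)
  expect_true(isDeduplicated(dd))
  df <- reports(dd)
  expect_identical(nrow(df), 3L)
  # case 1 had versions 101 (20190201) and 102 (20190315): later survives
  expect_identical(df$primaryid[df$caseid == "1"], "102")

  # receipt-date tie broken by greatest primaryid, digit-string order
  tt <- tinyTables()
  tt@demo$fda_dt[1:2] <- "20190201"
  tt@demo$primaryid[1:2] <- c("99", "100")
  tt@drug$primaryid[1:2] <- c("99", "100")
  tt@reac$primaryid[1:4] <- c("99", "99", "100", "100")
  tt@ther$primaryid[1:2] <- c("99", "100")
  tt@outc$primaryid[1:3] <- c("99", "100", "100")
  df2 <- reports(deduplicateReports(assembleReports(tt)))
  expect_identical(df2$primaryid[df2$caseid == "1"], "100")

  # idempotent, and identity when all caseids are unique
  expect_identical(reports(deduplicateReports(dd)), df)
})

test_that("randomised duplicate injection dedups to the configured case count", {
  cfg <- simConfig(seed = 42, nBackground = 400,
                   drugs = defaultDrugArms()[1],
                   duplicateFraction = 0.25, partialDateFraction = 0)
  sim <- simulateFaers(cfg)
  nCases <- nrow(sim$cases)
  expect_gt(nrow(sim$tables@demo), nCases)
  dd <- deduplicateReports(assembleReports(sim$tables))
  expect_identical(nrow(reports(dd)), nCases)
  # the surviving version of a duplicated case is the later receipt
  dup <- sim$tables@demo$caseid[duplicated(sim$tables@demo$caseid)]
  surv <- reports(dd)
  expect_true(all(endsWith(surv$primaryid[surv$caseid %in% dup], "2")))
})

test_that("drug matching is word-boundary, case-insensitive, role-filtered", {
  rep <- deduplicateReports(assembleReports(tinyTables()))
  dict <- tinyDrugDict()
  m <- matchDrug(rep, dict, "tigecycline")
  df <- reports(rep)
  expect_true(m[df$caseid == "1"])                 # TYGACIL, PS
  expect_false(m[df$caseid == "2"])                # vancomycin report
  expect_false(m[df$caseid == "3"])                # tigecycline concomitant only
  # widen the role filter and the concomitant entry matches
  m2 <- matchDrug(rep, dict, "tigecycline",
                  roles = c("primary_suspect", "concomitant"))
  expect_true(m2[df$caseid == "3"])                # "TIGECYCLINE 50MG VIAL"
  # no match inside a larger token
  tt <- tinyTables()
  tt@drug$drugname[3] <- "PROTIGECYCLINOL"
  tt@drug$prod_ai[3] <- "PROTIGECYCLINOL"
  m3 <- matchDrug(deduplicateReports(assembleReports(tt)), dict, "tigecycline")
  expect_false(m3[["201"]])
  expect_error(matchDrug(rep, dict, "daptomycin"),
               class = "faersignalConfigError")
})

test_that("event flags are report-level set intersections", {
  rep <- deduplicateReports(assembleReports(tinyTables()))
  flags <- flagEvents(rep, tinyEventDict())
  df <- reports(rep)
  r1 <- flags[df$caseid == "1", ]
  expect_identical(unname(r1), c(FALSE, TRUE, TRUE))
  expect_identical(unname(flags[df$caseid == "3", ]), rep(FALSE, 3))

  # two PTs of the same group still one flag; flags monotone under
  # dictionary enlargement
  tt <- tinyTables()
  tt@reac <- rbind(tt@reac, data.frame(primaryid = "201", caseid = "2",
                                       pt = "Platelet count decreased"))
  rep2 <- deduplicateReports(assembleReports(tt))
  f2 <- flagEvents(rep2, tinyEventDict())
  expect_identical(sum(f2[, "thrombocytopenia"]), 1L)
  bigger <- eventDictionary(list(
    thrombocytopenia = c("Thrombocytopenia", "Platelet count decreased",
                         "Nausea"),
    hypofibrinogenaemia = "Hypofibrinogenaemia",
    coagulation_dysfunction = c("Thrombocytopenia",
                                "Platelet count decreased", "Nausea",
                                "Hypofibrinogenaemia")))
  f3 <- flagEvents(rep2, bigger)
  expect_true(all(f3[f2[, "thrombocytopenia"], "thrombocytopenia"]))
  expect_true(sum(f3) >= sum(f2))
})

test_that("contingency cells match generator bookkeeping and partition", {
  cfg <- simConfig(seed = 5, nBackground = 2000,
                   drugs = defaultDrugArms()[c(1, 2)],
                   duplicateFraction = 0.05, partialDateFraction = 0.1)
  sim <- simulateFaers(cfg)
  dd <- deduplicateReports(assembleReports(sim$tables))
  dict <- defaultDrugDictionary()
  ed <- cfg$eventDict
  total <- nrow(reports(dd))

  full <- buildDesignTables(dd, dict, ed,
                            comparisonDesign("fd", "tigecycline",
                                             "full_database"))
  # full-database partition identity, and a+b constant across groups
  expect_true(all(full$a + full$b + full$c + full$d == total))
  expect_identical(length(unique(full$a + full$b)), 1L)

  # cells equal direct counting in the generator's case bookkeeping
  cases <- sim$cases
  tig <- cases$arm == "tigecycline"
  for (g in c("thrombocytopenia", "hypofibrinogenaemia",
              "coagulation_dysfunction")) {
    row <- full[full$event_group == g, ]
    expect_identical(row$a, sum(tig & cases[[g]]), label = g)
    expect_identical(row$b, sum(tig & !cases[[g]]), label = g)
    expect_identical(row$c, sum(!tig & cases[[g]]), label = g)
  }

  # per-drug comparator cells sum to the pooled cells (disjoint cohorts)
  perDrug <- buildDesignTables(dd, dict, ed,
                               comparisonDesign("cmp", "tigecycline",
                                                "vancomycin",
                                                pairing = "per_drug"))
  pooled <- buildDesignTables(dd, dict, ed,
                              comparisonDesign("cmp", "tigecycline",
                                               "vancomycin",
                                               pairing = "pooled"))
  for (g in unique(pooled$event_group)) {
    expect_identical(sum(perDrug$c[perDrug$event_group == g]),
                     pooled$c[pooled$event_group == g])
    expect_identical(sum(perDrug$d[perDrug$event_group == g]),
                     pooled$d[pooled$event_group == g])
  }

  expect_error(buildDesignTables(dd, dict, ed,
                                 comparisonDesign("none", "daptomycin",
                                                  "full_database")),
               "no target reports", class = "faersignalEmptyError")
})

test_that("event-arm split matches the reported cohort arithmetic", {
  # a target cohort of 1517 with 223 flagged yields a = 223, b = 1294
  a <- 223L; total <- 1517L
  expect_identical(total - a, 1294L)
  cfg <- recoveryConfig(1, nPerArm = 1500)
  sim <- simulateFaers(cfg)
  dd <- deduplicateReports(assembleReports(sim$tables))
  tab <- buildDesignTables(dd, recoveryDrugDict(), cfg$eventDict,
                           comparisonDesign("fd", "tigecycline",
                                            "full_database"),
                           groups = "coag")
  expect_identical(tab$a + tab$b,
                   sum(sim$cases$arm == "tigecycline"))
  expect_identical(tab$a, sum(sim$cases$coag[sim$cases$arm == "tigecycline"]))
})

test_that("a report qualifying for target and comparator goes to the target", {
  tt <- tinyTables()
  # case 2 now lists both vancomycin and tigecycline as primary suspects
  tt@drug <- rbind(tt@drug, data.frame(
    primaryid = "201", caseid = "2", drug_seq = "2", role_cod = "PS",
    drugname = "TYGACIL", prod_ai = "TIGECYCLINE", dose_amt = "100",
    dose_unit = "MG", dose_freq = "QD"))
  dd <- deduplicateReports(assembleReports(tt))
  expect_message(
    tab <- buildDesignTables(dd, tinyDrugDict(), tinyEventDict(),
                             comparisonDesign("cmp", "tigecycline",
                                              "vancomycin")),
    "assigned to target")
  # both remaining cases are target; comparator cells are empty
  expect_true(all(tab$c + tab$d == 0))
  expect_true(all(tab$a + tab$b == 2))
})
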