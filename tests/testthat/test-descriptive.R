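# Builds a cohort of known composition directly from raw tables, so the
# summary counts can be checked against hand bookkeeping.
compositionCohort <- function(n = 40, nEvent = 12, nMale = 18, nDeath = 5) {
  ids <- as.character(1000 + seq_len(n))
  demo <- data.frame(
    primaryid = ids, caseid = ids,
    event_dt = rep("20190510", n),
    sex = c(rep("M", nMale), rep("F", n - nMale)),
    age = rep("70", n), age_cod = rep("YR", n),
    occp_cod = rep("MD", n), fda_dt = rep("20190601", n),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = ids, caseid = ids, drug_seq = "1", role_cod = "PS",
    drugname = "TYGACIL", prod_ai = "TIGECYCLINE", dose_amt = "100",
    dose_unit = "MG", dose_freq = "QD", stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = ids, caseid = ids,
    pt = c(rep("Hypofibrinogenaemia", nEvent), rep("Nausea", n - nEvent)),
    stringsAsFactors = FALSE)
  ther <- data.frame(primaryid = ids, caseid = ids, dsg_seq = "1",
                     start_dt = "20190501", stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = ids[seq_len(nDeath)],
                     caseid = ids[seq_len(nDeath)],
                     outc_cod = rep("DE", nDeath),
                     stringsAsFactors = FALSE)
  dd <- deduplicateReports(assembleReports(
    FaersTables(demo = demo, drug = drug, reac = reac, ther = ther,
                outc = outc)))
  buildCohort(dd, tinyDrugDict(), tinyEventDict(), "tigecycline")
}

test_that("summary counts and percentages follow the cohort composition", {
  co <- compositionCohort(n = 40, nEvent = 12, nMale = 18, nDeath = 5)
  s <- summarizeCohort(co, group = "hypofibrinogenaemia")
  expect_identical(s@nEvent, 12L)
  expect_identical(s@nOther, 28L)
  tab <- strata(s)
  male <- tab[tab$stratification == "sex" & tab$stratum == "male", ]
  # events were planted on the first 12 cases, all male
  expect_identical(male$n_event, 12L)
  expect_identical(male$n_other, 6L)
  expect_equal(male$pct_event, 100)
  expect_equal(male$pct_other, 100 * 6 / 28, tolerance = 1e-12)
  elderly <- tab[tab$stratification == "age" & tab$stratum == ">=65", ]
  expect_identical(elderly$n_event + elderly$n_other, 40L)
  # exclusive stratifications partition each arm
  for (st in c("sex", "age", "reporter", "year")) {
    sub <- tab[tab$stratification == st, ]
    expect_equal(sum(sub$pct_event), 100, tolerance = 0.05, label = st)
    expect_equal(sum(sub$pct_other), 100, tolerance = 0.05, label = st)
  }
  expect_error(summarizeCohort(co, group = "nonexistent"),
               class = "faersignalConfigError")
})

test_that("percentage arithmetic reproduces the published-table identities", {
  # 125 male of 223 event cases -> 56.05%; 98 elderly -> 43.95%
  expect_equal(round(100 * 125 / 223, 2), 56.05)
  expect_equal(round(100 * 98 / 223, 2), 43.95)
  # case fatality: 45 deaths of 223 -> 20.18%
  co <- compositionCohort(n = 60, nEvent = 20, nMale = 30, nDeath = 60)
  s <- summarizeCohort(co, group = "hypofibrinogenaemia")
  expect_equal(caseFatality(s), 100)  # every case reported death
  co2 <- compositionCohort(n = 60, nEvent = 20, nMale = 30, nDeath = 0)
  expect_equal(caseFatality(summarizeCohort(co2, "hypofibrinogenaemia")), 0)
  co3 <- compositionCohort(n = 223, nEvent = 223, nMale = 100, nDeath = 45)
  expect_equal(round(caseFatality(summarizeCohort(co3, "hypofibrinogenaemia")),
                     2), 20.18)
})

test_that("outcome rows are non-exclusive and count case-level", {
  co <- compositionCohort(n = 10, nEvent = 4, nMale = 5, nDeath = 3)
  s <- summarizeCohort(co, group = "hypofibrinogenaemia")
  tab <- strata(s)
  oc <- tab[tab$stratification == "outcome", ]
  expect_identical(sum(oc$n_event[oc$stratum == "death"]), 3L)
  # cases without any outcome code land in the missing row
  expect_identical(oc$n_event[oc$stratum == "missing"] +
                     oc$n_other[oc$stratum == "missing"], 7L)
})

test_that("Pearson chi-square without correction matches published P values", {
  # loading vs non-loading dose comparison
  p1 <- chisqTest2x2(matrix(c(28, 121, 86, 305), 2))
  expect_equal(p1$p_value, 0.41, tolerance = 0.02)
  expect_equal(p1$p_value, 0.4149519, tolerance = 1e-6)
  # standard vs high maintenance dose comparison
  p2 <- chisqTest2x2(matrix(c(111, 34, 481, 124), 2))
  expect_equal(p2$p_value, 0.43, tolerance = 0.02)
  expect_equal(p2$p_value, 0.4336085, tolerance = 1e-6)
  # gender comparison: statistic ~ 11.93, p < 0.05
  p3 <- chisqTest2x2(matrix(c(125, 69, 520, 501), 2))
  expect_equal(p3$statistic, 11.93437, tolerance = 1e-6)
  expect_lt(p3$p_value, 0.05)
  expect_error(chisqTest2x2(matrix(c(0, 0, 5, 5), 2)),
               class = "faersignalDegenerateTable")
})

test_that("chi-square agrees with expected-counts arithmetic to 10 digits", {
  set.seed(77)
  for (i in 1:100) {
    m <- matrix(sample(20:400, 4, replace = TRUE), 2)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    statRef <- sum((m - e)^2 / e)
    pRef <- stats::pchisq(statRef, df = 1, lower.tail = FALSE)
    got <- chisqTest2x2(m)
    expect_equal(got$statistic, statRef, tolerance = 1e-10)
    expect_equal(got$p_value, pRef, tolerance = 1e-10)
  }
})

test_that("time-to-onset uses interpolated quantiles and day-precision dates", {
  mkCohort <- function(onsets, eventPrecision = "day") {
    n <- length(onsets)
    ids <- as.character(2000 + seq_len(n))
    start <- as.Date("2019-03-01")
    eventDates <- start + onsets
    event_dt <- format(eventDates, "%Y%m%d")
    if (eventPrecision == "month") event_dt <- substr(event_dt, 1, 6)
    demo <- data.frame(primaryid = ids, caseid = ids, event_dt = event_dt,
                       sex = "M", age = "60", age_cod = "YR",
                       occp_cod = "MD", fda_dt = "20191201",
                       stringsAsFactors = FALSE)
    drug <- data.frame(primaryid = ids, caseid = ids, drug_seq = "1",
                       role_cod = "PS", drugname = "TIGECYCLINE",
                       prod_ai = "TIGECYCLINE", dose_amt = "100",
                       dose_unit = "MG", dose_freq = "QD",
                       stringsAsFactors = FALSE)
    reac <- data.frame(primaryid = ids, caseid = ids,
                       pt = "Hypofibrinogenaemia", stringsAsFactors = FALSE)
    ther <- data.frame(primaryid = ids, caseid = ids, dsg_seq = "1",
                       start_dt = format(start, "%Y%m%d"),
                       stringsAsFactors = FALSE)
    outc <- data.frame(primaryid = character(0), caseid = character(0),
                       outc_cod = character(0), stringsAsFactors = FALSE)
    dd <- deduplicateReports(assembleReports(
      FaersTables(demo = demo, drug = drug, reac = reac, ther = ther,
                  outc = outc)))
    buildCohort(dd, tinyDrugDict(), tinyEventDict(), "tigecycline")
  }

  # odd length: the middle order statistic
  t1 <- timeToEvent(mkCohort(c(6, 8, 10, 12, 14)), "hypofibrinogenaemia")
  expect_equal(t1$median, 10)
  expect_equal(t1$fraction_within(14), 100)

  # even length, linear interpolation between order statistics:
  # median = (10+12)/2 = 11, q1 = 6 + 0.75*(8-6) = 7.5,
  # q3 = 14 + 0.25*(16-14) = 14.5
  t2 <- timeToEvent(mkCohort(c(4, 6, 8, 10, 12, 14, 16, 18)),
                    "hypofibrinogenaemia")
  expect_equal(t2$median, 11)
  expect_equal(unname(t2$iqr), c(7.5, 14.5))
  expect_equal(t2$fraction_within(10), 100 * 4 / 8)

  # cumulative curve is non-decreasing and reaches 100%
  expect_true(all(diff(t2$curve$cumulative_pct) >= 0))
  expect_equal(t2$curve$cumulative_pct[nrow(t2$curve)], 100)

  # negative onsets are excluded and tallied
  t3 <- timeToEvent(mkCohort(c(-5, 3, 7)), "hypofibrinogenaemia")
  expect_identical(nrow(t3$records), 2L)
  expect_identical(unname(t3$excluded["negative_interval"]), 1L)

  # month-precision event dates never enter day arithmetic
  expect_error(timeToEvent(mkCohort(c(3, 7), eventPrecision = "month"),
                           "hypofibrinogenaemia"),
               class = "faersignalEmptyError")
})
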