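# Hand-built fixtures used across the suite.  All data are constructed in
# code; nothing is read from disk except the shipped default dictionaries.

tinyDrugDict <- function() {
  drugDictionary(list(
    tigecycline = c("tigecycline", "tygacil"),
    vancomycin = c("vancomycin", "vancocin")
  ))
}

tinyEventDict <- function() {
  eventDictionary(list(
    thrombocytopenia = c("Thrombocytopenia", "Platelet count decreased"),
    hypofibrinogenaemia = c("Hypofibrinogenaemia"),
    coagulation_dysfunction = c("Thrombocytopenia", "Platelet count decreased",
                                "Hypofibrinogenaemia")
  ))
}

# Three cases: case 1 has two report versions (dedup must keep primaryid
# "102", the later receipt); case 2 is a vancomycin report; case 3 has
# tigecycline as concomitant only.
tinyTables <- function() {
  FaersTables(
    demo = data.frame(
      primaryid = c("101", "102", "201", "301"),
      caseid = c("1", "1", "2", "3"),
      event_dt = c("20190110", "20190110", "201903", "20200501"),
      sex = c("M", "M", "F", ""),
      age = c("730", "730", "64", ""),
      age_cod = c("DY", "DY", "YR", ""),
      occp_cod = c("MD", "MD", "CN", ""),
      fda_dt = c("20190201", "20190315", "20190401", "20200601"),
      stringsAsFactors = FALSE),
    drug = data.frame(
      primaryid = c("101", "102", "201", "301", "301"),
      caseid = c("1", "1", "2", "3", "3"),
      drug_seq = c("1", "1", "1", "1", "2"),
      role_cod = c("PS", "PS", "PS", "PS", "C"),
      drugname = c("TYGACIL", "TYGACIL", "VANCOCIN 500MG",
                   "ASPIRIN", "TIGECYCLINE 50MG VIAL"),
      prod_ai = c("TIGECYCLINE", "TIGECYCLINE", "VANCOMYCIN",
                  "ASPIRIN", "TIGECYCLINE"),
      dose_amt = c("200", "200", "500", "100", "50"),
      dose_unit = c("MG", "MG", "MG", "MG", "MG"),
      dose_freq = c("QD", "QD", "QD", "QD", "QD"),
      stringsAsFactors = FALSE),
    reac = data.frame(
      primaryid = c("101", "101", "102", "102", "201", "301"),
      caseid = c("1", "1", "1", "1", "2", "3"),
      pt = c("Hypofibrinogenaemia", "Nausea", "Hypofibrinogenaemia",
             "Nausea", "Thrombocytopenia", "Headache"),
      stringsAsFactors = FALSE),
    ther = data.frame(
      primaryid = c("101", "102", "201"),
      caseid = c("1", "1", "2"),
      dsg_seq = c("1", "1", "1"),
      start_dt = c("20190101", "20190101", "20190215"),
      stringsAsFactors = FALSE),
    outc = data.frame(
      primaryid = c("101", "102", "102", "201"),
      caseid = c("1", "1", "1", "2"),
      outc_cod = c("DE", "DE", "HO", "OT"),
      stringsAsFactors = FALSE)
  )
}

# A small two-arm simulation with a planted odds ratio, shared by several
# tests.  p_target = 0.28 and p_comparator = 0.10 give a true ROR of
# exactly (0.28/0.72)/(0.10/0.90) = 3.5.
recoveryConfig <- function(seed, nPerArm = 5000, duplicateFraction = 0.05,
                           partialDateFraction = 0.10) {
  simConfig(
    seed = seed, nBackground = nPerArm,
    drugs = list(drugSpec("tigecycline", c("TIGECYCLINE", "TYGACIL"),
                          nPerArm, eventProb = c(coag = 0.28))),
    backgroundEventProb = c(coag = 0.10),
    eventDict = eventDictionary(list(coag = c("Coagulopathy",
                                              "Hypofibrinogenaemia"))),
    duplicateFraction = duplicateFraction,
    partialDateFraction = partialDateFraction)
}

recoveryDrugDict <- function() {
  drugDictionary(list(tigecycline = c("tigecycline", "tygacil")))
}

# One full generator -> assemble -> dedup -> contingency -> ROR pass.
runRecoveryReplicate <- function(seed, nPerArm = 5000) {
  cfg <- recoveryConfig(seed, nPerArm)
  sim <- simulateFaers(cfg)
  dd <- deduplicateReports(assembleReports(sim$tables))
  tab <- buildDesignTables(dd, recoveryDrugDict(), cfg$eventDict,
                           comparisonDesign("fd", "tigecycline",
                                            "full_database"),
                           groups = "coag")
  evaluateDesigns(tab)
}
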