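Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Adverse
    Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in FDA Adverse
    Event Reporting System (FAERS) quarterly data: readers and writers for
    the '$'-delimited ASCII tables, case-level report assembly and
    deduplication, drug and MedDRA preferred-term dictionary matching,
    reporting odds ratio (ROR) estimation with Woolf confidence intervals
    and signal classification against configurable comparator designs,
    descriptive cohort summaries with time-to-onset analysis, and a
    synthetic FAERS generator with planted reporting-odds-ratio effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils-conditions.R'
    'utils-dates.R'
    'AllClasses.R'
    'AllGenerics.R'
    'faers-io.R'
    'assemble.R'
    'dictionaries.R'
    'cohort.R'
    'ror.R'
    'descriptive.R'
    'simulate.R'
    'pipeline.R'
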