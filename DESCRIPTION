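Package: cohortgram
Title: Person-Day Chronogram Curation for Infection and Vaccination
    Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for curating longitudinal infection and vaccination
    cohort studies. Sparse per-participant metadata and date-stamped
    experiment tables (antibody titers, PCR and antigen tests, symptom
    diaries, viral sequencing calls) are assembled into a dense
    chronogram: a keyed table with exactly one row per participant per
    calendar day. Annotation functions detect infection episodes by
    gap-threshold interval merging, detect seroconversion windows from
    serological marker transitions, fill episode-level values, and count
    cumulative vaccinations, infections and antigenic exposures per
    person-day. A filter-window-select grammar extracts analysis-ready
    sub-cohorts (for example, titers 28-35 days after a second vaccine
    dose). Chronograms serialize losslessly to a sparse plain-text
    container. A seeded synthetic cohort generator with ground truth
    emulates a two-dose-interval SARS-CoV-2 vaccine study for testing
    and examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DBI,
    RSQLite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
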