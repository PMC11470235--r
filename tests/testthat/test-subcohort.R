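subCohortFixture <- function(seed = 21, n = 30) {
    coh <- generateCohort(cohortDesign(nParticipants = n), seed = seed)
    annotatedCohort(coh)
}

test_that("filtering keeps matching rows, relaxes the grid, and records audit notes", {
    cg <- subCohortFixture()
    all_ <- cgFilter(cg, TRUE)
    expect_identical(nrow(all_), nrow(cg))
    expect_true(isSubcohort(all_))
    none <- cgFilter(cg, FALSE)
    expect_identical(nrow(none), 0L)
    expect_identical(names(cgData(none)), names(cgData(cg)))

    sub <- cgFilter(cg, exposures_count == 2 & episodes_count == 0)
    d <- cgData(sub)
    expect_true(all(d$exposures_count == 2 & d$episodes_count == 0))
    expect_match(provenance(sub), "exposures_count == 2", all = FALSE)
    expect_true(cgValidate(sub)$ok)  # key uniqueness still audited
    expect_error(cgFilter(cg, no_such_column > 1), "no_such_column")
})

test_that("metadata windows retain the inclusive offset range per participant", {
    meta <- data.frame(participant_id = c("P1", "P2"),
                       dose_2_date = as.Date(c("2021-06-01", NA)))
    cg <- cgAssemble("2021-05-01", "2021-07-31", meta)
    expect_message(w <- windowByMetadata(cg, "dose_2_date", 28, 35),
                   "dropped 1 participant")
    d <- cgData(w)
    expect_identical(unique(d$participant_id), "P1")
    expect_identical(range(d$date),
                     as.Date(c("2021-06-29", "2021-07-06")))
    expect_identical(nrow(w), 8L)

    z <- windowByMetadata(cgFilter(cg, participant_id == "P1"),
                          "dose_2_date", 0, 0)
    expect_identical(cgData(z)$date, as.Date("2021-06-01"))

    before <- windowByMetadata(cgFilter(cg, participant_id == "P1"),
                               "dose_2_date", -14, -1)
    expect_identical(range(cgData(before)$date),
                     as.Date(c("2021-05-18", "2021-05-31")))
    expect_error(windowByMetadata(cg, "dose_2_date", 5, 2), "offsetLo")
})

test_that("episode and visit windows resolve per-participant references", {
    meta <- data.frame(participant_id = c("P1", "P2"))
    swab <- data.frame(participant_id = "P1",
                       date = as.Date("2021-02-10"), pcr = "positive")
    sero <- data.frame(participant_id = rep("P1", 2),
                       date = as.Date(c("2021-02-01", "2021-05-01")),
                       titer = c(5, 100))
    cg <- cgAssemble("2021-01-01", "2021-06-30", meta,
                     list(swab = swab, serology = sero))
    cg <- episodesFind(cg, "pcr", "positive")

    expect_message(w <- windowByEpisode(cg, 1, 0, 13), "dropped 1")
    d <- cgData(w)
    expect_identical(unique(d$participant_id), "P1")
    expect_identical(range(d$date), as.Date(c("2021-02-10", "2021-02-23")))
    pre <- suppressMessages(windowByEpisode(cg, 1, -3, -1))
    expect_identical(range(cgData(pre)$date),
                     as.Date(c("2021-02-07", "2021-02-09")))
    expect_error(windowByEpisode(cg, 0, 0, 5), "episodeOrdinal")

    v2 <- suppressMessages(windowByVisit(cg, "titer", 2, 0, 0))
    expect_identical(cgData(v2)$date, as.Date("2021-05-01"))
    v3 <- suppressMessages(windowByVisit(cg, "titer", 3, 0, 0))
    expect_identical(nrow(v3), 0L)
    span <- suppressMessages(windowByVisit(cg, "titer", 1, 0, 120))
    expect_identical(sum(!is.na(cgData(span)$titer)), 2L)
})

test_that("selectVisit returns at most one non-missing row per participant", {
    meta <- data.frame(participant_id = c("P1", "P2"),
                       anchor = as.Date(c("2021-01-08", "2021-01-08")))
    sero <- data.frame(participant_id = c("P1", "P1", "P2"),
                       date = as.Date(c("2021-01-05", "2021-01-10",
                                        "2021-01-07")),
                       titer = c(10, 20, NA))
    cg <- cgAssemble("2021-01-01", "2021-01-31", meta,
                     list(serology = sero))
    first <- selectVisit(cg, "titer")
    expect_identical(cgData(first)$titer, 10)  # P2 has no value -> absent
    last <- selectVisit(cg, "titer", policy = "last")
    expect_identical(cgData(last)$titer, 20)
    near <- selectVisit(cg, "titer", policy = "nearest", refCol = "anchor")
    expect_identical(cgData(near)$titer, 20)  # Jan 10 is 2d from anchor, Jan 5 is 3d
    expect_error(selectVisit(cg, "titer", policy = "nearest"), "refCol")
    expect_error(selectVisit(cg, "titer", policy = "median"), "'arg'")

    cg2 <- subCohortFixture(seed = 4)
    sel <- selectVisit(suppressMessages(
        windowByMetadata(cg2, "dose_2_date", 28, 35)), "anti_S")
    tab <- table(cgData(sel)$participant_id)
    expect_true(all(tab == 1))
    expect_true(all(!is.na(cgData(sel)$anti_S)))
})

test_that("windowing never invents or edits cells, and views stay key-unique", {
    cg <- subCohortFixture(seed = 9)
    w <- suppressMessages(windowByMetadata(cg, "dose_2_date", 28, 35))
    d <- cgData(w); full <- cgData(cg)
    key <- paste(d$participant_id, d$date)
    expect_identical(anyDuplicated(key), 0L)
    hit <- match(key, paste(full$participant_id, full$date))
    expect_false(anyNA(hit))
    expect_identical(d$anti_S, full$anti_S[hit])
    expect_identical(d$antigenic_history, full$antigenic_history[hit])
})

test_that("pre/post sub-cohorts bind into a key-unique labelled table", {
    cg <- subCohortFixture(seed = 14)
    pre <- selectVisit(suppressMessages(
        windowByMetadata(cg, "dose_2_date", -28, -1)), "anti_S")
    post <- selectVisit(suppressMessages(
        windowByMetadata(cg, "dose_2_date", 28, 35)), "anti_S")
    a <- cgData(pre); a$cohort <- "pre dose 2"
    b <- cgData(post); b$cohort <- "post dose 2"
    both <- rbind(a, b)
    expect_identical(anyDuplicated(paste(both$participant_id, both$date,
                                         both$cohort)), 0L)
    expect_true(all(table(both$participant_id) <= 2))
})
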