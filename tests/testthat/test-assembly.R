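test_that("assembly builds the dense grid and places sparse observations", {
    meta <- data.frame(participant_id = c("P1", "P2"))
    cg <- cgAssemble("2021-01-01", "2021-01-03", meta)
    expect_identical(nrow(cg), 6L)

    sero <- data.frame(participant_id = "P1",
                       date = as.Date("2021-01-02"), titer = 100)
    cg2 <- cgAssemble("2021-01-01", "2021-01-03", meta,
                      list(serology = sero))
    d <- cgData(cg2)
    expect_identical(sum(!is.na(d$titer)), 1L)
    expect_identical(d$titer[d$participant_id == "P1" &
                             d$date == as.Date("2021-01-02")], 100)
})

test_that("assembly refuses malformed inputs with named errors", {
    meta <- data.frame(participant_id = c("P1", "P2"))
    dupExp <- data.frame(participant_id = c("P1", "P1"),
                         date = as.Date(c("2021-01-02", "2021-01-02")),
                         titer = c(1, 2))
    expect_error(cgAssemble("2021-01-01", "2021-01-03", meta,
                            list(serology = dupExp)),
                 "duplicate_key in experiment 'serology'.*P1.*2021-01-02")

    expect_error(cgAssemble("2021-01-01", "2021-01-03",
                            data.frame(participant_id = c("P1", "P1"))),
                 "duplicate participant_id.*P1")

    stranger <- data.frame(participant_id = "P9",
                           date = as.Date("2021-01-02"), titer = 1)
    expect_error(cgAssemble("2021-01-01", "2021-01-03", meta,
                            list(serology = stranger)),
                 "absent from metadata.*P9")

    late <- data.frame(participant_id = "P1",
                       date = as.Date("2021-02-10"), titer = 1)
    expect_error(cgAssemble("2021-01-01", "2021-01-03", meta,
                            list(serology = late)),
                 "dated outside")
    expect_message(
        cg <- cgAssemble("2021-01-01", "2021-01-03", meta,
                         list(serology = late), dropOutOfSpan = TRUE),
        "dropped 1 observation")
    expect_true(all(is.na(cgData(cg)$titer)))

    expect_error(cgAssemble("2021-01-05", "2021-01-01", meta), "start")
})

test_that("adding an experiment later equals assembling with it upfront", {
    meta <- tinyMeta(3)
    a <- data.frame(participant_id = c("P01", "P02"),
                    date = as.Date(c("2021-01-02", "2021-01-05")),
                    titer = c(10, 20))
    b <- data.frame(participant_id = "P03",
                    date = as.Date("2021-01-07"), pcr = "positive")
    oneShot <- cgAssemble("2021-01-01", "2021-01-10", meta, list(a = a, b = b))
    later <- cgAddExperiment(cgAssemble("2021-01-01", "2021-01-10", meta,
                                        list(a = a)), b, "b")
    expect_identical(cgData(oneShot), cgData(later))

    # 0-row experiment with a fresh column -> all-missing column of its class
    empty <- data.frame(participant_id = character(),
                        date = as.Date(character()), ct = numeric())
    cg <- cgAddExperiment(oneShot, empty, "swab2")
    expect_true(all(is.na(cgData(cg)$ct)))
    expect_type(cgData(cg)$ct, "double")

    # a clashing result-column name is refused
    clash <- data.frame(participant_id = "P01",
                        date = as.Date("2021-01-02"), titer = 5)
    expect_error(cgAddExperiment(oneShot, clash, "again"),
                 "column_collision.*titer")
})

test_that("cell values are invariant to input row order", {
    set.seed(42)
    meta <- tinyMeta(5)
    exp1 <- data.frame(participant_id = sample(meta$participant_id, 8,
                                               replace = TRUE),
                       date = as.Date("2021-01-01") + sample(0:9, 8,
                                                             replace = TRUE),
                       titer = rnorm(8))
    exp1 <- exp1[!duplicated(paste(exp1$participant_id, exp1$date)), ]
    base <- cgAssemble("2021-01-01", "2021-01-10", meta, list(e = exp1))
    shuffled <- cgAssemble("2021-01-01", "2021-01-10",
                           meta[sample(nrow(meta)), , drop = FALSE],
                           list(e = exp1[sample(nrow(exp1)), , drop = FALSE]))
    # same cells regardless of participant order: compare after sorting
    sortReset <- function(d) {
        d <- d[order(d$participant_id, d$date), , drop = FALSE]
        rownames(d) <- NULL
        d
    }
    expect_identical(sortReset(cgData(base)), sortReset(cgData(shuffled)))
})

test_that("readCohortTable parses ISO dates strictly and keeps ids opaque", {
    f <- tempfile(fileext = ".csv")
    write.csv(data.frame(participant_id = c("007", "008"),
                         dose_1_date = c("2021-03-07", ""),
                         n_doses = c("2", "1")),
              f, row.names = FALSE)
    tab <- readCohortTable(f, idCol = "participant_id")
    expect_identical(tab$participant_id, c("007", "008"))  # leading zero kept
    expect_identical(tab$dose_1_date, as.Date(c("2021-03-07", NA)))
    expect_identical(tab$n_doses, c(2, 1))

    # an ambiguous dialect is never guessed
    g <- tempfile(fileext = ".csv")
    write.csv(data.frame(participant_id = "P1", visit_date = "07/03/2021"),
              g, row.names = FALSE)
    expect_error(readCohortTable(g, dateCols = "visit_date"),
                 "unparseable.*visit_date")
    # ... but parses with an explicit format
    ok <- readCohortTable(g, dateCols = "visit_date",
                          dateFormat = "%d/%m/%Y")
    expect_identical(ok$visit_date, as.Date("2021-03-07"))

    expect_error(readCohortTable(tempfile(fileext = ".csv")), "no such file")
})

test_that("SQLite tables round through readCohortTable into assembly", {
    coh <- generateCohort(cohortDesign(nParticipants = 12), seed = 5)
    dir <- tempfile()
    writeCohortTables(coh, dir, sqlite = TRUE)
    db <- file.path(dir, "cohort.sqlite")
    meta <- readCohortTable(db, "metadata")
    expect_identical(nrow(meta), 12L)
    expect_s3_class(meta$dose_1_date, "Date")
    exps <- lapply(c(serology = "serology", swab = "swab",
                     symptom = "symptom"),
                   function(t) readCohortTable(db, t))
    cg <- cgAssemble(coh$start, coh$end, meta, exps)
    expect_true(cgValidate(cg)$ok)
    expect_identical(nParticipants(cg), 12L)
    # CSV twin assembles to the same cells
    metaCsv <- readCohortTable(file.path(dir, "metadata.csv"))
    expect_equal(metaCsv, meta)  # SQLite yields integers, CSV numerics
    expect_error(readCohortTable(db, "no_such_table"), "not found")
})
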