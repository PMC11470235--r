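evidenceCg <- function(evidence, start = "2021-01-01", end = "2021-03-31") {
    # evidence: data.frame(participant_id, date, col, value)
    ids <- unique(evidence$participant_id)
    if (!length(ids)) ids <- "P1"
    meta <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
    exps <- list()
    for (col in unique(evidence$col)) {
        sub <- evidence[evidence$col == col, , drop = FALSE]
        tab <- data.frame(participant_id = sub$participant_id,
                          date = sub$date, stringsAsFactors = FALSE)
        tab[[col]] <- sub$value
        exps[[col]] <- tab
    }
    cgAssemble(start, end, meta, exps)
}

test_that("evidence a few days apart merges into one numbered episode", {
    ev <- data.frame(participant_id = "P1",
                     date = as.Date(c("2021-01-05", "2021-01-07")),
                     col = c("symptom", "pcr"),
                     value = c("Y", "positive"), stringsAsFactors = FALSE)
    cg <- episodesFind(evidenceCg(ev), c("symptom", "pcr"),
                       list(symptom = "Y", pcr = "positive"), maxGap = 7)
    ep <- episodesTable(cg)
    expect_identical(nrow(ep), 1L)
    expect_identical(ep$episode_number, 1L)
    expect_identical(ep$start_date, as.Date("2021-01-05"))
    expect_identical(ep$end_date, as.Date("2021-01-07"))
    d <- cgData(cg)
    inEp <- !is.na(d$episode_number)
    expect_identical(range(d$date[inEp]),
                     as.Date(c("2021-01-05", "2021-01-07")))
    expect_true(d$episode_start[d$date == as.Date("2021-01-05")])
    expect_true(d$episode_end[d$date == as.Date("2021-01-07")])
})

test_that("a gap wider than maxGap splits episodes; none without evidence", {
    ev <- data.frame(participant_id = "P1",
                     date = as.Date(c("2021-01-05", "2021-03-20")),
                     col = "pcr", value = "positive",
                     stringsAsFactors = FALSE)
    cg <- episodesFind(evidenceCg(ev), "pcr", "positive", maxGap = 7)
    expect_identical(episodesTable(cg)$episode_number, c(1L, 2L))

    none <- data.frame(participant_id = "P1",
                       date = as.Date("2021-01-05"),
                       col = "pcr", value = "negative",
                       stringsAsFactors = FALSE)
    cg0 <- episodesFind(evidenceCg(none), "pcr", "positive", maxGap = 7)
    expect_identical(nrow(episodesTable(cg0)), 0L)
    expect_true(all(is.na(cgData(cg0)$episode_number)))
})

test_that("matching trims and case-folds; regex mode is available", {
    ev <- data.frame(participant_id = "P1",
                     date = as.Date("2021-01-05"),
                     col = "pcr", value = " Positive ",
                     stringsAsFactors = FALSE)
    cg <- episodesFind(evidenceCg(ev), "pcr", "positive")
    expect_identical(nrow(episodesTable(cg)), 1L)
    cg2 <- episodesFind(evidenceCg(ev), "pcr", "^ Pos", regex = TRUE)
    expect_identical(nrow(episodesTable(cg2)), 1L)
})

test_that("episode detection matches the graph-component oracle on random inputs", {
    set.seed(2024)
    for (rep in 1:8) {
        nDays <- 90
        meta <- tinyMeta(10, extra = FALSE)
        maxGap <- sample(0:20, 1)
        dens <- runif(1, 0, 0.4)
        obs <- expand.grid(participant_id = meta$participant_id,
                           date = as.Date("2021-01-01") + 0:(nDays - 1),
                           stringsAsFactors = FALSE)
        obs <- obs[runif(nrow(obs)) < dens, , drop = FALSE]
        obs$pcr <- sample(c("positive", "negative"), nrow(obs),
                          replace = TRUE)
        cg <- cgAssemble("2021-01-01", as.Date("2021-01-01") + nDays - 1,
                         meta, if (nrow(obs)) list(swab = obs) else list())
        if (!"pcr" %in% names(cgData(cg))) next
        got <- episodesFind(cg, "pcr", "positive", maxGap = maxGap)
        ep <- episodesTable(got)
        for (p in meta$participant_id) {
            evDays <- obs$date[obs$participant_id == p &
                               obs$pcr == "positive"]
            want <- oracleEpisodes(evDays, maxGap)
            have <- ep[ep$participant_id == p, , drop = FALSE]
            expect_identical(have$episode_number, want$episode_number)
            expect_identical(have$start_date, want$start_date)
            expect_identical(have$end_date, want$end_date)
        }
    }
})

test_that("episodes of one participant stay disjoint with gaps beyond maxGap", {
    set.seed(7)
    for (rep in 1:20) {
        maxGap <- sample(0:15, 1)
        days <- sort(sample(0:120, sample(1:25, 1)))
        ev <- data.frame(participant_id = "P1",
                         date = as.Date("2021-01-01") + days,
                         col = "pcr", value = "positive",
                         stringsAsFactors = FALSE)
        cg <- episodesFind(evidenceCg(ev, end = "2021-06-30"), "pcr",
                           "positive", maxGap = maxGap)
        ep <- episodesTable(cg)
        expect_true(all(ep$start_date <= ep$end_date))
        if (nrow(ep) > 1) {
            gaps <- as.integer(ep$start_date[-1] - ep$end_date[-nrow(ep)])
            expect_true(all(gaps > maxGap))
        }
    }
})

test_that("re-running needs overwrite, is then idempotent, and ignores scan order", {
    ev <- data.frame(participant_id = "P1",
                     date = as.Date(c("2021-01-05", "2021-01-07")),
                     col = c("symptom", "pcr"),
                     value = c("Y", "positive"), stringsAsFactors = FALSE)
    cg0 <- evidenceCg(ev)
    spec <- list(symptom = "Y", pcr = "positive")
    cg1 <- episodesFind(cg0, c("symptom", "pcr"), spec)
    expect_error(episodesFind(cg1, c("symptom", "pcr"), spec), "overwrite")
    cg2 <- episodesFind(cg1, c("symptom", "pcr"), spec, overwrite = TRUE)
    expect_identical(cgData(cg1), cgData(cg2))
    cg3 <- episodesFind(cg0, c("pcr", "symptom"),
                        list(pcr = "positive", symptom = "Y"))
    expect_identical(cgData(cg1)$episode_number, cgData(cg3)$episode_number)
    expect_error(episodesFind(cg0, "nonexistent", "x"), "nonexistent")
})

test_that("a negative-to-positive marker transition yields one half-open window", {
    ser <- data.frame(participant_id = "P590",
                      date = as.Date(c("2021-02-01", "2021-05-01")),
                      anti_N = c("negative", "positive"))
    cg <- cgAssemble("2021-01-01", "2021-06-30",
                     data.frame(participant_id = "P590"),
                     list(serology = ser))
    cg <- episodesFindSeroconversion(cg, "anti_N", "negative", "positive")
    st <- seroconversionTable(cg)
    expect_identical(nrow(st), 1L)
    expect_identical(st$window_start, as.Date("2021-02-01"))
    expect_identical(st$window_end, as.Date("2021-05-01"))
    d <- cgData(cg)
    inWin <- !is.na(d$sero_episode_number)
    # half-open: the last-negative day itself is outside the window
    expect_identical(min(d$date[inWin]), as.Date("2021-02-02"))
    expect_identical(max(d$date[inWin]), as.Date("2021-05-01"))
    expect_false(any(d$sero_baseline_positive))
})

test_that("baseline-positive participants are flagged, never counted as converters", {
    ser <- data.frame(participant_id = rep(c("P99", "P63"), each = 2),
                      date = as.Date(c("2021-02-01", "2021-05-01",
                                       "2021-02-10", "2021-05-10")),
                      anti_N = "positive")
    cg <- cgAssemble("2021-01-01", "2021-06-30",
                     data.frame(participant_id = c("P99", "P63")),
                     list(serology = ser))
    cg <- episodesFindSeroconversion(cg, "anti_N", "negative", "positive")
    expect_identical(nrow(seroconversionTable(cg)), 0L)
    expect_true(all(cgData(cg)$sero_baseline_positive))
})

test_that("neg,neg,pos,pos anchors the window at the inner pair", {
    ser <- data.frame(participant_id = "P1",
                      date = as.Date(c("2021-01-10", "2021-02-10",
                                       "2021-03-10", "2021-04-10")),
                      anti_N = c("negative", "negative",
                                 "positive", "positive"))
    cg <- cgAssemble("2021-01-01", "2021-05-01",
                     data.frame(participant_id = "P1"),
                     list(serology = ser))
    cg <- episodesFindSeroconversion(cg, "anti_N", "negative", "positive")
    st <- seroconversionTable(cg)
    expect_identical(nrow(st), 1L)
    expect_identical(st$window_start, as.Date("2021-02-10"))
    expect_identical(st$window_end, as.Date("2021-03-10"))
})

test_that("unknown marker values abort with value and location", {
    ser <- data.frame(participant_id = "P1",
                      date = as.Date("2021-01-10"), anti_N = "equivocal")
    cg <- cgAssemble("2021-01-01", "2021-02-01",
                     data.frame(participant_id = "P1"),
                     list(serology = ser))
    expect_error(episodesFindSeroconversion(cg, "anti_N", "negative",
                                            "positive"),
                 "equivocal.*P1")
    expect_error(episodesFindSeroconversion(cg, "anti_N", "negative",
                                            c("positive", "negative")),
                 "disjoint")
})

test_that("seroconversion agrees with the pairwise-scan oracle on random sequences", {
    set.seed(31)
    for (rep in 1:30) {
        nV <- sample(1:6, 1)
        dates <- sort(as.Date("2021-01-01") + sample(0:180, nV))
        states <- sample(c("neg", "pos", NA), nV, replace = TRUE)
        ser <- data.frame(participant_id = "P1", date = dates,
                          anti_N = unname(c(neg = "negative",
                                            pos = "positive")[states]),
                          stringsAsFactors = FALSE)
        ser <- ser[!is.na(ser$anti_N), , drop = FALSE]
        cg <- cgAssemble("2021-01-01", "2021-06-30",
                         data.frame(participant_id = "P1"),
                         if (nrow(ser)) list(serology = ser) else list())
        if (!"anti_N" %in% names(cgData(cg)))
            cg <- cgAddExperiment(cg, data.frame(
                participant_id = character(), date = as.Date(character()),
                anti_N = character()), "serology")
        cg <- episodesFindSeroconversion(cg, "anti_N", "negative", "positive")
        want <- oracleSero(dates, states)
        st <- seroconversionTable(cg)
        expect_identical(nrow(st), nrow(want$intervals))
        expect_identical(st$window_start, want$intervals$window_start)
        expect_identical(st$window_end, want$intervals$window_end)
        base <- cgData(cg)$sero_baseline_positive[1]
        expect_identical(base, want$baselinePositive)
    }
})

test_that("reversion is flagged and repeated conversions are all reported", {
    ser <- data.frame(participant_id = "P1",
                      date = as.Date(c("2021-01-10", "2021-02-10",
                                       "2021-03-10", "2021-04-10")),
                      anti_N = c("negative", "positive",
                                 "negative", "positive"))
    cg <- cgAssemble("2021-01-01", "2021-05-01",
                     data.frame(participant_id = "P1"),
                     list(serology = ser))
    cg <- episodesFindSeroconversion(cg, "anti_N", "negative", "positive")
    st <- seroconversionTable(cg)
    expect_identical(st$sero_episode_number, c(1L, 2L))
    expect_true(all(cgData(cg)$sero_reversion))
})

test_that("episode fill broadcasts single calls and honours the conflict policy", {
    ev <- data.frame(participant_id = "P1",
                     date = as.Date(c("2021-01-05", "2021-01-09")),
                     col = "pcr", value = "positive",
                     stringsAsFactors = FALSE)
    seq_ <- data.frame(participant_id = "P1",
                       date = as.Date("2021-01-06"),
                       lineage = "Delta")
    cg <- cgAddExperiment(evidenceCg(ev), seq_, "sequencing")
    cg <- episodesFind(cg, "pcr", "positive", maxGap = 7)
    filled <- episodesFill(cg, "lineage")
    d <- cgData(filled)
    inEp <- !is.na(d$episode_number)
    expect_identical(sum(inEp), 5L)  # Jan 5..9 span
    expect_true(all(d$lineage_filled[inEp] == "Delta"))
    expect_true(all(is.na(d$lineage_filled[!inEp])))

    # two distinct calls inside one episode
    seq2 <- data.frame(participant_id = "P1",
                       date = as.Date(c("2021-01-06", "2021-01-08")),
                       lineage = c("Delta", "Omicron"))
    cg2 <- cgAddExperiment(evidenceCg(ev), seq2, "sequencing")
    cg2 <- episodesFind(cg2, "pcr", "positive", maxGap = 7)
    expect_error(episodesFill(cg2, "lineage"), "Delta / Omicron")
    soft <- episodesFill(cg2, "lineage", policy = "first_nonmissing")
    d2 <- cgData(soft)
    expect_true(all(d2$lineage_filled[!is.na(d2$episode_number)] == "Delta"))

    expect_error(episodesFill(evidenceCg(ev), "pcr"), "episodesFind")
})

test_that("episodes_count steps up on start dates and is monotone", {
    ev <- data.frame(participant_id = "P1",
                     date = as.Date(c("2021-01-05", "2021-03-20")),
                     col = "pcr", value = "positive",
                     stringsAsFactors = FALSE)
    cg <- episodesCount(episodesFind(evidenceCg(ev), "pcr", "positive"))
    d <- cgData(cg)
    expect_identical(d$episodes_count[d$date == as.Date("2021-01-04")], 0L)
    expect_identical(d$episodes_count[d$date == as.Date("2021-01-05")], 1L)
    expect_identical(d$episodes_count[d$date == as.Date("2021-03-31")], 2L)
    expect_true(all(diff(d$episodes_count) >= 0))

    none <- data.frame(participant_id = "P1",
                       date = as.Date("2021-01-05"),
                       col = "pcr", value = "negative",
                       stringsAsFactors = FALSE)
    cg0 <- episodesCount(episodesFind(evidenceCg(none), "pcr", "positive"))
    expect_true(all(cgData(cg0)$episodes_count == 0L))

    expect_error(episodesCount(evidenceCg(ev)), "episodesFind")
})

test_that("sero-only conversions add to the count; attributed ones do not", {
    # participant with a test-evidenced episode inside the sero window
    ev <- data.frame(participant_id = "P1",
                     date = as.Date("2021-03-01"),
                     col = "pcr", value = "positive",
                     stringsAsFactors = FALSE)
    ser <- data.frame(participant_id = "P1",
                      date = as.Date(c("2021-02-01", "2021-04-01")),
                      anti_N = c("negative", "positive"))
    cg <- cgAddExperiment(evidenceCg(ev, end = "2021-06-30"), ser, "serology")
    cg <- episodesFind(cg, "pcr", "positive")
    cg <- episodesFindSeroconversion(cg, "anti_N", "negative", "positive")
    both <- episodesCount(cg)
    expect_identical(max(cgData(both)$episodes_count), 1L)  # deduplicated

    # sero-only participant: the conversion itself is the episode
    noSwab <- cgAssemble("2021-01-01", "2021-06-30",
                         data.frame(participant_id = "P2"),
                         list(serology = data.frame(
                             participant_id = "P2",
                             date = as.Date(c("2021-02-01", "2021-04-01")),
                             anti_N = c("negative", "positive")),
                             swab = data.frame(participant_id = "P2",
                                               date = as.Date("2021-01-02"),
                                               pcr = "negative")))
    noSwab <- episodesFind(noSwab, "pcr", "positive")
    noSwab <- episodesFindSeroconversion(noSwab, "anti_N", "negative",
                                         "positive")
    d <- cgData(episodesCount(noSwab))
    expect_identical(d$episodes_count[d$date == as.Date("2021-03-31")], 0L)
    expect_identical(d$episodes_count[d$date == as.Date("2021-04-01")], 1L)
    dOff <- cgData(episodesCount(noSwab, includeSeroconversions = FALSE))
    expect_true(all(dOff$episodes_count == 0L))
})
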