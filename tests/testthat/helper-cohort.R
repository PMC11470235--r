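# Fixture builders and independent oracles used across the suite.

tinyMeta <- function(n = 3, extra = TRUE) {
    m <- data.frame(participant_id = sprintf("P%02d", seq_len(n)),
                    stringsAsFactors = FALSE)
    if (extra) m$group <- rep(c("a", "b"), length.out = n)
    m
}

tinyCg <- function(n = 3, start = "2021-01-01", end = "2021-01-10",
                   experiments = list(), ...) {
    cgAssemble(start, end, tinyMeta(n), experiments = experiments, ...)
}

# Independent episode oracle: evidence days are nodes of a graph with an
# edge whenever two days are <= maxGap apart; episodes are the connected
# components (breadth-first search over the full pairwise matrix), each
# spanning its min..max day.  A deliberately different route from the
# sequential gap scan inside the package.
oracleEpisodes <- function(evDates, maxGap) {
    evDates <- sort(unique(as.Date(evDates)))
    n <- length(evDates)
    if (n == 0L)
        return(data.frame(episode_number = integer(),
                          start_date = as.Date(character()),
                          end_date = as.Date(character())))
    adj <- abs(outer(as.numeric(evDates), as.numeric(evDates), "-")) <= maxGap
    comp <- rep(NA_integer_, n)
    k <- 0L
    for (i in seq_len(n)) {
        if (!is.na(comp[i])) next
        k <- k + 1L
        queue <- i
        comp[i] <- k
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            nb <- which(adj[v, ] & is.na(comp))
            comp[nb] <- k
            queue <- c(queue, nb)
        }
    }
    starts <- as.Date(as.vector(tapply(as.numeric(evDates), comp, min)),
                      origin = "1970-01-01")
    ends <- as.Date(as.vector(tapply(as.numeric(evDates), comp, max)),
                    origin = "1970-01-01")
    ord <- order(starts)
    data.frame(episode_number = seq_along(ord),
               start_date = starts[ord], end_date = ends[ord])
}

# Independent seroconversion oracle: drop missing measurements, then scan
# consecutive pairs for negative -> positive.
oracleSero <- function(dates, states) {
    keep <- !is.na(states)
    o <- order(dates[keep])
    states <- states[keep][o]
    dates <- dates[keep][o]
    if (length(states) == 0L)
        return(list(baselinePositive = NA, intervals = data.frame(
            window_start = as.Date(character()),
            window_end = as.Date(character()))))
    idx <- which(states[-length(states)] == "neg" & states[-1L] == "pos")
    list(baselinePositive = states[1L] == "pos",
         intervals = data.frame(window_start = dates[idx],
                                window_end = dates[idx + 1L]))
}

# A random small chronogram (optionally with experiments) for property and
# round-trip tests.
randomCg <- function(seed, maxN = 6, maxDays = 40, withExperiments = TRUE) {
    set.seed(seed)
    n <- sample(maxN, 1)
    nDays <- sample(maxDays, 1)
    start <- as.Date("2021-01-01") + sample(0:200, 1)
    end <- start + nDays - 1
    meta <- data.frame(participant_id = sprintf("%03d", sample(900, n)),
                       group = sample(c("x", "y"), n, replace = TRUE),
                       stringsAsFactors = FALSE)
    exps <- list()
    if (withExperiments && stats::runif(1) < 0.8) {
        nObs <- sample(0:(n * min(nDays, 5)), 1)
        ids <- sample(meta$participant_id, nObs, replace = TRUE)
        dates <- start + sample(0:(nDays - 1), nObs, replace = TRUE)
        keep <- !duplicated(paste(ids, dates))
        exps$assay <- data.frame(participant_id = ids[keep],
                                 date = dates[keep],
                                 titer = round(stats::rlnorm(sum(keep), 5, 1), 1),
                                 call = sample(c("pos", "neg", NA), sum(keep),
                                               replace = TRUE),
                                 stringsAsFactors = FALSE)
    }
    cgAssemble(start, end, meta, exps)
}

# The standard demo pipeline: assemble + annotate a generated cohort.
annotatedCohort <- function(coh, includeSero = TRUE) {
    cg <- cgAssemble(coh$start, coh$end, coh$metadata, coh$experiments)
    cg <- episodesFind(cg, c("pcr_result", "symptom"),
                       list(pcr_result = "positive", symptom = "Y"),
                       maxGap = 7)
    cg <- episodesFindSeroconversion(cg, "anti_N", "negative", "positive")
    cg <- episodesFill(cg, "lineage")
    cg <- vaccinesCount(cg, c("dose_1_date", "dose_2_date"))
    cg <- episodesCount(cg, includeSeroconversions = includeSero)
    cg <- exposuresCount(cg)
    antigenicHistory(cg, "lineage_filled")
}

# Last chronological row of each participant, ordered by id.
lastRows <- function(cg) {
    d <- cgData(cg)
    out <- d[!duplicated(d[[idCol(cg)]], fromLast = TRUE), , drop = FALSE]
    out[order(out[[idCol(cg)]]), , drop = FALSE]
}

expect_same_chronogram <- function(a, b) {
    expect_identical(cgData(a), cgData(b))
    expect_identical(idCol(a), idCol(b))
    expect_identical(dateCol(a), dateCol(b))
    expect_identical(metadataCols(a), metadataCols(b))
    expect_identical(annotationCols(a), annotationCols(b))
    expect_identical(dateSpan(a), dateSpan(b))
    expect_identical(isSubcohort(a), isSubcohort(b))
    expect_identical(provenance(a), provenance(b))
    expect_identical(episodesTable(a), episodesTable(b))
    expect_identical(seroconversionTable(a), seroconversionTable(b))
    expect_equal(a@params, b@params)
}
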