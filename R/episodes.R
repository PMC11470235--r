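#' Detect infection episodes by merging sparse evidence days
#'
#' Symptoms, rapid antigen tests, PCRs and sequencing results for one
#' infection typically land a few days apart.  \code{episodesFind} scans the
#' given columns for positive evidence and merges, per participant, evidence
#' days into maximal clusters in which consecutive evidence days are at most
#' \code{maxGap} days apart.  Each cluster becomes one episode spanning its
#' first to last evidence day (both inclusive; intervening evidence-free
#' days inside the span belong to the episode).  Episodes are numbered
#' 1-based in chronological order per participant.
#'
#' Matching is exact equality after trimming and case-folding, so
#' \code{"Positive "} matches \code{"positive"}; set \code{regex = TRUE} to
#' match regular expressions instead.  Missing values never match.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @param scanCols character vector of columns to scan for evidence.
#' @param matchValues values counting as positive evidence: either one
#'   character vector applied to every scanned column, or a list parallel
#'   to (or named by) \code{scanCols}.
#' @param maxGap maximum day gap (>= 0) between consecutive evidence days
#'   of one episode.  The default, 7 days, is a deliberate, explicit choice
#'   — evidence for one episode is usually a few days apart, but no single
#'   value fits every pathogen, so tune it (e.g. towards 90 days for
#'   SARS-CoV-2 reinfection definitions).
#' @param overwrite re-running on an already-annotated chronogram is
#'   refused unless \code{TRUE} (the columns would silently change
#'   downstream counts).
#' @param regex interpret \code{matchValues} as regular expressions.
#' @return a new \code{Chronogram} with annotation columns
#'   \code{episode_number} (integer, on every day of an episode span, NA
#'   elsewhere), \code{episode_start}, \code{episode_end} (logical flags on
#'   the boundary days), and a filled \code{\link{episodesTable}} listing
#'   \{participant, episode_number, start_date, end_date,
#'   evidence_summary\}.
#' @examples
#' meta <- data.frame(participant_id = "P1")
#' swab <- data.frame(participant_id = "P1",
#'                    date = as.Date(c("2021-01-05", "2021-01-07")),
#'                    pcr = c(NA, "positive"))
#' diary <- data.frame(participant_id = "P1",
#'                     date = as.Date("2021-01-05"), symptom = "Y")
#' cg <- cgAssemble("2021-01-01", "2021-01-31", meta,
#'                  list(swab = swab, diary = diary))
#' cg <- episodesFind(cg, c("pcr", "symptom"),
#'                    list(pcr = "positive", symptom = "Y"), maxGap = 7)
#' episodesTable(cg)  # one episode, Jan 5 .. Jan 7
#' @seealso \code{\link{episodesFindSeroconversion}} for the serology-based
#'   counterpart, \code{\link{episodesFill}}, \code{\link{episodesCount}}.
#' @export
episodesFind <- function(cg, scanCols, matchValues, maxGap = 7,
                         overwrite = FALSE, regex = FALSE) {
    stopifnot(is(cg, "Chronogram"))
    if (length(scanCols) == 0L)
        stop("'scanCols' must name at least one column", call. = FALSE)
    needCols(cg, scanCols, "scan column")
    if (!is.numeric(maxGap) || length(maxGap) != 1L || maxGap < 0)
        stop("'maxGap' must be a single non-negative number", call. = FALSE)
    epCols <- c("episode_number", "episode_start", "episode_end")
    if (any(epCols %in% names(cg@data)) && !overwrite)
        stop("episode columns already present; use overwrite = TRUE to redo",
             call. = FALSE)
    matchValues <- normalizeMatchValues(scanCols, matchValues)

    d <- cg@data
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]

    ## evidence day: any scanned column matches its value list
    evidence <- rep(FALSE, nrow(d))
    whichCols <- vector("list", nrow(d))
    for (col in scanCols) {
        hit <- matchesEvidence(d[[col]], matchValues[[col]], regex = regex)
        idxNew <- which(hit)
        evidence[idxNew] <- TRUE
        for (i in idxNew) whichCols[[i]] <- c(whichCols[[i]], col)
    }

    epNum <- rep(NA_integer_, nrow(d))
    epStart <- rep(NA, nrow(d)); epEnd <- rep(NA, nrow(d))
    epTabs <- list()
    for (p in unique(ids)) {
        rows <- which(ids == p)
        evRows <- rows[evidence[rows]]
        if (length(evRows) == 0L) next
        evRows <- evRows[order(dates[evRows])]
        clusters <- clusterDays(dates[evRows], maxGap)
        for (k in seq_along(clusters)) {
            cRows <- evRows[clusters[[k]]]
            s <- dates[cRows[1L]]; e <- dates[cRows[length(cRows)]]
            inSpan <- rows[dates[rows] >= s & dates[rows] <= e]
            epNum[inSpan] <- k
            epStart[inSpan] <- dates[inSpan] == s
            epEnd[inSpan] <- dates[inSpan] == e
            cols <- sort(unique(unlist(whichCols[cRows])))
            epTabs[[length(epTabs) + 1L]] <- data.frame(
                participant_id = p, episode_number = k,
                start_date = s, end_date = e,
                evidence_summary = sprintf("%d evidence day(s): %s",
                                           length(cRows),
                                           paste(cols, collapse = ", ")),
                stringsAsFactors = FALSE)
        }
    }
    d$episode_number <- epNum
    d$episode_start <- epStart
    d$episode_end <- epEnd
    episodes <- if (length(epTabs)) do.call(rbind, epTabs)
                else emptyEpisodeTable()
    cgReplace(cg, data = d,
              annotationCols = union(setdiff(cg@annotationCols, epCols),
                                     epCols),
              episodes = episodes,
              params = modifyList(cg@params,
                                  list(episodeMaxGap = as.integer(maxGap))))
}

normalizeMatchValues <- function(scanCols, matchValues) {
    if (!is.list(matchValues))
        matchValues <- rep(list(matchValues), length(scanCols))
    if (!is.null(names(matchValues)) && all(nzchar(names(matchValues)))) {
        missing <- setdiff(scanCols, names(matchValues))
        if (length(missing))
            stop(sprintf("no match values given for scan column(s): %s",
                         paste(missing, collapse = ", ")), call. = FALSE)
        matchValues <- matchValues[scanCols]
    } else if (length(matchValues) != length(scanCols))
        stop("'matchValues' must be one vector, or one entry per scan column",
             call. = FALSE)
    names(matchValues) <- scanCols
    if (any(vapply(matchValues, length, integer(1)) == 0L))
        stop("every scan column needs a non-empty match list", call. = FALSE)
    matchValues
}

#' Detect seroconversion windows from a serological marker
#'
#' A marker that flips from negative to positive between successive blood
#' tests implies an exposure somewhere inside the inter-measurement window
#' — for anti-nucleocapsid IgG under spike-based vaccination, an infection,
#' since nucleocapsid is encountered only in intact virus.  Because that
#' window (weeks to months between venepunctures) is much wider than the
#' day-scale episodes of \code{\link{episodesFind}}, the two annotations
#' are kept distinct: this function writes its own columns and table.
#'
#' Each transition from a measurement in \code{negativeValues} to the
#' \emph{next} chronological measurement in \code{positiveValues} yields one
#' seroconversion interval, half-open \code{(last_negative,
#' first_positive]} so a single measurement date can never sit in two
#' intervals.  Missing marker values are skipped (carried over), not
#' treated as negative.  Participants already positive at their first
#' measurement are flagged baseline-positive, not counted as
#' seroconverters; positive-to-negative reversions are flagged but create
#' no interval; repeated conversions (neg, pos, neg, pos) are all reported.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @param markerCol the serological marker column (e.g. anti-N IgG status).
#' @param negativeValues,positiveValues disjoint value sets classifying
#'   every non-missing marker value; any other value is an error naming the
#'   value and row.
#' @param overwrite as in \code{\link{episodesFind}}.
#' @return a new \code{Chronogram} with annotation columns
#'   \code{sero_episode_number}, \code{sero_window_start},
#'   \code{sero_window_end} (set on the rows inside each half-open
#'   interval), per-participant flags \code{sero_baseline_positive} and
#'   \code{sero_reversion}, and a filled \code{\link{seroconversionTable}}.
#' @examples
#' meta <- data.frame(participant_id = "P590")
#' ser <- data.frame(participant_id = "P590",
#'                   date = as.Date(c("2021-02-01", "2021-05-01")),
#'                   anti_N = c("negative", "positive"))
#' cg <- cgAssemble("2021-01-01", "2021-06-30", meta, list(serology = ser))
#' cg <- episodesFindSeroconversion(cg, "anti_N", "negative", "positive")
#' seroconversionTable(cg)  # one interval (Feb 1, May 1]
#' @export
episodesFindSeroconversion <- function(cg, markerCol, negativeValues,
                                       positiveValues, overwrite = FALSE) {
    stopifnot(is(cg, "Chronogram"))
    needCols(cg, markerCol, "marker column")
    norm <- function(s) tolower(trimws(as.character(s)))
    negN <- norm(negativeValues); posN <- norm(positiveValues)
    if (length(intersect(negN, posN)))
        stop("'negativeValues' and 'positiveValues' must be disjoint",
             call. = FALSE)
    seroCols <- c("sero_episode_number", "sero_window_start",
                  "sero_window_end", "sero_baseline_positive",
                  "sero_reversion")
    if (any(seroCols %in% names(cg@data)) && !overwrite)
        stop("seroconversion columns already present; use overwrite = TRUE to redo",
             call. = FALSE)

    d <- cg@data
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    marker <- d[[markerCol]]
    state <- rep(NA_character_, nrow(d))
    measured <- !is.na(marker)
    mNorm <- norm(marker[measured])
    state[measured][mNorm %in% negN] <- "neg"
    state[measured][mNorm %in% posN] <- "pos"
    unknown <- measured & is.na(state)
    if (any(unknown)) {
        i <- which(unknown)[1L]
        stop(sprintf(
            "marker value '%s' (participant %s, %s) is neither negative nor positive",
            as.character(marker[i]), ids[i], format(dates[i])),
            call. = FALSE)
    }

    n <- nrow(d)
    seroNum <- rep(NA_integer_, n)
    wStart <- as.Date(rep(NA_character_, n))
    wEnd <- as.Date(rep(NA_character_, n))
    basePos <- rep(NA, n)
    reversion <- rep(NA, n)
    tabs <- list()
    for (p in unique(ids)) {
        rows <- which(ids == p)
        mRows <- rows[measured[rows]]
        if (length(mRows) == 0L) next
        mRows <- mRows[order(dates[mRows])]
        st <- state[mRows]
        basePos[rows] <- st[1L] == "pos"
        reversion[rows] <- any(st[-length(st)] == "pos" & st[-1L] == "neg")
        conv <- which(st[-length(st)] == "neg" & st[-1L] == "pos")
        for (k in seq_along(conv)) {
            lastNeg <- dates[mRows[conv[k]]]
            firstPos <- dates[mRows[conv[k] + 1L]]
            inWin <- rows[dates[rows] > lastNeg & dates[rows] <= firstPos]
            seroNum[inWin] <- k
            wStart[inWin] <- lastNeg
            wEnd[inWin] <- firstPos
            tabs[[length(tabs) + 1L]] <- data.frame(
                participant_id = p, sero_episode_number = k,
                window_start = lastNeg, window_end = firstPos,
                stringsAsFactors = FALSE)
        }
    }
    d$sero_episode_number <- seroNum
    d$sero_window_start <- wStart
    d$sero_window_end <- wEnd
    d$sero_baseline_positive <- basePos
    d$sero_reversion <- reversion
    cgReplace(cg, data = d,
              annotationCols = union(setdiff(cg@annotationCols, seroCols),
                                     seroCols),
              seroEpisodes = if (length(tabs)) do.call(rbind, tabs)
                             else emptySeroTable())
}

#' Broadcast episode-level values over whole episodes
#'
#' A sequencing call (say, a lineage assignment from one swab) is usually
#' observed on a single day of an episode, but downstream slicing — taking
#' the first or last row of each episode while retaining the call — needs
#' it on every episode day.  For each episode and each column in
#' \code{fillCols}, a companion column \code{<col>_filled} carries one
#' episode-level value across the episode's span: the unique non-missing
#' value observed inside the span, or, when several distinct values occur,
#' whatever \code{policy} dictates.  Rows outside episodes stay missing.
#'
#' @param cg a \code{\link{Chronogram}} already run through
#'   \code{\link{episodesFind}}.
#' @param fillCols columns to fill (e.g. a sequencing-result column).
#' @param policy \code{"error"} (default): two or more distinct non-missing
#'   values inside one episode is a conflict error naming the participant,
#'   episode and values; \code{"first_nonmissing"}: the earliest-dated
#'   value wins.
#' @return a new \code{Chronogram} with the \code{*_filled} annotation
#'   columns.
#' @export
episodesFill <- function(cg, fillCols,
                         policy = c("error", "first_nonmissing")) {
    stopifnot(is(cg, "Chronogram"))
    policy <- match.arg(policy)
    needAnnotation(cg, "episode_number", "episodesFind")
    needCols(cg, fillCols, "fill column")
    d <- cg@data
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    newCols <- paste0(fillCols, "_filled")
    clash <- intersect(newCols, names(d))
    if (length(clash))
        stop(sprintf("filled column(s) already present: %s",
                     paste(clash, collapse = ", ")), call. = FALSE)
    for (ci in seq_along(fillCols)) {
        col <- fillCols[ci]
        filled <- rep(d[[col]][NA_integer_], nrow(d))
        if (nrow(cg@episodes)) for (e in seq_len(nrow(cg@episodes))) {
            ep <- cg@episodes[e, ]
            rows <- which(ids == ep$participant_id &
                          dates >= ep$start_date & dates <= ep$end_date)
            vals <- d[[col]][rows]
            keep <- !is.na(vals)
            if (!any(keep)) next
            uq <- unique(vals[keep])
            if (length(uq) > 1L && policy == "error")
                stop(sprintf(
                    "conflicting '%s' values within episode %d of participant %s: %s",
                    col, ep$episode_number, ep$participant_id,
                    paste(uq, collapse = " / ")), call. = FALSE)
            ## rows are date-ordered within participant, so the first
            ## non-missing is the earliest-dated
            filled[rows] <- vals[keep][1L]
        }
        d[[newCols[ci]]] <- filled
    }
    cgReplace(cg, data = d,
              annotationCols = union(cg@annotationCols, newCols))
}

#' Cumulative infection-episode count per person-day
#'
#' Adds \code{episodes_count}: for each row, the number of the
#' participant's infection episodes that have started on or before the row
#' date (the count steps up on the episode start date itself, the first day
#' infection is evidenced).  Non-decreasing over time by construction.
#'
#' Seroconversion intervals found by
#' \code{\link{episodesFindSeroconversion}} are included by default, dated
#' conservatively at their first-positive measurement; only \emph{sero-only}
#' conversions add to the count.  A seroconversion interval is attributed to
#' an existing test-evidenced episode (and not double counted) when that
#' episode starts inside the interval, or up to \code{seroLagDays} before
#' its last-negative measurement — a blood test drawn within the
#' serological lag after infection onset can still read negative, so the
#' window's left edge is soft.
#'
#' @param cg a \code{\link{Chronogram}} after \code{\link{episodesFind}}
#'   (calling this first is an error: the annotations build on each other).
#' @param includeSeroconversions count sero-only conversions as episodes.
#' @param seroLagDays assumed maximum days from infection to marker
#'   positivity, used only for attributing conversions to episodes
#'   (default 21, an upper-range IgG seroconversion time).
#' @return a new \code{Chronogram} with integer \code{episodes_count}.
#' @export
episodesCount <- function(cg, includeSeroconversions = TRUE,
                          seroLagDays = 21) {
    stopifnot(is(cg, "Chronogram"))
    needAnnotation(cg, "episode_number", "episodesFind")
    d <- cg@data
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    events <- infectionEvents(cg, includeSeroconversions, seroLagDays)
    cnt <- rep(0L, nrow(d))
    for (p in unique(events$participant_id)) {
        ev <- sort(events$event_date[events$participant_id == p])
        rows <- which(ids == p)
        cnt[rows] <- findInterval(dates[rows], ev)
    }
    d$episodes_count <- as.integer(cnt)
    cgReplace(cg, data = d,
              annotationCols = union(cg@annotationCols, "episodes_count"),
              params = modifyList(cg@params,
                                  list(includeSeroconversions =
                                           includeSeroconversions,
                                       seroLagDays = seroLagDays)))
}

## One row per counted infection event: test-evidenced episodes at their
## start date, plus (optionally) sero-only conversions at first-positive.
## A sero interval is attributed to (and deduplicated against) a
## test-evidenced episode starting in (window_start - seroLagDays,
## window_end].
infectionEvents <- function(cg, includeSeroconversions = TRUE,
                            seroLagDays = 21) {
    ep <- cg@episodes
    out <- data.frame(participant_id = as.character(ep$participant_id),
                      event_date = ep$start_date,
                      source = rep("episode", nrow(ep)),
                      end_date = ep$end_date,
                      stringsAsFactors = FALSE)
    if (includeSeroconversions && nrow(cg@seroEpisodes)) {
        se <- cg@seroEpisodes
        seroOnly <- vapply(seq_len(nrow(se)), function(i) {
            starts <- ep$start_date[ep$participant_id == se$participant_id[i]]
            !any(starts > se$window_start[i] - seroLagDays &
                 starts <= se$window_end[i])
        }, logical(1))
        if (any(seroOnly))
            out <- rbind(out, data.frame(
                participant_id = as.character(se$participant_id[seroOnly]),
                event_date = se$window_end[seroOnly],
                source = "seroconversion",
                end_date = se$window_end[seroOnly],
                stringsAsFactors = FALSE))
    }
    out[order(out$participant_id, out$event_date), , drop = FALSE]
}
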