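#' Cumulative vaccine-dose count per person-day
#'
#' Adds \code{vaccines_count}: for each row, the number of the
#' participant's vaccine doses dated on or before the row date.  The count
#' steps up on the dose date itself (day 0 of a dose is post-dose); since
#' one-day conventions move downstream analysis windows, this inclusive
#' convention is fixed and documented rather than configurable.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @param doseDateCols ordered character vector of registered metadata
#'   columns holding dose dates (or \code{NA} for doses not received).  Per
#'   participant, the non-missing dose dates must be strictly increasing in
#'   the listed order; a dose 2 earlier than dose 1 is an error naming the
#'   participant.  The columns are remembered for
#'   \code{\link{antigenicHistory}}.
#' @return a new \code{Chronogram} with integer \code{vaccines_count}.
#' @examples
#' meta <- data.frame(participant_id = "P1",
#'                    dose_1_date = as.Date("2021-01-01"),
#'                    dose_2_date = as.Date("2021-03-01"))
#' cg <- cgAssemble("2020-12-25", "2021-03-10", meta)
#' cg <- vaccinesCount(cg, c("dose_1_date", "dose_2_date"))
#' range(cgData(cg)$vaccines_count)  # 0 before dose 1, 2 from dose 2
#' @export
vaccinesCount <- function(cg, doseDateCols) {
    stopifnot(is(cg, "Chronogram"))
    needCols(cg, doseDateCols, "dose-date column")
    notMeta <- setdiff(doseDateCols, cg@metadataCols)
    if (length(notMeta))
        stop(sprintf("dose-date column(s) not registered as metadata: %s",
                     paste(notMeta, collapse = ", ")), call. = FALSE)
    d <- cg@data
    for (col in doseDateCols)
        if (!inherits(d[[col]], "Date"))
            stop(sprintf("dose-date column '%s' must hold class 'Date'", col),
                 call. = FALSE)
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    first <- !duplicated(ids)
    doseMat <- do.call(cbind, lapply(doseDateCols,
                                     function(col) as.numeric(d[[col]][first])))
    uids <- ids[first]
    for (i in seq_along(uids)) {
        dd <- doseMat[i, ]
        dd <- dd[!is.na(dd)]
        if (length(dd) > 1L && any(diff(dd) <= 0))
            stop(sprintf(
                "dose dates of participant %s are not strictly increasing in the order of 'doseDateCols'",
                uids[i]), call. = FALSE)
    }
    cnt <- rep(0L, nrow(d))
    for (i in seq_along(uids)) {
        dd <- sort(doseMat[i, ][!is.na(doseMat[i, ])])
        if (length(dd) == 0L) next
        rows <- which(ids == uids[i])
        cnt[rows] <- findInterval(as.numeric(dates[rows]), dd)
    }
    d$vaccines_count <- as.integer(cnt)
    cgReplace(cg, data = d,
              annotationCols = union(cg@annotationCols, "vaccines_count"),
              params = modifyList(cg@params,
                                  list(doseDateCols = doseDateCols)))
}

#' Cumulative antigenic-exposure count per person-day
#'
#' Adds \code{exposures_count = vaccines_count + episodes_count}, the total
#' number of antigenic exposures (vaccinations plus infections) accumulated
#' by each participant up to each day — e.g. two doses plus one prior
#' infection make three exposures to Spike.  Both component columns must
#' exist already; the order of annotation steps matters.
#'
#' @param cg a \code{\link{Chronogram}} after \code{\link{vaccinesCount}}
#'   and \code{\link{episodesCount}}.
#' @return a new \code{Chronogram} with integer \code{exposures_count}.
#' @export
exposuresCount <- function(cg) {
    stopifnot(is(cg, "Chronogram"))
    needAnnotation(cg, "vaccines_count", "vaccinesCount")
    needAnnotation(cg, "episodes_count", "episodesCount")
    d <- cg@data
    d$exposures_count <- as.integer(d$vaccines_count + d$episodes_count)
    cgReplace(cg, data = d,
              annotationCols = union(cg@annotationCols, "exposures_count"))
}

#' Antigenic-history string per person-day
#'
#' Adds \code{antigenic_history}: the chronologically ordered sequence of
#' all exposure events on or before the row date, encoded as
#' \code{"V1"}, \code{"V2"}, ... for vaccine doses (ordinal = dose index)
#' and \code{"I1"}, \code{"I2"}, ... for infections (ordinal =
#' chronological infection order), joined by \code{":"} — for example
#' \code{"V1:I1[Delta]:V2"}.  An infection code carries a bracketed label
#' when \code{infectionLabelCol} (typically a column filled by
#' \code{\link{episodesFill}}, e.g. a lineage call) has a value on the
#' episode's start day.  Rows before any exposure carry \code{""}.  A
#' vaccine dose and an infection on the same calendar day are ordered
#' vaccine first (and flagged with a message).  The history at any date is
#' a prefix of the history at every later date, and its code count equals
#' \code{exposures_count} on every row.
#'
#' The string format is this package's own convention;
#' \code{\link{parseAntigenicHistory}} round-trips it.
#'
#' @param cg a \code{\link{Chronogram}} after \code{\link{vaccinesCount}}
#'   and \code{\link{episodesCount}}.
#' @param infectionLabelCol optional column providing per-episode labels.
#' @param includeSeroconversions as in \code{\link{episodesCount}};
#'   defaults to the choice recorded by that call so the history length
#'   always matches \code{episodes_count}.
#' @return a new \code{Chronogram} with character \code{antigenic_history}.
#' @export
antigenicHistory <- function(cg, infectionLabelCol = NULL,
                             includeSeroconversions = NULL) {
    stopifnot(is(cg, "Chronogram"))
    needAnnotation(cg, "vaccines_count", "vaccinesCount")
    needAnnotation(cg, "episodes_count", "episodesCount")
    if (is.null(includeSeroconversions))
        includeSeroconversions <-
            isTRUE(cg@params$includeSeroconversions)
    seroLagDays <- if (is.null(cg@params$seroLagDays)) 21
                   else cg@params$seroLagDays
    doseDateCols <- cg@params$doseDateCols
    if (!is.null(infectionLabelCol)) needCols(cg, infectionLabelCol)
    d <- cg@data
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    first <- !duplicated(ids)
    uids <- ids[first]
    inf <- infectionEvents(cg, includeSeroconversions, seroLagDays)

    hist <- rep("", nrow(d))
    sameDayFlag <- FALSE
    for (i in seq_along(uids)) {
        p <- uids[i]
        rows <- which(ids == p)
        ## vaccine events, dose index = position in doseDateCols
        vDates <- as.Date(vapply(doseDateCols, function(col)
            as.numeric(d[[col]][rows[1L]]), numeric(1)),
            origin = "1970-01-01")
        vKeep <- which(!is.na(vDates))
        ev <- data.frame(date = vDates[vKeep],
                         code = sprintf("V%d", vKeep),
                         rank = 0L, stringsAsFactors = FALSE)
        ## infection events in chronological order
        pInf <- inf[inf$participant_id == p, , drop = FALSE]
        if (nrow(pInf)) {
            labels <- rep(NA_character_, nrow(pInf))
            if (!is.null(infectionLabelCol))
                for (k in seq_len(nrow(pInf))) {
                    v <- d[[infectionLabelCol]][rows[dates[rows] >= pInf$event_date[k] &
                                                     dates[rows] <= pInf$end_date[k]]]
                    v <- v[!is.na(v)]
                    if (length(v)) labels[k] <- as.character(v[1L])
                }
            code <- sprintf("I%d", seq_len(nrow(pInf)))
            code <- ifelse(is.na(labels), code,
                           sprintf("%s[%s]", code, labels))
            ev <- rbind(ev, data.frame(date = pInf$event_date, code = code,
                                       rank = 1L, stringsAsFactors = FALSE))
        }
        if (nrow(ev) == 0L) next
        if (anyDuplicated(ev$date) && length(unique(ev$rank[duplicated(ev$date) |
                                                            duplicated(ev$date, fromLast = TRUE)])) > 1L)
            sameDayFlag <- TRUE
        ## same-day tie: vaccine (rank 0) before infection (rank 1)
        ev <- ev[order(ev$date, ev$rank), , drop = FALSE]
        prefixes <- c("", cumpaste(ev$code))
        k <- findInterval(as.numeric(dates[rows]), as.numeric(ev$date))
        hist[rows] <- prefixes[k + 1L]
    }
    if (sameDayFlag)
        message("same-day vaccine + infection event(s): ordered vaccine first")
    d$antigenic_history <- hist
    cgReplace(cg, data = d,
              annotationCols = union(cg@annotationCols, "antigenic_history"))
}

cumpaste <- function(x) {
    out <- character(length(x))
    acc <- ""
    for (i in seq_along(x)) {
        acc <- if (nzchar(acc)) paste(acc, x[i], sep = ":") else x[i]
        out[i] <- acc
    }
    out
}

#' Parse an antigenic-history string
#'
#' Inverts the encoding of \code{\link{antigenicHistory}}.
#'
#' @param x a single history string, e.g. \code{"V1:I1[Delta]:V2"}.
#' @return a data.frame with one row per exposure event in order, columns
#'   \code{code}, \code{kind} (\code{"vaccine"}/\code{"infection"}),
#'   \code{ordinal} and \code{label} (\code{NA} when absent); zero rows for
#'   \code{""}.
#' @examples
#' parseAntigenicHistory("V1:I1[Delta]:V2")
#' @export
parseAntigenicHistory <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    empty <- data.frame(code = character(), kind = character(),
                        ordinal = integer(), label = character(),
                        stringsAsFactors = FALSE)
    if (is.na(x) || !nzchar(x)) return(empty)
    codes <- strsplit(x, ":", fixed = TRUE)[[1L]]
    m <- regmatches(codes, regexec("^([VI])([0-9]+)(\\[(.*)\\])?$", codes))
    bad <- vapply(m, length, integer(1)) == 0L
    if (any(bad))
        stop(sprintf("malformed history code: '%s'", codes[bad][1L]),
             call. = FALSE)
    data.frame(
        code = codes,
        kind = ifelse(vapply(m, `[`, "", 2L) == "V", "vaccine", "infection"),
        ordinal = as.integer(vapply(m, `[`, "", 3L)),
        label = ifelse(vapply(m, `[`, "", 4L) == "", NA_character_,
                       vapply(m, `[`, "", 5L)),
        stringsAsFactors = FALSE)
}
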