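## Internal: make a sub-cohort view with a provenance note, keeping slots.
asView <- function(cg, data, note) {
    cgReplace(cg, data = data, subcohort = TRUE,
              provenance = c(cg@provenance, note))
}

#' Filter chronogram rows by a predicate
#'
#' The first stage of the filter/window/select grammar: keep the rows for
#' which \code{expr}, evaluated over the chronogram's columns, is
#' \code{TRUE} (\code{NA} counts as \code{FALSE}).  The result is a
#' sub-cohort view: key uniqueness still holds, grid completeness is
#' relaxed, and the filter expression is recorded in
#' \code{\link{provenance}} for audit.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @param expr an unquoted predicate over column names, e.g.
#'   \code{exposures_count == 4 & episodes_count == 0}; objects from the
#'   calling environment may be referenced too.
#' @return a sub-cohort \code{Chronogram} view.
#' @examples
#' meta <- data.frame(participant_id = c("P1", "P2"), group = c("a", "b"))
#' cg <- cgAssemble("2021-01-01", "2021-01-05", meta)
#' nrow(cgFilter(cg, group == "a"))  # 5
#' @seealso \code{\link{windowByMetadata}}, \code{\link{selectVisit}}
#' @export
cgFilter <- function(cg, expr) {
    stopifnot(is(cg, "Chronogram"))
    e <- substitute(expr)
    keep <- eval(e, cg@data, parent.frame())
    if (!is.logical(keep) || !length(keep) %in% c(1L, nrow(cg@data)))
        stop("filter expression must evaluate to a logical over the rows",
             call. = FALSE)
    keep[is.na(keep)] <- FALSE
    asView(cg, cg@data[keep, , drop = FALSE],
           sprintf("filter: %s", paste(deparse(e), collapse = " ")))
}

#' Window a chronogram around a per-participant metadata date
#'
#' The second stage of the grammar: per participant, retain the rows dated
#' within \code{[ref + offsetLo, ref + offsetHi]} (both ends inclusive,
#' matching phrasings like "28-35 days after the second dose") of the
#' participant's reference date in \code{refCol}.  Offsets are signed, so
#' "the fortnight before" is \code{offsetLo = -14, offsetHi = -1}.
#' Participants with a missing reference date are dropped, with the count
#' logged to the console — sub-cohorting intentionally narrows.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @param refCol a registered metadata column of class \code{Date} (e.g. a
#'   dose date).
#' @param offsetLo,offsetHi signed day offsets, \code{offsetLo <= offsetHi}.
#' @return a sub-cohort \code{Chronogram} view.
#' @examples
#' meta <- data.frame(participant_id = "P1",
#'                    dose_2_date = as.Date("2021-06-01"))
#' cg <- cgAssemble("2021-05-01", "2021-07-31", meta)
#' w <- windowByMetadata(cg, "dose_2_date", 28, 35)
#' range(cgData(w)$date)  # 2021-06-29 .. 2021-07-06
#' @export
windowByMetadata <- function(cg, refCol, offsetLo, offsetHi) {
    stopifnot(is(cg, "Chronogram"))
    needCols(cg, refCol, "reference column")
    checkOffsets(offsetLo, offsetHi)
    ref <- cg@data[[refCol]]
    if (!inherits(ref, "Date"))
        stop(sprintf("reference column '%s' must hold class 'Date'", refCol),
             call. = FALSE)
    dropMissingRef(cg, is.na(ref), sprintf("missing '%s'", refCol))
    dates <- cg@data[[cg@dateCol]]
    keep <- !is.na(ref) & dates >= ref + offsetLo & dates <= ref + offsetHi
    asView(cg, cg@data[keep, , drop = FALSE],
           sprintf("window: %s %+d..%+d days", refCol, offsetLo, offsetHi))
}

#' Window a chronogram around an episode onset
#'
#' As \code{\link{windowByMetadata}}, but the per-participant reference is
#' the start date of the participant's \code{episodeOrdinal}-th infection
#' episode (from \code{\link{episodesFind}}).  Participants without that
#' episode are dropped, with the count logged.
#'
#' @param cg a \code{\link{Chronogram}} with episode annotations.
#' @param episodeOrdinal 1-based chronological episode number.
#' @param offsetLo,offsetHi signed day offsets, \code{offsetLo <= offsetHi}.
#' @return a sub-cohort \code{Chronogram} view.
#' @export
windowByEpisode <- function(cg, episodeOrdinal = 1L, offsetLo, offsetHi) {
    stopifnot(is(cg, "Chronogram"))
    needAnnotation(cg, "episode_number", "episodesFind")
    if (!is.numeric(episodeOrdinal) || length(episodeOrdinal) != 1L ||
        episodeOrdinal < 1)
        stop("'episodeOrdinal' must be a single integer >= 1", call. = FALSE)
    checkOffsets(offsetLo, offsetHi)
    ep <- cg@episodes[cg@episodes$episode_number == episodeOrdinal, ,
                      drop = FALSE]
    refOf <- ep$start_date[match(as.character(cg@data[[cg@idCol]]),
                                 ep$participant_id)]
    dropMissingRef(cg, is.na(refOf),
                   sprintf("no episode %d", as.integer(episodeOrdinal)))
    dates <- cg@data[[cg@dateCol]]
    keep <- !is.na(refOf) & dates >= refOf + offsetLo &
            dates <= refOf + offsetHi
    asView(cg, cg@data[keep, , drop = FALSE],
           sprintf("window: episode %d start %+d..%+d days",
                   as.integer(episodeOrdinal), offsetLo, offsetHi))
}

#' Window a chronogram around a study visit
#'
#' As \code{\link{windowByMetadata}}, but the per-participant reference is
#' the date of the participant's \code{visitOrdinal}-th chronological
#' non-missing entry in \code{visitCol} (e.g. the second venepuncture).
#' Participants with fewer visits are dropped, with the count logged.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @param visitCol column non-missing on visit days (an assay-result or
#'   visit-marker column).
#' @param visitOrdinal 1-based chronological visit number.
#' @param offsetLo,offsetHi signed day offsets, \code{offsetLo <= offsetHi}.
#' @return a sub-cohort \code{Chronogram} view.
#' @export
windowByVisit <- function(cg, visitCol, visitOrdinal = 1L, offsetLo,
                          offsetHi) {
    stopifnot(is(cg, "Chronogram"))
    needCols(cg, visitCol, "visit column")
    if (!is.numeric(visitOrdinal) || length(visitOrdinal) != 1L ||
        visitOrdinal < 1)
        stop("'visitOrdinal' must be a single integer >= 1", call. = FALSE)
    checkOffsets(offsetLo, offsetHi)
    d <- cg@data
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    visited <- !is.na(d[[visitCol]])
    uids <- ids[!duplicated(ids)]
    refDates <- as.Date(rep(NA_character_, length(uids)))
    for (i in seq_along(uids)) {
        vd <- sort(dates[visited & ids == uids[i]])
        if (length(vd) >= visitOrdinal) refDates[i] <- vd[visitOrdinal]
    }
    refOf <- refDates[match(ids, uids)]
    dropMissingRef(cg, is.na(refOf),
                   sprintf("fewer than %d '%s' visits",
                           as.integer(visitOrdinal), visitCol))
    keep <- !is.na(refOf) & dates >= refOf + offsetLo &
            dates <= refOf + offsetHi
    asView(cg, d[keep, , drop = FALSE],
           sprintf("window: visit %d of %s %+d..%+d days",
                   as.integer(visitOrdinal), visitCol, offsetLo, offsetHi))
}

#' Select one visit row per participant
#'
#' The last stage of the grammar: from a (typically windowed) view, drop
#' rows where \code{valueCol} is missing, then keep exactly one row per
#' participant — the earliest (\code{"first"}, the default: deterministic),
#' the latest (\code{"last"}), or the one nearest to a per-participant
#' reference date (\code{"nearest"}, ties to the earlier row).  The output
#' has at most one row per participant, each with a non-missing
#' \code{valueCol}, so downstream statistics never double-count an
#' individual.  Participants with no non-missing value are absent from the
#' output.
#'
#' @param cg a \code{\link{Chronogram}}, usually a windowed view.
#' @param valueCol the result column a retained row must carry.
#' @param policy \code{"first"}, \code{"last"} or \code{"nearest"}.
#' @param refCol metadata \code{Date} column required by
#'   \code{policy = "nearest"}.
#' @return a sub-cohort \code{Chronogram} view with <= 1 row per
#'   participant.
#' @export
selectVisit <- function(cg, valueCol, policy = c("first", "last", "nearest"),
                        refCol = NULL) {
    stopifnot(is(cg, "Chronogram"))
    policy <- match.arg(policy)
    needCols(cg, valueCol, "value column")
    if (policy == "nearest") {
        if (is.null(refCol))
            stop("policy 'nearest' needs a 'refCol' reference date column",
                 call. = FALSE)
        needCols(cg, refCol, "reference column")
    }
    d <- cg@data
    present <- !is.na(d[[valueCol]])
    d <- d[present, , drop = FALSE]
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    keepIdx <- integer()
    for (p in ids[!duplicated(ids)]) {
        rows <- which(ids == p)
        rows <- rows[order(dates[rows])]
        keepIdx <- c(keepIdx, switch(policy,
            first = rows[1L],
            last = rows[length(rows)],
            nearest = {
                ref <- d[[refCol]][rows[1L]]
                if (is.na(ref)) rows[1L]
                else rows[which.min(abs(as.numeric(dates[rows] - ref)))]
            }))
    }
    asView(cg, d[sort(keepIdx), , drop = FALSE],
           sprintf("select: %s per participant by '%s'", policy, valueCol))
}

checkOffsets <- function(offsetLo, offsetHi) {
    if (!is.numeric(offsetLo) || !is.numeric(offsetHi) ||
        length(offsetLo) != 1L || length(offsetHi) != 1L)
        stop("offsets must be single integers", call. = FALSE)
    if (offsetLo > offsetHi)
        stop("'offsetLo' must not exceed 'offsetHi'", call. = FALSE)
    invisible(TRUE)
}

dropMissingRef <- function(cg, missingRef, why) {
    ids <- as.character(cg@data[[cg@idCol]])
    dropped <- unique(ids[missingRef])
    if (length(dropped))
        message(sprintf("windowing dropped %d participant(s) (%s)",
                        length(dropped), why))
    invisible(TRUE)
}
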