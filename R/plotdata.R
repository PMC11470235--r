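#' Swimmers-plot event table
#'
#' Produces the tidy per-event table behind a swimmers plot: one record per
#' vaccine dose, per venepuncture visit, and per infection episode, for
#' each participant, sorted by participant (first-appearance order) then
#' date.  Visit records carry a shade value (e.g. the anti-N IgG result on
#' that day) for square shading; rendering itself is left to the caller.
#'
#' @param cg a \code{\link{Chronogram}} whose metadata includes dose dates.
#' @param visitMarkerCol column non-missing on venepuncture days.
#' @param shadeCol optional column whose visit-day value shades the visit
#'   square.
#' @param doseDateCols ordered dose-date metadata columns; defaults to
#'   those recorded by \code{\link{vaccinesCount}}.
#' @return a data.frame with columns \code{participant}, \code{date},
#'   \code{event_kind} (\code{"dose"}, \code{"visit"}, \code{"episode"}),
#'   \code{label} (dose index, visit ordinal, or episode number) and
#'   \code{shade_value}; zero rows (same schema) for an empty chronogram.
#' @export
swimmersTable <- function(cg, visitMarkerCol, shadeCol = NULL,
                          doseDateCols = NULL) {
    stopifnot(is(cg, "Chronogram"))
    needCols(cg, visitMarkerCol, "visit marker column")
    if (!is.null(shadeCol)) needCols(cg, shadeCol, "shade column")
    if (is.null(doseDateCols)) doseDateCols <- cg@params$doseDateCols
    if (is.null(doseDateCols))
        stop("no dose-date columns: pass 'doseDateCols' or run vaccinesCount() first",
             call. = FALSE)
    needCols(cg, doseDateCols, "dose-date column")
    d <- cg@data
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    uids <- ids[!duplicated(ids)]
    recs <- list()
    add <- function(p, date, kind, label, shade)
        recs[[length(recs) + 1L]] <<- data.frame(
            participant = p, date = date, event_kind = kind, label = label,
            shade_value = shade, stringsAsFactors = FALSE)
    for (p in uids) {
        rows <- which(ids == p)
        for (k in seq_along(doseDateCols)) {
            dd <- d[[doseDateCols[k]]][rows[1L]]
            if (!is.na(dd)) add(p, dd, "dose", as.character(k), NA_character_)
        }
        vRows <- rows[!is.na(d[[visitMarkerCol]][rows])]
        vRows <- vRows[order(dates[vRows])]
        for (k in seq_along(vRows)) {
            shade <- if (is.null(shadeCol)) NA_character_
                     else as.character(d[[shadeCol]][vRows[k]])
            add(p, dates[vRows[k]], "visit", as.character(k), shade)
        }
        ep <- cg@episodes[cg@episodes$participant_id == p, , drop = FALSE]
        for (k in seq_len(nrow(ep)))
            add(p, ep$start_date[k], "episode",
                as.character(ep$episode_number[k]), NA_character_)
    }
    if (!length(recs))
        return(data.frame(participant = character(),
                          date = as.Date(character()),
                          event_kind = character(), label = character(),
                          shade_value = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, recs)
    out <- out[order(match(out$participant, uids), out$date), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Titer-trajectory table with a highlighted analysis window
#'
#' Produces the tidy table behind per-participant assay trajectories: one
#' record per non-missing \code{valueCol} row, with \code{highlighted}
#' marking samples that fall inside the participant's inclusive
#' \code{[ref + offsetLo, ref + offsetHi]} window (e.g. 28-35 days after
#' the second dose), a per-participant \code{sample_index} so consecutive
#' samples can be line-joined, and any requested facet columns carried
#' along.  Participants whose reference date is missing keep their rows
#' with \code{highlighted = FALSE}; their count is logged.
#'
#' The highlighted rows are, by construction, exactly the
#' \code{\link{windowByMetadata}} output restricted to non-missing
#' \code{valueCol}.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @param valueCol numeric assay column (e.g. anti-S IgG).
#' @param refCol per-participant reference date column.
#' @param offsetLo,offsetHi inclusive signed day offsets of the window.
#' @param facetCols metadata columns copied into the output for faceting
#'   (e.g. interval group and prior-infection status).
#' @return a data.frame with columns \code{participant}, \code{date},
#'   \code{value}, \code{highlighted}, \code{sample_index}, then
#'   \code{facetCols}.
#' @export
trajectoryTable <- function(cg, valueCol, refCol, offsetLo = 28,
                            offsetHi = 35, facetCols = character()) {
    stopifnot(is(cg, "Chronogram"))
    needCols(cg, c(valueCol, refCol), "column")
    if (length(facetCols)) needCols(cg, facetCols, "facet column")
    checkOffsets(offsetLo, offsetHi)
    d <- cg@data
    keep <- !is.na(d[[valueCol]])
    d <- d[keep, , drop = FALSE]
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    ref <- d[[refCol]]
    if (!inherits(ref, "Date"))
        stop(sprintf("reference column '%s' must hold class 'Date'", refCol),
             call. = FALSE)
    noRef <- unique(ids[is.na(ref)])
    if (length(noRef))
        message(sprintf(
            "%d participant(s) lack '%s'; their samples are never highlighted",
            length(noRef), refCol))
    highlighted <- !is.na(ref) & dates >= ref + offsetLo &
                   dates <= ref + offsetHi
    ord <- order(match(ids, unique(ids)), dates)
    out <- data.frame(participant = ids, date = dates,
                      value = d[[valueCol]], highlighted = highlighted,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
    out$sample_index <- stats::ave(seq_len(nrow(out)), out$participant,
                                   FUN = seq_along)
    for (col in facetCols) out[[col]] <- d[[col]][ord]
    rownames(out) <- NULL
    out
}
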