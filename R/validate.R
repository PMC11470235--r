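#' Audit a chronogram against its invariants
#'
#' Checks every chronogram invariant and returns a report rather than
#' stopping at the first problem: key uniqueness (exactly one row per
#' \{participant, date\}), grid completeness (every participant has one row
#' for every day of the span, so rows = participants x days), dates inside
#' the declared span, and per-participant constancy of every registered
#' metadata column.  For sub-cohort views (see \code{\link{cgFilter}} and
#' the windowing functions) grid completeness is relaxed; key uniqueness is
#' always enforced.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @return a list of class \code{ChronogramValidation} with elements
#'   \code{ok} (logical) and \code{violations}, a data.frame with columns
#'   \code{rule_id} (\code{"duplicate_key"}, \code{"grid_incomplete"},
#'   \code{"date_outside_span"}, \code{"nonconstant_metadata"}),
#'   \code{participant_id} (or \code{NA}) and \code{detail}.  \code{ok} is
#'   \code{TRUE} iff no rule is violated.
#' @examples
#' meta <- data.frame(participant_id = c("P1", "P2"), group = c("a", "b"))
#' cg <- cgAssemble("2021-01-01", "2021-01-10", meta)
#' cgValidate(cg)$ok
#' @export
cgValidate <- function(cg) {
    stopifnot(is(cg, "Chronogram"))
    d <- cg@data
    if (!cg@idCol %in% names(d))
        stop(sprintf("id column '%s' is absent from the table", cg@idCol),
             call. = FALSE)
    if (!cg@dateCol %in% names(d))
        stop(sprintf("date column '%s' is absent from the table", cg@dateCol),
             call. = FALSE)
    ids <- as.character(d[[cg@idCol]])
    dates <- d[[cg@dateCol]]
    viol <- list()
    addViol <- function(rule, pid, detail)
        viol[[length(viol) + 1L]] <<- data.frame(
            rule_id = rule, participant_id = pid, detail = detail,
            stringsAsFactors = FALSE)

    ## one row per {participant, date}
    key <- keyString(ids, dates)
    dup <- unique(key[duplicated(key)])
    for (k in dup) {
        parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
        addViol("duplicate_key", parts[1L],
                sprintf("%d rows for {%s, %s}", sum(key == k),
                        parts[1L], parts[2L]))
    }

    ## dates within the inclusive span
    outside <- !is.na(dates) & (dates < cg@dateSpan[1L] | dates > cg@dateSpan[2L])
    if (any(outside))
        for (p in unique(ids[outside]))
            addViol("date_outside_span", p,
                    sprintf("%d row(s) dated outside %s..%s",
                            sum(outside & ids == p),
                            format(cg@dateSpan[1L]), format(cg@dateSpan[2L])))

    ## complete contiguous grid (skipped for sub-cohort views)
    if (!cg@subcohort) {
        nDays <- as.integer(cg@dateSpan[2L] - cg@dateSpan[1L]) + 1L
        cnt <- table(ids)
        for (p in names(cnt)[cnt != nDays])
            addViol("grid_incomplete", p,
                    sprintf("participant has %d rows, span requires %d",
                            as.integer(cnt[[p]]), nDays))
    }

    ## registered metadata columns constant per participant
    for (col in cg@metadataCols) {
        v <- d[[col]]
        nDistinct <- tapply(v, ids, function(x) {
            x <- x[!is.na(x)]
            length(unique(x))
        })
        for (p in names(nDistinct)[!is.na(nDistinct) & nDistinct > 1L])
            addViol("nonconstant_metadata", p,
                    sprintf("metadata column '%s' takes %d distinct values",
                            col, as.integer(nDistinct[[p]])))
    }

    violations <- if (length(viol)) do.call(rbind, viol)
        else data.frame(rule_id = character(), participant_id = character(),
                        detail = character(), stringsAsFactors = FALSE)
    structure(list(ok = nrow(violations) == 0L, violations = violations),
              class = "ChronogramValidation")
}

#' @export
print.ChronogramValidation <- function(x, ...) {
    if (x$ok) cat("chronogram OK: all invariants hold\n")
    else {
        cat(sprintf("chronogram INVALID: %d violation(s)\n",
                    nrow(x$violations)))
        print(x$violations, row.names = FALSE)
    }
    invisible(x)
}

#' Collapse a chronogram to one metadata row per participant
#'
#' Inverts the broadcast that \code{\link{cgAssemble}} performs: returns a
#' table with one row per participant carrying the participant identifier
#' and each registered metadata column's unique per-participant value.  Row
#' order is the participants' first-appearance order.  This collapsed table
#' is what \code{\link{cgSave}} stores instead of the full grid.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @return a \code{data.frame} with columns \code{idCol(cg)} followed by
#'   \code{metadataCols(cg)}; zero rows for an empty chronogram.
#' @examples
#' meta <- data.frame(participant_id = c("P1", "P2"), group = c("a", "b"))
#' cg <- cgAssemble("2021-01-01", "2021-01-10", meta)
#' collapseMetadata(cg)
#' @export
collapseMetadata <- function(cg) {
    stopifnot(is(cg, "Chronogram"))
    d <- cg@data
    ids <- as.character(d[[cg@idCol]])
    ## refuse on non-constant metadata: collapsing would silently pick a value
    for (col in cg@metadataCols) {
        nDistinct <- tapply(d[[col]], ids,
                            function(x) length(unique(x[!is.na(x)])))
        offender <- names(nDistinct)[!is.na(nDistinct) & nDistinct > 1L]
        if (length(offender))
            stop(sprintf(
                "metadata column '%s' is not constant for participant '%s'",
                col, offender[1L]), call. = FALSE)
    }
    ## one row per participant, first-appearance order; per column take the
    ## participant's unique non-missing value (guaranteed unique above)
    uids <- ids[!duplicated(ids)]
    out <- data.frame(uids, stringsAsFactors = FALSE)
    names(out) <- cg@idCol
    fid <- factor(ids, levels = uids)
    for (col in cg@metadataCols) {
        v <- d[[col]]
        picked <- rep(v[NA_integer_], length(uids))  # NA of v's class
        byId <- split(v, fid)
        for (i in seq_along(uids)) {
            vals <- byId[[i]]
            vals <- vals[!is.na(vals)]
            if (length(vals)) picked[i] <- vals[1L]
        }
        out[[col]] <- picked
    }
    rownames(out) <- NULL
    out
}

#' @describeIn Chronogram structured summary: participant/row counts, span,
#'   columns classified by role (registered metadata, package-produced
#'   annotations, everything else bar the keys = experiment), and
#'   per-column non-missing counts.
#' @export
setMethod("summary", "Chronogram", function(object, ...) {
    d <- object@data
    nonKey <- setdiff(names(d), c(object@idCol, object@dateCol))
    expCols <- setdiff(nonKey, c(object@metadataCols, object@annotationCols))
    nonMissing <- vapply(nonKey, function(col) sum(!is.na(d[[col]])),
                         integer(1))
    new("ChronogramSummary",
        nParticipants = nParticipants(object),
        dateSpan = object@dateSpan,
        nRows = nrow(d),
        subcohort = object@subcohort,
        columnsByRole = list(metadata = object@metadataCols,
                             experiment = expCols,
                             annotation = object@annotationCols),
        nonMissing = nonMissing)
})
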