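#' Assemble a chronogram from metadata and experiment tables
#'
#' Builds the dense person-day grid: one row per participant per calendar
#' day of the inclusive span \code{[start, end]}.  Per-participant metadata
#' is broadcast across each participant's rows; each experiment table's
#' result columns are placed on their observation dates and left missing
#' elsewhere.  Input data are checked before anything is joined: duplicate
#' \{participant, date\} keys in any experiment, duplicate participant
#' identifiers in the metadata, experiment rows for participants absent
#' from the metadata, and (by default) observation dates outside the span
#' all refuse assembly with an error naming the offending table and key —
#' silent loss of data in a curation tool is worse than a loud failure.
#'
#' @param start,end inclusive study span; \code{Date} or \code{"YYYY-MM-DD"}
#'   strings.
#' @param metadata a data.frame with one row per participant: the
#'   identifier column plus constant attributes (group labels, dose dates).
#'   Date-typed columns are kept as dates; see \code{\link{readCohortTable}}
#'   for parsing files.
#' @param experiments a (possibly named) list of sparse experiment
#'   data.frames, each keyed by \{\code{idCol}, \code{dateCol}\} with one
#'   or more result columns.  Names are used in error messages; unnamed
#'   tables are called \code{"experiment 1"}, etc.  Two experiment tables
#'   may share a participant/date but not a result-column name.
#' @param idCol,dateCol key column names, present in \code{metadata}
#'   (id only) and in every experiment table.
#' @param dropOutOfSpan if \code{TRUE}, experiment observations dated
#'   outside \code{[start, end]} are dropped with a logged count instead of
#'   refusing assembly.
#' @return a valid \code{\link{Chronogram}} with
#'   \code{nrow = nrow(metadata) * nDays}.
#' @examples
#' meta <- data.frame(participant_id = c("P1", "P2"), group = c("a", "b"))
#' sero <- data.frame(participant_id = "P1", date = as.Date("2021-01-02"),
#'                    titer = 100)
#' cg <- cgAssemble("2021-01-01", "2021-01-03", meta,
#'                  experiments = list(serology = sero))
#' nrow(cg)  # 2 participants x 3 days = 6
#' @seealso \code{\link{cgAddExperiment}} to add modalities later;
#'   \code{\link{cgValidate}} for the invariant audit.
#' @export
cgAssemble <- function(start, end, metadata, experiments = list(),
                       idCol = "participant_id", dateCol = "date",
                       dropOutOfSpan = FALSE) {
    start <- parseDates(start, what = "start")
    end <- parseDates(end, what = "end")
    stopifnot(length(start) == 1L, length(end) == 1L)
    if (start > end)
        stop("'start' must not be after 'end'", call. = FALSE)
    metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
    if (nrow(metadata) == 0L)
        stop("'metadata' must contain at least one participant",
             call. = FALSE)
    if (!idCol %in% names(metadata))
        stop(sprintf("id column '%s' not found in metadata", idCol),
             call. = FALSE)
    if (dateCol %in% names(metadata))
        stop(sprintf(
            "metadata must not contain the date column '%s'; dates belong to experiment tables",
            dateCol), call. = FALSE)
    metadata <- canonicalizeMissing(metadata)
    ids <- as.character(metadata[[idCol]])
    if (anyNA(ids))
        stop("metadata participant identifiers must not be missing",
             call. = FALSE)
    dupIds <- unique(ids[duplicated(ids)])
    if (length(dupIds))
        stop(sprintf("duplicate participant_id in metadata: %s",
                     paste(dupIds, collapse = ", ")), call. = FALSE)

    days <- seq(start, end, by = "day")
    nDays <- length(days)
    grid <- data.frame(rep(ids, each = nDays), rep(days, times = length(ids)),
                       stringsAsFactors = FALSE)
    names(grid) <- c(idCol, dateCol)

    ## broadcast metadata
    metaCols <- setdiff(names(metadata), idCol)
    rowOf <- match(grid[[idCol]], ids)
    for (col in metaCols)
        grid[[col]] <- metadata[[col]][rowOf]

    cg <- newChronogram(grid, idCol, dateCol, metadataCols = metaCols,
                        dateSpan = c(start, end))
    if (length(experiments)) {
        nms <- names(experiments)
        if (is.null(nms)) nms <- rep("", length(experiments))
        for (i in seq_along(experiments)) {
            nm <- if (nzchar(nms[i])) nms[i] else sprintf("experiment %d", i)
            cg <- cgAddExperiment(cg, experiments[[i]], name = nm,
                                  dropOutOfSpan = dropOutOfSpan)
        }
    }
    validObject(cg)
    cg
}

#' Add an experiment table to an existing chronogram
#'
#' Joins a sparse experiment table onto the person-day grid.  The result is
#' identical, cell for cell, to having passed the table to
#' \code{\link{cgAssemble}} in the first place, so modalities (including
#' slow research assays, or downstream analysis outputs) can be added as
#' they become available.
#'
#' @param cg a \code{\link{Chronogram}} (must not be a sub-cohort view).
#' @param exp a data.frame keyed by \{\code{idCol(cg)}, \code{dateCol(cg)}\}
#'   with one or more new result columns.  A 0-row table adds its result
#'   columns as all-missing.
#' @param name label used in error messages (the assay/modality name).
#' @param dropOutOfSpan as in \code{\link{cgAssemble}}.
#' @return a new \code{Chronogram}; \code{cg} is not modified.
#' @export
cgAddExperiment <- function(cg, exp, name = "experiment",
                            dropOutOfSpan = FALSE) {
    stopifnot(is(cg, "Chronogram"))
    if (cg@subcohort)
        stop("experiments are added to full chronograms, not sub-cohort views",
             call. = FALSE)
    idCol <- cg@idCol; dateCol <- cg@dateCol
    exp <- as.data.frame(exp, stringsAsFactors = FALSE)
    for (k in c(idCol, dateCol))
        if (!k %in% names(exp))
            stop(sprintf("experiment '%s' lacks key column '%s'", name, k),
                 call. = FALSE)
    exp <- canonicalizeMissing(exp)
    exp[[idCol]] <- as.character(exp[[idCol]])
    exp[[dateCol]] <- parseDates(exp[[dateCol]],
                                 what = sprintf("'%s' %s", name, dateCol))

    resCols <- setdiff(names(exp), c(idCol, dateCol))
    if (length(resCols) == 0L)
        stop(sprintf("experiment '%s' has no result columns", name),
             call. = FALSE)
    clash <- intersect(resCols, names(cg@data))
    if (length(clash))
        stop(sprintf("column_collision in experiment '%s': column(s) %s already present",
                     name, paste(clash, collapse = ", ")), call. = FALSE)

    if (nrow(exp)) {
        key <- keyString(exp[[idCol]], exp[[dateCol]])
        dup <- key[duplicated(key)]
        if (length(dup)) {
            parts <- strsplit(dup[1L], "\r", fixed = TRUE)[[1L]]
            stop(sprintf("duplicate_key in experiment '%s': {%s, %s}",
                         name, parts[1L], parts[2L]), call. = FALSE)
        }
        known <- unique(as.character(cg@data[[idCol]]))
        unknown <- setdiff(exp[[idCol]], known)
        if (length(unknown))
            stop(sprintf(
                "experiment '%s' has participant(s) absent from metadata: %s",
                name, paste(utils::head(unknown, 5L), collapse = ", ")),
                call. = FALSE)
        outside <- exp[[dateCol]] < cg@dateSpan[1L] |
                   exp[[dateCol]] > cg@dateSpan[2L]
        if (any(outside)) {
            if (!dropOutOfSpan)
                stop(sprintf(
                    "experiment '%s' has %d observation(s) dated outside %s..%s (set dropOutOfSpan = TRUE to drop them)",
                    name, sum(outside), format(cg@dateSpan[1L]),
                    format(cg@dateSpan[2L])), call. = FALSE)
            message(sprintf(
                "experiment '%s': dropped %d observation(s) outside the span",
                name, sum(outside)))
            exp <- exp[!outside, , drop = FALSE]
        }
    }

    d <- cg@data
    hit <- if (nrow(exp))
        match(keyString(exp[[idCol]], exp[[dateCol]]),
              keyString(d[[idCol]], d[[dateCol]]))
    else integer()
    for (col in resCols) {
        v <- rep(exp[[col]][NA_integer_], nrow(d))  # NA of the column's class
        if (length(hit)) v[hit] <- exp[[col]]
        d[[col]] <- v
    }
    cgReplace(cg, data = d)
}
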