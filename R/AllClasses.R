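#' @import methods
NULL

#' Chronogram: a dense person-day cohort table
#'
#' A \code{Chronogram} holds a long-format table with exactly one row per
#' \{participant, calendar date\} pair, covering every date of an inclusive
#' study span for every participant.  Columns fall into three roles:
#' \emph{metadata} (constant per participant, e.g. group labels and vaccine
#' dose dates), \emph{experiment} (sparse date-stamped assay or diary
#' observations), and \emph{annotation} (columns derived by this package,
#' e.g. episode numbers and cumulative exposure counts).  The key column
#' names and the column-role registries travel with the object so that every
#' downstream operation can find them without re-declaration.
#'
#' Sub-cohort views (produced by the filter/window/select grammar) relax the
#' complete-grid invariant but keep key uniqueness; \code{isSubcohort} marks
#' them and \code{provenance} records how they were derived.
#'
#' @slot data a \code{data.frame}; one row per participant-day.
#' @slot idCol name of the participant identifier column.  Identifiers are
#'   opaque strings; they are never coerced to numbers (REDCap-style exports
#'   may carry leading zeros).
#' @slot dateCol name of the calendar-date column (class \code{Date},
#'   timezone-free whole days).
#' @slot metadataCols names of the registered per-participant-constant
#'   columns.
#' @slot annotationCols names of columns produced by annotation functions.
#' @slot dateSpan length-2 \code{Date}: inclusive start and end of the grid.
#' @slot subcohort logical flag; \code{TRUE} for filtered/windowed views.
#' @slot provenance character vector of audit notes (filter expressions,
#'   window specifications) appended by sub-cohorting operations.
#' @slot episodes per-participant infection-episode table with columns
#'   \code{participant_id}, \code{episode_number}, \code{start_date},
#'   \code{end_date}, \code{evidence_summary} (filled by
#'   \code{\link{episodesFind}}).
#' @slot seroEpisodes per-participant seroconversion-interval table with
#'   columns \code{participant_id}, \code{sero_episode_number},
#'   \code{window_start}, \code{window_end} (filled by
#'   \code{\link{episodesFindSeroconversion}}).
#' @slot params list of bookkeeping values recorded by annotation steps
#'   (e.g. the ordered dose-date columns used by \code{\link{vaccinesCount}}).
#'
#' @seealso \code{\link{cgAssemble}}, \code{\link{cgValidate}},
#'   \code{\link{summary,Chronogram-method}}
#' @export
setClass("Chronogram",
    representation(
        data = "data.frame",
        idCol = "character",
        dateCol = "character",
        metadataCols = "character",
        annotationCols = "character",
        dateSpan = "Date",
        subcohort = "logical",
        provenance = "character",
        episodes = "data.frame",
        seroEpisodes = "data.frame",
        params = "list"
    ),
    prototype(
        subcohort = FALSE,
        provenance = character(),
        params = list()
    )
)

## Structural validity only: cheap checks that must hold for the object to be
## usable at all.  The full invariant audit (grid completeness, metadata
## constancy, ...) lives in cgValidate(), which returns a report instead of
## stopping.
setValidity("Chronogram", function(object) {
    msgs <- character()
    d <- object@data
    if (length(object@idCol) != 1L || is.na(object@idCol))
        msgs <- c(msgs, "'idCol' must be a single column name")
    if (length(object@dateCol) != 1L || is.na(object@dateCol))
        msgs <- c(msgs, "'dateCol' must be a single column name")
    if (length(msgs) == 0L) {
        if (!object@idCol %in% names(d))
            msgs <- c(msgs, sprintf("id column '%s' not found in data",
                                    object@idCol))
        if (!object@dateCol %in% names(d))
            msgs <- c(msgs, sprintf("date column '%s' not found in data",
                                    object@dateCol))
    }
    if (length(object@dateSpan) != 2L || anyNA(object@dateSpan))
        msgs <- c(msgs, "'dateSpan' must be two non-missing dates")
    else if (object@dateSpan[1L] > object@dateSpan[2L])
        msgs <- c(msgs, "'dateSpan' start is after its end")
    bad <- setdiff(object@metadataCols, names(d))
    if (length(bad))
        msgs <- c(msgs, sprintf("registered metadata column(s) missing: %s",
                                paste(bad, collapse = ", ")))
    bad <- setdiff(object@annotationCols, names(d))
    if (length(bad))
        msgs <- c(msgs, sprintf("registered annotation column(s) missing: %s",
                                paste(bad, collapse = ", ")))
    if (object@dateCol %in% names(d) && !inherits(d[[object@dateCol]], "Date"))
        msgs <- c(msgs, "date column must hold class 'Date'")
    if (length(msgs)) msgs else TRUE
})

#' Summary of a chronogram
#'
#' Produced by \code{summary()} on a \code{\link{Chronogram}}: participant
#' and row counts, the date span, the columns grouped by role, and per-column
#' non-missing counts.
#'
#' @slot nParticipants number of distinct participants.
#' @slot dateSpan inclusive study span.
#' @slot nRows number of person-day rows.
#' @slot subcohort whether the summarized object is a sub-cohort view.
#' @slot columnsByRole list with elements \code{metadata},
#'   \code{experiment}, \code{annotation}.
#' @slot nonMissing named integer vector of non-missing cell counts for the
#'   non-key columns.
#' @export
setClass("ChronogramSummary",
    representation(
        nParticipants = "integer",
        dateSpan = "Date",
        nRows = "integer",
        subcohort = "logical",
        columnsByRole = "list",
        nonMissing = "integer"
    )
)

## Internal constructor: normalizes row names, orders slots, runs validity.
newChronogram <- function(data, idCol, dateCol, metadataCols,
                          annotationCols = character(),
                          dateSpan, subcohort = FALSE,
                          provenance = character(),
                          episodes = NULL, seroEpisodes = NULL,
                          params = list()) {
    rownames(data) <- NULL
    if (is.null(episodes)) episodes <- emptyEpisodeTable()
    if (is.null(seroEpisodes)) seroEpisodes <- emptySeroTable()
    new("Chronogram",
        data = data, idCol = idCol, dateCol = dateCol,
        metadataCols = metadataCols, annotationCols = annotationCols,
        dateSpan = as.Date(dateSpan), subcohort = subcohort,
        provenance = provenance, episodes = episodes,
        seroEpisodes = seroEpisodes, params = params)
}

emptyEpisodeTable <- function() {
    data.frame(participant_id = character(), episode_number = integer(),
               start_date = as.Date(character()),
               end_date = as.Date(character()),
               evidence_summary = character(),
               stringsAsFactors = FALSE)
}

emptySeroTable <- function() {
    data.frame(participant_id = character(),
               sero_episode_number = integer(),
               window_start = as.Date(character()),
               window_end = as.Date(character()),
               stringsAsFactors = FALSE)
}

## Clone with replacement slots; keeps everything else.
cgReplace <- function(cg, data = cg@data,
                      metadataCols = cg@metadataCols,
                      annotationCols = cg@annotationCols,
                      subcohort = cg@subcohort,
                      provenance = cg@provenance,
                      episodes = cg@episodes,
                      seroEpisodes = cg@seroEpisodes,
                      params = cg@params) {
    newChronogram(data, cg@idCol, cg@dateCol, metadataCols, annotationCols,
                  cg@dateSpan, subcohort, provenance, episodes, seroEpisodes,
                  params)
}
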