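#' Accessors for Chronogram objects
#'
#' Accessor functions are the supported way to reach the components of a
#' \code{\link{Chronogram}}; the slots themselves are internal.
#'
#' @param x a \code{Chronogram}.
#' @return \code{cgData} returns the underlying person-day
#'   \code{data.frame}; \code{idCol}/\code{dateCol} the key column names;
#'   \code{metadataCols}/\code{annotationCols} the role registries;
#'   \code{dateSpan} the inclusive study span; \code{participants} the
#'   participant identifiers in first-appearance order; \code{nParticipants}
#'   their count; \code{isSubcohort} the view flag; \code{provenance} the
#'   audit notes; \code{episodesTable} the per-participant episode table;
#'   \code{seroconversionTable} the seroconversion-interval table.
#'
#' @examples
#' meta <- data.frame(participant_id = c("P1", "P2"), group = c("a", "b"))
#' cg <- cgAssemble("2021-01-01", "2021-01-05", meta)
#' nParticipants(cg)
#' dateSpan(cg)
#' head(cgData(cg))
#'
#' @name chronogram-accessors
#' @aliases cgData idCol dateCol metadataCols annotationCols dateSpan
#'   participants nParticipants isSubcohort provenance episodesTable
#'   seroconversionTable
NULL

#' @rdname chronogram-accessors
#' @export
setGeneric("cgData", function(x) standardGeneric("cgData"))
#' @rdname chronogram-accessors
#' @export
setGeneric("idCol", function(x) standardGeneric("idCol"))
#' @rdname chronogram-accessors
#' @export
setGeneric("dateCol", function(x) standardGeneric("dateCol"))
#' @rdname chronogram-accessors
#' @export
setGeneric("metadataCols", function(x) standardGeneric("metadataCols"))
#' @rdname chronogram-accessors
#' @export
setGeneric("annotationCols", function(x) standardGeneric("annotationCols"))
#' @rdname chronogram-accessors
#' @export
setGeneric("dateSpan", function(x) standardGeneric("dateSpan"))
#' @rdname chronogram-accessors
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))
#' @rdname chronogram-accessors
#' @export
setGeneric("nParticipants", function(x) standardGeneric("nParticipants"))
#' @rdname chronogram-accessors
#' @export
setGeneric("isSubcohort", function(x) standardGeneric("isSubcohort"))
#' @rdname chronogram-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname chronogram-accessors
#' @export
setGeneric("episodesTable", function(x) standardGeneric("episodesTable"))
#' @rdname chronogram-accessors
#' @export
setGeneric("seroconversionTable",
           function(x) standardGeneric("seroconversionTable"))

#' @rdname chronogram-accessors
setMethod("cgData", "Chronogram", function(x) x@data)
#' @rdname chronogram-accessors
setMethod("idCol", "Chronogram", function(x) x@idCol)
#' @rdname chronogram-accessors
setMethod("dateCol", "Chronogram", function(x) x@dateCol)
#' @rdname chronogram-accessors
setMethod("metadataCols", "Chronogram", function(x) x@metadataCols)
#' @rdname chronogram-accessors
setMethod("annotationCols", "Chronogram", function(x) x@annotationCols)
#' @rdname chronogram-accessors
setMethod("dateSpan", "Chronogram", function(x) x@dateSpan)
#' @rdname chronogram-accessors
setMethod("participants", "Chronogram", function(x) {
    ids <- x@data[[x@idCol]]
    ids[!duplicated(ids)]
})
#' @rdname chronogram-accessors
setMethod("nParticipants", "Chronogram",
          function(x) length(participants(x)))
#' @rdname chronogram-accessors
setMethod("isSubcohort", "Chronogram", function(x) x@subcohort)
#' @rdname chronogram-accessors
setMethod("provenance", "Chronogram", function(x) x@provenance)
#' @rdname chronogram-accessors
setMethod("episodesTable", "Chronogram", function(x) x@episodes)
#' @rdname chronogram-accessors
setMethod("seroconversionTable", "Chronogram", function(x) x@seroEpisodes)

#' @describeIn Chronogram number of person-day rows.
#' @param x a \code{Chronogram}.
#' @export
setMethod("nrow", "Chronogram", function(x) nrow(x@data))

#' @describeIn Chronogram compact display: span, dimensions, column roles.
#' @param object a \code{Chronogram}.
#' @export
setMethod("show", "Chronogram", function(object) {
    d <- object@data
    cat(sprintf("%s chronogram: %d participants x %d days (%d rows)\n",
                if (object@subcohort) "Sub-cohort view of a" else "A",
                nParticipants(object),
                as.integer(object@dateSpan[2L] - object@dateSpan[1L]) + 1L,
                nrow(d)))
    cat(sprintf("  span: %s .. %s (inclusive)\n",
                format(object@dateSpan[1L]), format(object@dateSpan[2L])))
    cat(sprintf("  key: {%s, %s}\n", object@idCol, object@dateCol))
    expCols <- setdiff(names(d), c(object@idCol, object@dateCol,
                                   object@metadataCols,
                                   object@annotationCols))
    fmtCols <- function(x) if (length(x)) paste(x, collapse = ", ") else "<none>"
    cat("  metadata:  ", fmtCols(object@metadataCols), "\n", sep = "")
    cat("  experiment:", fmtCols(expCols), "\n", sep = " ")
    cat("  annotation:", fmtCols(object@annotationCols), "\n", sep = " ")
    if (nrow(object@episodes))
        cat(sprintf("  episodes: %d across %d participants\n",
                    nrow(object@episodes),
                    length(unique(object@episodes$participant_id))))
    if (length(object@provenance))
        cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
    invisible(NULL)
})

#' @describeIn ChronogramSummary fixed-field-order text rendering:
#'   participants, span, rows, columns by role, non-missing counts.
#' @param object a \code{ChronogramSummary}.
#' @export
setMethod("show", "ChronogramSummary", function(object) {
    cat("participants:", object@nParticipants, "\n")
    cat("span:        ", format(object@dateSpan[1L]), "..",
        format(object@dateSpan[2L]), "\n")
    cat("rows:        ", object@nRows,
        if (object@subcohort) " (sub-cohort view)" else "", "\n", sep = "")
    for (role in c("metadata", "experiment", "annotation")) {
        cols <- object@columnsByRole[[role]]
        cat(sprintf("%-11s  %s\n", paste0(role, ":"),
                    if (length(cols)) paste(cols, collapse = ", ")
                    else "<none>"))
    }
    if (length(object@nonMissing)) {
        cat("non-missing:\n")
        for (nm in names(object@nonMissing))
            cat(sprintf("  %-20s %d\n", nm, object@nonMissing[[nm]]))
    }
    invisible(NULL)
})
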