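FORMAT_TAG <- "cohortgram-v1"

#' Save a chronogram as a sparse plain-text container
#'
#' Writes a directory holding a JSON manifest plus CSV parts: the metadata
#' collapsed to one row per participant, the sparse observations (only
#' person-days carrying at least one non-missing experiment or annotation
#' value), and the episode tables.  File size therefore grows with the
#' number of observations, not with participants x days; the dense grid is
#' regenerated on load.  Plain-text parts keep the artifact inspectable
#' and diff-able, and writing is deterministic: saving the same chronogram
#' twice produces byte-identical files.
#'
#' Annotation columns are saved as data, not recomputed on load, so a later
#' algorithm change can never silently alter previously saved analysis
#' results; re-run the annotation functions explicitly to re-annotate.
#'
#' For sub-cohort views the grid is not reconstructible from the span, so
#' every retained row is written; the view flag and provenance notes are
#' recorded in the manifest.
#'
#' The container format (\code{"cohortgram-v1"}, named in the manifest) is
#' this package's own convention.  The manifest carries an MD5 checksum per
#' part; \code{\link{cgLoad}} verifies them.
#'
#' @param cg a \code{\link{Chronogram}}.
#' @param path directory to create (must not already exist unless
#'   \code{overwrite = TRUE}).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{cgLoad}}
#' @export
cgSave <- function(cg, path, overwrite = FALSE) {
    stopifnot(is(cg, "Chronogram"))
    if (dir.exists(path)) {
        if (!overwrite)
            stop(sprintf("'%s' already exists; use overwrite = TRUE", path),
                 call. = FALSE)
        unlink(file.path(path, c("manifest.json", "metadata.csv",
                                 "observations.csv", "episodes.csv",
                                 "sero_episodes.csv")))
    } else if (!dir.create(path, recursive = TRUE))
        stop(sprintf("cannot create directory '%s'", path), call. = FALSE)

    d <- cg@data
    nonKey <- setdiff(names(d), c(cg@idCol, cg@dateCol))
    obsCols <- setdiff(nonKey, cg@metadataCols)

    meta <- collapseMetadata(cg)
    if (cg@subcohort) {
        obs <- d[, c(cg@idCol, cg@dateCol, obsCols), drop = FALSE]
    } else {
        keep <- if (length(obsCols))
            Reduce(`|`, lapply(obsCols, function(col) !is.na(d[[col]])))
        else rep(FALSE, nrow(d))
        obs <- d[keep, c(cg@idCol, cg@dateCol, obsCols), drop = FALSE]
    }

    writePart(meta, file.path(path, "metadata.csv"))
    writePart(obs, file.path(path, "observations.csv"))
    writePart(cg@episodes, file.path(path, "episodes.csv"))
    writePart(cg@seroEpisodes, file.path(path, "sero_episodes.csv"))

    parts <- c("metadata.csv", "observations.csv", "episodes.csv",
               "sero_episodes.csv")
    sums <- as.list(tools::md5sum(file.path(path, parts)))
    names(sums) <- parts

    manifest <- list(
        format = FORMAT_TAG,
        id_col = cg@idCol,
        date_col = cg@dateCol,
        date_span = format(cg@dateSpan),
        metadata_cols = as.list(cg@metadataCols),
        annotation_cols = as.list(cg@annotationCols),
        column_order = as.list(names(d)),
        column_classes = lapply(d, storageClassOf),
        subcohort = cg@subcohort,
        provenance = as.list(cg@provenance),
        params = cg@params,
        participants = as.list(as.character(meta[[cg@idCol]])),
        checksums = sums)
    jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
    invisible(path)
}

storageClassOf <- function(v) {
    if (inherits(v, "Date")) "Date"
    else if (is.integer(v)) "integer"
    else if (is.numeric(v)) "numeric"
    else if (is.logical(v)) "logical"
    else "character"
}

## CSV writer with lossless, deterministic cell encoding: dates ISO-8601,
## doubles with 17 significant digits (binary round-trip), NA as the empty
## string, character cells quoted.
writePart <- function(df, file) {
    enc <- df
    quoteCols <- integer()
    for (j in seq_along(df)) {
        v <- df[[j]]
        cell <- if (inherits(v, "Date")) format(v, "%Y-%m-%d")
        else if (is.integer(v)) as.character(v)
        else if (is.numeric(v)) sprintf("%.17g", v)
        else if (is.logical(v)) as.character(v)
        else {
            quoteCols <- c(quoteCols, j)
            as.character(v)
        }
        cell[is.na(v)] <- NA_character_
        enc[[j]] <- cell
    }
    ## NA is written as the bare token NA: canonicalization guarantees no
    ## chronogram cell ever holds the literal string "NA", so the empty
    ## string (a legitimate value, e.g. a pre-exposure antigenic history)
    ## stays distinguishable from missing
    utils::write.table(enc, file, sep = ",", na = "NA", row.names = FALSE,
                       col.names = TRUE, quote = quoteCols,
                       qmethod = "double", eol = "\n",
                       fileEncoding = "UTF-8")
}

readPart <- function(file, classes) {
    df <- utils::read.csv(file, colClasses = "character", na.strings = "NA",
                          check.names = FALSE, fileEncoding = "UTF-8")
    for (col in names(df)) {
        cls <- classes[[col]]
        if (is.null(cls)) cls <- "character"
        df[[col]] <- switch(cls,
            Date = as.Date(df[[col]]),
            integer = as.integer(df[[col]]),
            numeric = as.numeric(df[[col]]),
            logical = as.logical(df[[col]]),
            df[[col]])
    }
    df
}

#' Load a saved chronogram
#'
#' Reads a \code{\link{cgSave}} container, verifies the format version and
#' the per-part checksums, regenerates the dense person-day grid from the
#' manifest's span and participant list (sub-cohort views are restored
#' row-for-row instead), re-broadcasts the metadata, places the sparse
#' observations, and restores column classes, role registries, episode
#' tables, parameters and provenance.  \code{cgLoad(cgSave(cg))} equals
#' \code{cg} in every cell, attribute and registry entry.
#'
#' @param path directory written by \code{\link{cgSave}}.
#' @return a \code{\link{Chronogram}}.
#' @export
cgLoad <- function(path) {
    mf <- file.path(path, "manifest.json")
    if (!file.exists(mf))
        stop(sprintf("'%s' does not contain a chronogram manifest", path),
             call. = FALSE)
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    if (!identical(manifest$format, FORMAT_TAG))
        stop(sprintf(
            "unsupported container format '%s' (this build reads %s)",
            as.character(manifest$format), FORMAT_TAG), call. = FALSE)
    for (part in names(manifest$checksums)) {
        f <- file.path(path, part)
        if (!file.exists(f))
            stop(sprintf("integrity error: part '%s' is missing", part),
                 call. = FALSE)
        if (!identical(unname(tools::md5sum(f)),
                       manifest$checksums[[part]]))
            stop(sprintf("integrity error: checksum mismatch for '%s'", part),
                 call. = FALSE)
    }
    idCol <- manifest$id_col
    dateCol <- manifest$date_col
    classes <- as.list(manifest$column_classes)
    span <- as.Date(unlist(manifest$date_span))
    metaCols <- as.character(unlist(manifest$metadata_cols))
    annCols <- as.character(unlist(manifest$annotation_cols))
    colOrder <- as.character(unlist(manifest$column_order))

    meta <- readPart(file.path(path, "metadata.csv"), classes)
    obs <- readPart(file.path(path, "observations.csv"), classes)
    obs[[dateCol]] <- as.Date(obs[[dateCol]])
    participants <- as.character(unlist(manifest$participants))

    badDate <- nrow(obs) > 0L &&
        (any(obs[[dateCol]] < span[1L]) || any(obs[[dateCol]] > span[2L]))
    badId <- nrow(obs) > 0L && !all(obs[[idCol]] %in% participants)
    if (badDate || badId)
        stop("integrity error: observations fall outside the manifest's grid",
             call. = FALSE)

    if (isTRUE(manifest$subcohort)) {
        d <- obs
        mRow <- match(d[[idCol]], meta[[idCol]])
        for (col in metaCols) d[[col]] <- meta[[col]][mRow]
    } else {
        days <- seq(span[1L], span[2L], by = "day")
        nDays <- length(days)
        d <- data.frame(rep(participants, each = nDays),
                        rep(days, times = length(participants)),
                        stringsAsFactors = FALSE)
        names(d) <- c(idCol, dateCol)
        mRow <- match(d[[idCol]], meta[[idCol]])
        for (col in metaCols) d[[col]] <- meta[[col]][mRow]
        obsCols <- setdiff(names(obs), c(idCol, dateCol))
        hit <- match(keyString(obs[[idCol]], obs[[dateCol]]),
                     keyString(d[[idCol]], d[[dateCol]]))
        for (col in obsCols) {
            v <- rep(obs[[col]][NA_integer_], nrow(d))
            v[hit] <- obs[[col]]
            d[[col]] <- v
        }
    }
    d <- d[, colOrder, drop = FALSE]

    episodes <- readPart(file.path(path, "episodes.csv"),
                         list(participant_id = "character",
                              episode_number = "integer",
                              start_date = "Date", end_date = "Date",
                              evidence_summary = "character"))
    sero <- readPart(file.path(path, "sero_episodes.csv"),
                     list(participant_id = "character",
                          sero_episode_number = "integer",
                          window_start = "Date", window_end = "Date"))
    params <- manifest$params
    if (is.null(params)) params <- list()
    if (!is.null(params$doseDateCols))
        params$doseDateCols <- as.character(unlist(params$doseDateCols))
    cg <- newChronogram(d, idCol, dateCol, metaCols, annCols,
                        dateSpan = span,
                        subcohort = isTRUE(manifest$subcohort),
                        provenance = as.character(unlist(manifest$provenance)),
                        episodes = episodes, seroEpisodes = sero,
                        params = params)
    validObject(cg)
    cg
}
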