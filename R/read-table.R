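#' Read a metadata or experiment table from CSV or a SQL database
#'
#' Reads one rectangular table from a CSV file (RFC 4180, UTF-8) or from a
#' SQL database (a \code{DBI} connection, or the path of a SQLite file),
#' normalizes missing values (\code{""}, \code{"NA"}, \code{NULL} all
#' become \code{NA}), and parses date-like columns to calendar days.
#'
#' Date parsing is strict: ISO-8601 (\code{"YYYY-MM-DD"}) by default, other
#' dialects only via an explicit \code{dateFormat}.  Ambiguous dialects are
#' never guessed — a cell such as \code{"07/03/2021"} with the default
#' format is a per-cell parse error listing the offending rows, not a
#' silent coercion.  Columns listed in \code{dateCols} must parse; when
#' \code{dateCols} is \code{NULL}, columns whose every non-missing value
#' matches the ISO pattern are parsed automatically.
#'
#' Participant identifiers are opaque strings and are never coerced to
#' numbers (REDCap-style exports may carry leading zeros); name the column
#' in \code{idCol} (or \code{keepCharacter}) to protect it.  Other columns
#' whose values are all numeric are converted to numeric.
#'
#' @param source a CSV file path, a SQLite file path (extension
#'   \code{.sqlite}/\code{.db}/\code{.sqlite3}), or a \code{DBI} connection.
#' @param tableName table to read when \code{source} is a database.
#' @param idCol participant identifier column, kept as character.
#' @param dateCols columns to parse as dates; \code{NULL} auto-detects
#'   ISO-formatted columns.
#' @param dateFormat \code{strptime}-style format for \code{dateCols}.
#' @param keepCharacter further columns to exclude from numeric conversion.
#' @return a \code{data.frame} ready for \code{\link{cgAssemble}}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(participant_id = c("007", "008"),
#'                      dose_1_date = c("2021-01-04", "2021-02-01")),
#'           f, row.names = FALSE)
#' readCohortTable(f, idCol = "participant_id")
#' @export
readCohortTable <- function(source, tableName = NULL,
                            idCol = "participant_id", dateCols = NULL,
                            dateFormat = "%Y-%m-%d",
                            keepCharacter = character()) {
    df <- if (inherits(source, "DBIConnection")) {
        readSqlTable(source, tableName)
    } else if (is.character(source) && length(source) == 1L) {
        if (!file.exists(source))
            stop(sprintf("no such file: %s", source), call. = FALSE)
        if (grepl("\\.(sqlite3?|db)$", source, ignore.case = TRUE)) {
            con <- openSqlite(source)
            on.exit(DBI::dbDisconnect(con))
            readSqlTable(con, tableName)
        } else {
            utils::read.csv(source, colClasses = "character",
                            na.strings = c("", "NA"), check.names = FALSE,
                            fileEncoding = "UTF-8")
        }
    } else stop("'source' must be a file path or a DBI connection",
                call. = FALSE)

    df <- canonicalizeMissing(df)
    for (j in names(df)) if (!is.character(df[[j]]) && !is.numeric(df[[j]]) &&
                             !inherits(df[[j]], "Date"))
        df[[j]] <- as.character(df[[j]])

    if (is.null(dateCols)) {
        isoLike <- function(v) {
            if (!is.character(v)) return(FALSE)
            v <- v[!is.na(v)]
            length(v) > 0L && all(grepl("^\\d{4}-\\d{2}-\\d{2}$", v))
        }
        dateCols <- names(df)[vapply(df, isoLike, logical(1))]
    } else {
        missing <- setdiff(dateCols, names(df))
        if (length(missing))
            stop(sprintf("dateCols not present: %s",
                         paste(missing, collapse = ", ")), call. = FALSE)
    }
    for (col in dateCols)
        df[[col]] <- parseDates(df[[col]], format = dateFormat,
                                what = sprintf("'%s'", col))

    protect <- union(c(idCol, keepCharacter), dateCols)
    numericLike <- function(v) {
        if (!is.character(v)) return(FALSE)
        v <- v[!is.na(v)]
        length(v) > 0L &&
            !any(grepl("^0\\d", v)) &&  # leading zeros stay strings
            !anyNA(suppressWarnings(as.numeric(v)))
    }
    for (col in setdiff(names(df), protect))
        if (numericLike(df[[col]]))
            df[[col]] <- as.numeric(df[[col]])
    df
}

openSqlite <- function(path) {
    if (!requireNamespace("DBI", quietly = TRUE) ||
        !requireNamespace("RSQLite", quietly = TRUE))
        stop("reading SQL sources needs the DBI and RSQLite packages",
             call. = FALSE)
    DBI::dbConnect(RSQLite::SQLite(), path)
}

readSqlTable <- function(con, tableName) {
    if (is.null(tableName))
        stop("'tableName' is required when reading from a database",
             call. = FALSE)
    if (!requireNamespace("DBI", quietly = TRUE))
        stop("reading SQL sources needs the DBI package", call. = FALSE)
    if (!tableName %in% DBI::dbListTables(con))
        stop(sprintf("table '%s' not found in database (available: %s)",
                     tableName,
                     paste(DBI::dbListTables(con), collapse = ", ")),
             call. = FALSE)
    DBI::dbReadTable(con, tableName)
}
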