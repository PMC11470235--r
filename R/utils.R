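## Internal helpers shared across modules.

## Strict day-granular date coercion.  Accepts Date (passed through) or
## character in the given format (ISO-8601 by default).  Never guesses at
## ambiguous dialects: a cell that does not parse is an error listing the
## offending row indices.
parseDates <- function(x, format = "%Y-%m-%d", what = "date") {
    if (inherits(x, "Date")) return(x)
    if (inherits(x, "POSIXt")) return(as.Date(x))
    if (is.numeric(x) && all(is.na(x)))
        return(as.Date(rep(NA_character_, length(x))))
    x <- as.character(x)
    x[!is.na(x) & trimws(x) == ""] <- NA_character_
    out <- as.Date(x, format = format)
    ## reject partial matches (e.g. "2021-1-1" parses but "2021-13-40" not;
    ## round-trip check catches dialect mismatches such as "07/03/2021")
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
        stop(sprintf(
            "unparseable %s value(s) (expected format %s) at row(s) %s: %s",
            what, format,
            paste(utils::head(bad, 5L), collapse = ", "),
            paste(utils::head(x[bad], 5L), collapse = ", ")),
            call. = FALSE)
    out
}

## Canonical missing marker: "", "NA" and whitespace-only strings in
## character columns become NA; factors are flattened to character so role
## registries and serialization see one representation.
canonicalizeMissing <- function(df) {
    for (j in seq_along(df)) {
        if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
        if (is.character(df[[j]])) {
            v <- df[[j]]
            v[!is.na(v) & trimws(v) %in% c("", "NA")] <- NA_character_
            df[[j]] <- v
        }
    }
    df
}

## Exact-equality evidence matching after normalization (trim + case-fold);
## regex = TRUE switches to pattern matching instead.
matchesEvidence <- function(values, patterns, regex = FALSE) {
    v <- as.character(values)
    if (regex) {
        hit <- rep(FALSE, length(v))
        ok <- !is.na(v)
        for (p in patterns)
            hit[ok] <- hit[ok] | grepl(p, v[ok])
        return(hit)
    }
    norm <- function(s) tolower(trimws(s))
    !is.na(v) & norm(v) %in% norm(as.character(patterns))
}

keyString <- function(ids, dates) paste(ids, format(dates), sep = "\r")

## Ordered merging of sorted evidence days into maximal clusters whose
## consecutive members are <= maxGap days apart.  Returns a list of integer
## index vectors into `days` (which must be sorted, unique).
clusterDays <- function(days, maxGap) {
    n <- length(days)
    if (n == 0L) return(list())
    gaps <- as.integer(diff(days))
    grp <- cumsum(c(0L, as.integer(gaps > maxGap)))
    unname(split(seq_len(n), grp))
}

## Stop unless the chronogram has all of `cols`.
needCols <- function(cg, cols, what = "column") {
    missing <- setdiff(cols, names(cg@data))
    if (length(missing))
        stop(sprintf("%s(s) not present in chronogram: %s", what,
                     paste(missing, collapse = ", ")), call. = FALSE)
    invisible(TRUE)
}

## Require an annotation step to have been run already (their order of
## execution matters: counts build on episode finding, exposures on counts).
needAnnotation <- function(cg, col, step) {
    if (!col %in% cg@annotationCols)
        stop(sprintf(
            "column '%s' not found: run %s() first (annotations build on each other)",
            col, step), call. = FALSE)
    invisible(TRUE)
}
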