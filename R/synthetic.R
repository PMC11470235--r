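#' Design parameters for the synthetic vaccine-cohort generator
#'
#' Describes a two-dose SARS-CoV-2-style vaccine study of the kind used to
#' compare long (10-12 week) against short (3-4 week) dose intervals, with
#' and without prior infection: per-group fractions, first-dose months,
#' dose-interval ranges, a three-visit venepuncture schedule, a log-normal
#' anti-Spike titer model, and a mid-study infection rate.  The defaults
#' are the study conditions every bundled test and example runs under; see
#' the methods vignette for the reasoning behind each value.
#'
#' @param nParticipants cohort size.
#' @param groupFractions named fractions (summing to 1) over the four
#'   strata \code{long_N}, \code{long_Y}, \code{short_N}, \code{short_Y}
#'   (interval group x prior infection).
#' @param dose1Months \code{"YYYY-MM"} months first doses are drawn from.
#' @param doseIntervalLong,doseIntervalShort inclusive day ranges between
#'   doses 1 and 2 (defaults 70-84 and 21-28 days, i.e. 10-12 and 3-4
#'   weeks).
#' @param baselineJitter inclusive day range of the baseline venepuncture
#'   before dose 1.
#' @param peakVisitOffset,lateVisitOffset inclusive day ranges after dose 2
#'   for the second and third venepunctures (default 28-35 and 56-63 days,
#'   so the second visit always falls in the canonical post-dose-2 peak
#'   window).
#' @param baselineGM named geometric means (arbitrary BAU/mL-like units) of
#'   the baseline anti-S titer by prior-infection status (\code{N}/\code{Y}).
#' @param peakGM named geometric means of the post-dose-2 peak titer per
#'   stratum.  The default embeds a 2-fold long-over-short effect in the
#'   uninfected stratum and a deliberately null effect (equal means) in the
#'   prior-infected stratum.
#' @param lateDecay multiplicative decay of the peak by the third visit.
#' @param sdLog log-scale (natural log) noise SD of every titer draw.
#' @param infectionRate fraction of participants infected mid-study.
#' @param secondInfectionRate fraction of those with a second, well
#'   separated infection.
#' @param seroLagDays days from infection to anti-N positivity.
#' @param variantCutoff calendar date splitting the two circulating-variant
#'   labels assigned to sequenced infections.
#' @param variantLabels length-2 lineage labels (pre/post cutoff).
#' @return a validated list of class \code{CohortDesign}.
#' @seealso \code{\link{generateCohort}}
#' @export
cohortDesign <- function(nParticipants = 200,
                         groupFractions = c(long_N = 0.35, long_Y = 0.15,
                                            short_N = 0.35, short_Y = 0.15),
                         dose1Months = c("2020-12", "2021-01", "2021-02"),
                         doseIntervalLong = c(70, 84),
                         doseIntervalShort = c(21, 28),
                         baselineJitter = c(3, 10),
                         peakVisitOffset = c(28, 35),
                         lateVisitOffset = c(56, 63),
                         baselineGM = c(N = 5, Y = 50),
                         peakGM = c(long_N = 2000, short_N = 1000,
                                    long_Y = 5000, short_Y = 5000),
                         lateDecay = 0.6,
                         sdLog = 0.5,
                         infectionRate = 0.15,
                         secondInfectionRate = 0.2,
                         seroLagDays = 14,
                         variantCutoff = "2021-05-15",
                         variantLabels = c("Alpha", "Delta")) {
    design <- list(nParticipants = as.integer(nParticipants),
                   groupFractions = groupFractions,
                   dose1Months = dose1Months,
                   doseIntervalLong = doseIntervalLong,
                   doseIntervalShort = doseIntervalShort,
                   baselineJitter = baselineJitter,
                   peakVisitOffset = peakVisitOffset,
                   lateVisitOffset = lateVisitOffset,
                   baselineGM = baselineGM, peakGM = peakGM,
                   lateDecay = lateDecay, sdLog = sdLog,
                   infectionRate = infectionRate,
                   secondInfectionRate = secondInfectionRate,
                   seroLagDays = as.integer(seroLagDays),
                   variantCutoff = as.Date(variantCutoff),
                   variantLabels = variantLabels)
    strata <- c("long_N", "long_Y", "short_N", "short_Y")
    if (design$nParticipants < 1L)
        stop("'nParticipants' must be positive", call. = FALSE)
    if (!setequal(names(design$groupFractions), strata))
        stop(sprintf("'groupFractions' must be named %s",
                     paste(strata, collapse = ", ")), call. = FALSE)
    if (abs(sum(design$groupFractions) - 1) > 1e-8)
        stop("'groupFractions' must sum to 1", call. = FALSE)
    for (f in c("doseIntervalLong", "doseIntervalShort", "baselineJitter",
                "peakVisitOffset", "lateVisitOffset"))
        if (length(design[[f]]) != 2L || any(design[[f]] < 0) ||
            design[[f]][1L] > design[[f]][2L])
            stop(sprintf("'%s' must be an increasing pair of non-negative days",
                         f), call. = FALSE)
    if (any(design$doseIntervalLong <= 0) || any(design$doseIntervalShort <= 0))
        stop("dose intervals must be positive", call. = FALSE)
    if (!setequal(names(design$peakGM), strata))
        stop("'peakGM' must be named by stratum", call. = FALSE)
    if (!setequal(names(design$baselineGM), c("N", "Y")))
        stop("'baselineGM' must be named N, Y", call. = FALSE)
    if (design$infectionRate < 0 || design$infectionRate > 1 ||
        design$secondInfectionRate < 0 || design$secondInfectionRate > 1)
        stop("infection rates must lie in [0, 1]", call. = FALSE)
    if (length(design$variantLabels) != 2L)
        stop("'variantLabels' must have length 2", call. = FALSE)
    class(design) <- "CohortDesign"
    design
}

## Run expr under a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

sampleRange <- function(n, range) {
    if (range[1L] == range[2L]) rep(as.integer(range[1L]), n)
    else sample(seq(as.integer(range[1L]), as.integer(range[2L])), n,
                replace = TRUE)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Emits REDCap/LIMS-shaped input tables — per-participant metadata plus
#' sparse serology, swab and symptom-diary experiment tables — for a
#' two-dose-interval vaccine study, together with a per-participant truth
#' record, so the whole assemble/annotate/sub-cohort pipeline can be tested
#' end to end with no external data.  Deterministic given \code{seed}.
#'
#' What the tables encode, by construction:
#' \itemize{
#'   \item first-dose dates are drawn as a study month plus a uniform
#'     day-of-month 1..28 (via \code{\link{perturbDates}}), and the second
#'     dose follows at the stored group-specific interval;
#'   \item anti-S titers follow the design's log-normal model, with the
#'     long-interval peak exceeding the short-interval peak in the
#'     uninfected stratum and no embedded effect in the prior-infected
#'     stratum;
#'   \item prior-infected participants are anti-N positive from their
#'     baseline visit; mid-study infected participants seroconvert
#'     \code{seroLagDays} after infection, so those with straddling visits
#'     show a negative-to-positive anti-N transition;
#'   \item each infection emits swab and symptom evidence rows 0-3 days
#'     apart, so \code{\link{episodesFind}} must merge them into one
#'     episode; second infections are >= 60 days later, forcing a split.
#' }
#'
#' @param design a \code{\link{cohortDesign}}.
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @return a list with elements \code{start}, \code{end} (suggested study
#'   span), \code{metadata}, \code{experiments} (named list:
#'   \code{serology}, \code{swab}, \code{symptom}), \code{truth} (one row
#'   per participant: group labels, dose dates, number and dates of true
#'   infections, variant labels, true seroconversion visit index, expected
#'   end-of-study antigenic history), and \code{design}.
#' @examples
#' coh <- generateCohort(cohortDesign(nParticipants = 20), seed = 1)
#' head(coh$truth)
#' @export
generateCohort <- function(design = cohortDesign(), seed = 1) {
    stopifnot(inherits(design, "CohortDesign"))
    withSeed(seed, {
        n <- design$nParticipants
        ids <- sprintf("%03d", seq_len(n))  # leading zeros on purpose
        stratum <- sample(names(design$groupFractions), n, replace = TRUE,
                          prob = design$groupFractions)
        interval_group <- sub("_[NY]$", "", stratum)
        prior_infection <- sub("^.*_", "", stratum)

        meta <- data.frame(
            participant_id = ids,
            interval_group = interval_group,
            prior_infection = prior_infection,
            dose1_month = sample(design$dose1Months, n, replace = TRUE),
            dose_interval_days = ifelse(
                interval_group == "long",
                sampleRange(n, design$doseIntervalLong),
                sampleRange(n, design$doseIntervalShort)),
            stringsAsFactors = FALSE)
        meta <- perturbDates(meta, monthCol = "dose1_month",
                             intervals = c(dose_2_date = "dose_interval_days"),
                             dateCol = "dose_1_date", seed = NULL)

        start <- min(meta$dose_1_date) - 14L
        end <- max(meta$dose_2_date) + 70L

        ## venepuncture schedule
        v1 <- meta$dose_1_date - sampleRange(n, design$baselineJitter)
        v2 <- meta$dose_2_date + sampleRange(n, design$peakVisitOffset)
        v3 <- meta$dose_2_date + sampleRange(n, design$lateVisitOffset)
        visits <- cbind(v1, v2, v3)

        ## true infections
        infected <- sort(sample(seq_len(n),
                                round(design$infectionRate * n)))
        inf1 <- as.Date(rep(NA_character_, n))
        inf2 <- as.Date(rep(NA_character_, n))
        ## uniform integer day in [lo, hi] (safe for lo == hi, where
        ## sample() would otherwise sample from 1..lo)
        drawDay <- function(lo, hi)
            as.Date(lo + sample.int(hi - lo + 1L, 1L) - 1L,
                    origin = "1970-01-01")
        for (i in infected) {
            inf1[i] <- drawDay(as.integer(meta$dose_1_date[i]) + 10L,
                               as.integer(end) - 10L)
        }
        again <- infected[stats::runif(length(infected)) <
                              design$secondInfectionRate]
        for (i in again) {
            lo <- as.integer(inf1[i]) + 60L
            hi <- as.integer(end) - 10L
            if (lo <= hi) inf2[i] <- drawDay(lo, hi)
        }
        variantOf <- function(d)
            ifelse(d < design$variantCutoff, design$variantLabels[1L],
                   design$variantLabels[2L])

        ## serology: anti-S titer + anti-N status at each visit
        serRows <- list()
        for (i in seq_len(n)) {
            gm <- c(design$baselineGM[[prior_infection[i]]],
                    design$peakGM[[stratum[i]]],
                    design$peakGM[[stratum[i]]] * design$lateDecay)
            titer <- round(exp(stats::rnorm(3L, log(gm), design$sdLog)), 1L)
            seroPosFrom <- if (prior_infection[i] == "Y") start
                else if (!is.na(inf1[i])) inf1[i] + design$seroLagDays
                else NA
            antiN <- if (is.na(seroPosFrom)) rep("negative", 3L)
                else ifelse(visits[i, ] >= seroPosFrom, "positive", "negative")
            serRows[[i]] <- data.frame(
                participant_id = ids[i],
                date = as.Date(visits[i, ], origin = "1970-01-01"),
                anti_S = titer, anti_N = antiN,
                stringsAsFactors = FALSE)
        }
        serology <- do.call(rbind, serRows)

        ## swab + symptom evidence around each true infection
        swabRows <- list(); sympRows <- list()
        addEvidence <- function(id, t) {
            d1 <- sample(1:3, 1L)  # confirmatory swab a few days later
            d2 <- sample(1:3, 1L)  # a further symptomatic day
            swabRows[[length(swabRows) + 1L]] <<- data.frame(
                participant_id = id,
                date = c(t, t + d1),
                pcr_result = c("positive", "positive"),
                lineage = c(NA_character_, variantOf(t)),
                stringsAsFactors = FALSE)
            sympRows[[length(sympRows) + 1L]] <<- data.frame(
                participant_id = id,
                date = c(t, t + d2),
                symptom = c("Y", "Y"),
                stringsAsFactors = FALSE)
        }
        for (i in infected) {
            addEvidence(ids[i], inf1[i])
            if (!is.na(inf2[i])) addEvidence(ids[i], inf2[i])
        }
        ## sprinkle negative swabs / symptom-free diary days on a few
        ## uninfected participants so matching has chaff to ignore
        clean <- setdiff(seq_len(n), infected)
        chaff <- clean[seq_len(min(5L, length(clean)))]
        for (i in chaff) {
            t <- meta$dose_1_date[i] + 5L
            swabRows[[length(swabRows) + 1L]] <- data.frame(
                participant_id = ids[i], date = t,
                pcr_result = "negative", lineage = NA_character_,
                stringsAsFactors = FALSE)
            sympRows[[length(sympRows) + 1L]] <- data.frame(
                participant_id = ids[i], date = t, symptom = "N",
                stringsAsFactors = FALSE)
        }
        swab <- if (length(swabRows)) do.call(rbind, swabRows)
            else data.frame(participant_id = character(),
                            date = as.Date(character()),
                            pcr_result = character(),
                            lineage = character(), stringsAsFactors = FALSE)
        symptom <- if (length(sympRows)) do.call(rbind, sympRows)
            else data.frame(participant_id = character(),
                            date = as.Date(character()),
                            symptom = character(), stringsAsFactors = FALSE)

        ## ground truth, including the expected end-of-study history under
        ## the package's encoding (vaccine-first on same-day ties)
        nInf <- (!is.na(inf1)) + (!is.na(inf2))
        seroVisit <- rep(NA_integer_, n)
        for (i in infected) {
            if (prior_infection[i] == "Y") next
            posAt <- which(visits[i, ] >= inf1[i] + design$seroLagDays)
            negBefore <- any(visits[i, ] < inf1[i])
            if (length(posAt) && negBefore) seroVisit[i] <- min(posAt)
        }
        expected <- vapply(seq_len(n), function(i) {
            ev <- data.frame(date = c(meta$dose_1_date[i],
                                      meta$dose_2_date[i]),
                             code = c("V1", "V2"), rank = 0L)
            infs <- sort(c(inf1[i], inf2[i]))
            if (length(infs))
                ev <- rbind(ev, data.frame(
                    date = infs,
                    code = sprintf("I%d[%s]", seq_along(infs),
                                   variantOf(infs)),
                    rank = 1L))
            ev <- ev[order(ev$date, ev$rank), ]
            paste(ev$code, collapse = ":")
        }, character(1))
        truth <- data.frame(
            participant_id = ids,
            interval_group = interval_group,
            prior_infection = prior_infection,
            dose_1_date = meta$dose_1_date,
            dose_2_date = meta$dose_2_date,
            n_infections = as.integer(nInf),
            infection_1_date = inf1,
            infection_2_date = inf2,
            variant_1 = ifelse(is.na(inf1), NA_character_, variantOf(inf1)),
            variant_2 = ifelse(is.na(inf2), NA_character_, variantOf(inf2)),
            sero_visit = seroVisit,
            expected_history = expected,
            stringsAsFactors = FALSE)

        list(start = start, end = end, metadata = meta,
             experiments = list(serology = serology, swab = swab,
                                symptom = symptom),
             truth = truth, design = design)
    })
}

#' Perturb month-resolution first-dose dates to fictional days
#'
#' Public cohort releases often redact dates to month resolution
#' (\code{"YYYY-MM"}) while reporting between-dose intervals in days.  This
#' reconstructs analyzable (fictional) calendar dates: the first-dose
#' day-of-month is drawn uniformly from 1..28 per participant (never 29-31,
#' so every month is valid), and each downstream date is recomputed as the
#' fictional first-dose date plus its stored interval, preserving every
#' interval exactly.
#'
#' @param metadata a data.frame with a \code{"YYYY-MM"} month column and
#'   integer day-interval column(s).
#' @param monthCol name of the month column.
#' @param intervals named character vector: \code{c(new_date_col =
#'   "interval_col", ...)} — each entry adds a date column at first dose +
#'   interval.
#' @param dateCol name for the reconstructed first-dose date column.
#' @param seed optional seed (caller's RNG state restored); \code{NULL}
#'   draws from the current RNG stream.
#' @return \code{metadata} with the reconstructed date column(s) appended.
#' @examples
#' meta <- data.frame(participant_id = "P1", dose1_month = "2021-01",
#'                    dose_interval_days = 77L)
#' perturbDates(meta, seed = 1)
#' @export
perturbDates <- function(metadata,
                         monthCol = "dose1_month",
                         intervals = c(dose_2_date = "dose_interval_days"),
                         dateCol = "dose_1_date", seed = NULL) {
    if (!monthCol %in% names(metadata))
        stop(sprintf("month column '%s' not found", monthCol), call. = FALSE)
    missing <- setdiff(unname(intervals), names(metadata))
    if (length(missing))
        stop(sprintf("interval column(s) not found: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    months <- as.character(metadata[[monthCol]])
    if (!all(grepl("^\\d{4}-\\d{2}$", months)))
        stop(sprintf("column '%s' must hold 'YYYY-MM' months", monthCol),
             call. = FALSE)
    withSeed(seed, {
        day <- sample(1:28, nrow(metadata), replace = TRUE)
        metadata[[dateCol]] <- as.Date(sprintf("%s-%02d", months, day))
        for (j in seq_along(intervals))
            metadata[[names(intervals)[j]]] <-
                metadata[[dateCol]] + as.integer(metadata[[intervals[[j]]]])
        metadata
    })
}

#' Write a synthetic cohort as a SQLite database and CSV files
#'
#' Materializes the tables of \code{\link{generateCohort}} the way a study
#' would export them: one CSV per table and, when the DBI/RSQLite packages
#' are available, a single SQLite file with the same tables (dates stored
#' as ISO-8601 text), so the SQL ingestion path of
#' \code{\link{readCohortTable}} can be exercised without a database
#' server.
#'
#' @param cohort a \code{\link{generateCohort}} result.
#' @param dir output directory (created if needed).
#' @param sqlite also write \code{cohort.sqlite}.
#' @return invisibly, the paths written.
#' @export
writeCohortTables <- function(cohort, dir, sqlite = TRUE) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tabs <- c(list(metadata = cohort$metadata), cohort$experiments)
    asText <- function(df) {
        for (j in names(df)) if (inherits(df[[j]], "Date"))
            df[[j]] <- format(df[[j]], "%Y-%m-%d")
        df
    }
    paths <- character()
    for (nm in names(tabs)) {
        f <- file.path(dir, paste0(nm, ".csv"))
        utils::write.csv(asText(tabs[[nm]]), f, row.names = FALSE, na = "")
        paths <- c(paths, f)
    }
    if (sqlite) {
        if (!requireNamespace("DBI", quietly = TRUE) ||
            !requireNamespace("RSQLite", quietly = TRUE))
            stop("writing SQLite needs the DBI and RSQLite packages",
                 call. = FALSE)
        db <- file.path(dir, "cohort.sqlite")
        con <- DBI::dbConnect(RSQLite::SQLite(), db)
        on.exit(DBI::dbDisconnect(con))
        for (nm in names(tabs))
            DBI::dbWriteTable(con, nm, asText(tabs[[nm]]), overwrite = TRUE)
        paths <- c(paths, db)
    }
    invisible(paths)
}
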