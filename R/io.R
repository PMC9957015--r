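## Delimited-text IO for residue time-course tables. Comma-delimited UTF-8
## with a header row; metadata (units, seed) carried in '#' comment lines so
## a table is self-describing and re-runnable.

.TC_COLUMNS <- c("pesticide", "matrix", "temperature_C", "rh_pct",
                 "replicate", "day", "concentration_mg_kg", "censored")

#' Tidy table of a list of time courses
#'
#' @param tcs list of [ResidueTimeCourse-class].
#' @return `data.frame` with columns `pesticide`, `matrix`,
#'   `temperature_C`, `rh_pct`, `replicate`, `day`, `concentration_mg_kg`,
#'   `censored` (one row per observation).
#' @export
timecourseTable <- function(tcs) {
    rows <- lapply(tcs, function(tc) {
        data.frame(pesticide = tc@pesticide, matrix = tc@foodMatrix,
                   temperature_C = tc@temperatureC, rh_pct = tc@rhPct,
                   replicate = tc@replicate, day = tc@data$day,
                   concentration_mg_kg = tc@data$concentration,
                   censored = tc@data$censored, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write residue time courses to a delimited file
#'
#' @param tcs list of [ResidueTimeCourse-class] or a tidy `data.frame` as
#'   returned by [timecourseTable()].
#' @param path output path (CSV).
#' @param seed optional integer recorded in the file header so a simulated
#'   table documents its noise stream.
#' @return `path`, invisibly.
#' @export
writeTimecourses <- function(tcs, path, seed = NULL) {
    tab <- if (is.data.frame(tcs)) tcs else timecourseTable(tcs)
    miss <- setdiff(.TC_COLUMNS, names(tab))
    if (length(miss))
        stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c("# residue time courses; concentration in mg/kg, day in days,",
                 "# temperature_C in deg C, rh_pct in percentage points",
                 if (!is.null(seed)) sprintf("# seed=%d", as.integer(seed))),
               con)
    utils::write.csv(tab[, .TC_COLUMNS], con, row.names = FALSE)
    invisible(path)
}

#' Read residue time courses from a delimited file
#'
#' Parses and validates a tidy time-course table (comma-delimited, header
#' row, '#' comments ignored) and groups it into one
#' [ResidueTimeCourse-class] per pesticide x matrix x condition x replicate.
#'
#' @param path input path.
#' @return named list of [ResidueTimeCourse-class].
#' @export
readTimecourses <- function(path) {
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
    miss <- setdiff(.TC_COLUMNS, names(tab))
    if (length(miss))
        stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
    key <- interaction(tab$pesticide, tab$matrix, tab$temperature_C,
                       tab$rh_pct, tab$replicate, drop = TRUE, sep = ".")
    groups <- split(tab, key)
    out <- lapply(names(groups), function(k) {
        g <- groups[[k]]
        if (nrow(g) > 1L && any(diff(g$day) <= 0))
            stop("validation error: days not strictly increasing in group ", k)
        new("ResidueTimeCourse",
            pesticide = g$pesticide[1], foodMatrix = g$matrix[1],
            temperatureC = g$temperature_C[1], rhPct = g$rh_pct[1],
            replicate = as.integer(g$replicate[1]),
            data = data.frame(day = g$day,
                              concentration = g$concentration_mg_kg,
                              censored = as.logical(g$censored)))
    })
    names(out) <- names(groups)
    out
}
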