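# Reading and writing population projections in the Eurostat
# bulk-download TSV dialect, plus plain CSV matrix IO.
#
# Dialect: column 1 is a comma-joined dimension header such as
# "unit,age,geo\time"; remaining columns are calendar years; cells may
# carry trailing flags ("p", "e", "b", ":" for missing). Ages are coded
# Y0..Y99 with an open-ended top group (Y_GE100 / Y_OPEN), which is
# folded into the closed top age 100.

parse_eurostat_age <- function(code) {
  code <- trimws(code)
  if (grepl("^Y_GE[0-9]+$", code) || code == "Y_OPEN") return(100L)
  if (grepl("^Y[0-9]+$", code)) return(as.integer(sub("^Y", "", code)))
  if (code == "Y_LT1") return(0L)
  NA_integer_
}

#' Read a population projection from a Eurostat bulk TSV extract
#'
#' Parses the bulk-download dialect (comma-joined dimension header in the
#' first column, one column per year, observation flags appended to
#' numbers), folds the open-ended top age group into age 100, and returns
#' a `population_projection` restricted to the requested years. Cohort
#' deaths are derived by cohort differencing under the closed-population
#' assumption (the survivors of the two oldest ages are pooled at the
#' top age, where a common mortality rate is assumed when splitting).
#'
#' @param path Path to the TSV file.
#' @param years Calendar years required, default 2015:2080; any requested
#'   year absent from the file is an error naming the gap. `NULL` uses
#'   the years present in the file.
#' @param ages Ages required (after folding); `NULL` uses the ages present.
#' @return A `population_projection`.
#' @export
read_eurostat_tsv <- function(path, years = 2015:2080, ages = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("TSV file has no data rows", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  dims <- strsplit(sub("\\\\.*$", "", header[1L]), ",", fixed = TRUE)[[1L]]
  age_dim <- which(tolower(dims) == "age")
  if (!length(age_dim))
    stop("no 'age' dimension in the TSV header: ", header[1L], call. = FALSE)
  file_years <- as.integer(trimws(header[-1L]))
  if (any(is.na(file_years)))
    stop("malformed year columns in header: ",
         paste(header[-1L][is.na(file_years)], collapse = ", "), call. = FALSE)

  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  vals <- matrix(NA_real_, length(rows), length(file_years))
  row_age <- integer(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    key <- strsplit(r[1L], ",", fixed = TRUE)[[1L]]
    row_age[i] <- parse_eurostat_age(key[age_dim])
    cells <- trimws(r[-1L])
    for (j in seq_along(cells)) {
      cell <- sub("[ ]*[a-z:]+$", "", cells[j])   # strip flags like "p", "e"
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v) && nzchar(cell))
        stop(sprintf("malformed numeric cell '%s' at data row %d, year %d",
                     cells[j], i, file_years[j]), call. = FALSE)
      vals[i, j] <- v
    }
  }
  keep <- !is.na(row_age)
  vals <- vals[keep, , drop = FALSE]
  row_age <- row_age[keep]
  if (!length(row_age)) stop("no parseable age rows in the TSV", call. = FALSE)

  # fold duplicate ages (e.g. Y_GE100 folded onto 100, TOTAL rows dropped)
  uages <- sort(unique(row_age))
  counts_all <- matrix(0, length(uages), length(file_years),
                       dimnames = list(uages, file_years))
  for (i in seq_along(row_age))
    counts_all[as.character(row_age[i]), ] <-
      counts_all[as.character(row_age[i]), ] + vals[i, ]

  if (is.null(years)) years <- file_years
  years <- as.integer(years)
  missing_years <- setdiff(years, file_years)
  if (length(missing_years))
    stop("TSV is missing required year(s): ",
         paste(sort(missing_years), collapse = ", "), call. = FALSE)
  if (is.null(ages)) ages <- uages
  ages <- as.integer(ages)
  missing_ages <- setdiff(ages, uages)
  if (length(missing_ages))
    stop("TSV is missing required age(s): ",
         paste(sort(missing_ages), collapse = ", "), call. = FALSE)
  if (any(diff(ages) != 1L) || any(diff(years) != 1L))
    stop("requested ages and years must be consecutive", call. = FALSE)

  counts <- counts_all[as.character(ages), as.character(years), drop = FALSE]
  if (anyNA(counts)) stop("missing (':') cells inside the requested range", call. = FALSE)
  projection_from_counts(counts, ages, years)
}

# Build a population_projection from a counts matrix, deriving cohort
# deaths by differencing (closed population). The two oldest ages feed a
# pooled top-age cohort; a shared mortality rate splits their deaths.
projection_from_counts <- function(counts, ages, years) {
  na <- length(ages); nt <- length(years)
  deaths <- matrix(0, na, nt, dimnames = dimnames(counts))
  for (t in seq_len(nt - 1L)) {
    if (na > 2L) {
      d <- counts[1:(na - 2L), t] - counts[2:(na - 1L), t + 1L]
      deaths[1:(na - 2L), t] <- pmax(d, 0)
    }
    pool <- counts[na - 1L, t] + counts[na, t]
    rate <- if (pool > 0) max(0, min(1, 1 - counts[na, t + 1L] / pool)) else 0
    deaths[na - 1L, t] <- counts[na - 1L, t] * rate
    deaths[na, t] <- counts[na, t] * rate
  }
  if (nt > 1L) deaths[, nt] <- deaths[, nt - 1L] / pmax(counts[, nt - 1L], 1) * counts[, nt]
  cfg <- projection_config(total_base = max(sum(counts[, 1L]), 1),
                           ages = ages, years = years)
  structure(list(counts = counts, cohort_deaths = deaths,
                 net_migration = matrix(0, na, max(nt - 1L, 1L)),
                 ages = ages, years = years, config = cfg),
            class = "population_projection")
}

#' Write a projection's counts in the Eurostat bulk TSV dialect
#'
#' Inverse of [read_eurostat_tsv()] for round-tripping: full-precision
#' counts, ages coded `Y<age>`, no observation flags.
#'
#' @param p A `population_projection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eurostat_tsv <- function(p, path) {
  stopifnot(inherits(p, "population_projection"))
  header <- paste(c("unit,age,geo\\time", p$years), collapse = "\t")
  body <- vapply(seq_along(p$ages), function(i) {
    paste(c(sprintf("NR,Y%d,EU28", p$ages[i]),
            formatC(p$counts[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read an age-by-year matrix as CSV
#'
#' Plain matrix interchange (age rows, year columns) used for
#' projections, mortality tables and incidence schedules.
#'
#' @param m Numeric matrix with age rownames and year colnames.
#' @param path File path.
#' @return `write_age_year_csv`: `path` invisibly; `read_age_year_csv`:
#'   the matrix.
#' @export
write_age_year_csv <- function(m, path) {
  df <- data.frame(age = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_age_year_csv
#' @export
read_age_year_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
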