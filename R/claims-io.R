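#' @importFrom rlang .data
#' @importFrom Matrix sparseMatrix colSums rowSums t crossprod
NULL

ICD3_PATTERN <- "^[A-Za-z][0-9]{2}$"

#' Define the study timeline
#'
#' The analysis window is split into four consecutive periods: a
#' *no-admission period* `[t0, t1)` used to select patients without recent
#' hospital contact, a *feature period* `[t1, t2)` from which predictor
#' diagnoses are taken, a *target period* `[t2, t3)` whose (accumulated)
#' diagnoses are predicted, and a *follow-up period* `[t3, t4)` used for
#' mortality comparison.
#'
#' @param t0,t1,t2,t3,t4 Calendar dates (anything coercible with
#'   [as.Date()]), strictly increasing.
#' @return An object of class `study_periods`: a named list of the five
#'   boundary dates.
#' @examples
#' default_study_periods()
#' @export
study_periods <- function(t0, t1, t2, t3, t4) {
  b <- as.Date(c(t0, t1, t2, t3, t4))
  if (anyNA(b)) stop("study period boundaries must be valid dates")
  if (any(diff(b) <= 0)) stop("study period boundaries must be strictly increasing")
  structure(list(t0 = b[1], t1 = b[2], t2 = b[3], t3 = b[4], t4 = b[5]),
            class = "study_periods")
}

#' @rdname study_periods
#' @details `default_study_periods()` returns the 6y / 3y / 3y / 6y split
#'   starting 1997-01-01 used throughout the package examples.
#' @export
default_study_periods <- function() {
  study_periods("1997-01-01", "2003-01-01", "2006-01-01", "2009-01-01", "2015-01-01")
}

#' @export
print.study_periods <- function(x, ...) {
  cat("Study periods:\n")
  cat("  no-admission: [", format(x$t0), ",", format(x$t1), ")\n")
  cat("  feature:      [", format(x$t1), ",", format(x$t2), ")\n")
  cat("  target:       [", format(x$t2), ",", format(x$t3), ")\n")
  cat("  follow-up:    [", format(x$t3), ",", format(x$t4), ")\n")
  invisible(x)
}

validate_stays <- function(stays, strict = FALSE) {
  bad_date <- is.na(stays$entry_date) | is.na(stays$exit_date)
  bad_order <- !bad_date & stays$exit_date < stays$entry_date
  bad_primary <- !grepl(ICD3_PATTERN, stays$primary_dx)
  bad_secondary <- !vapply(
    stays$secondary_dx,
    function(s) length(s) == 0 || all(grepl(ICD3_PATTERN, s)),
    logical(1)
  )
  bad <- bad_date | bad_order | bad_primary | bad_secondary
  if (any(bad)) {
    msg <- sprintf(
      "%d stay record(s) rejected (%d bad dates, %d exit before entry, %d bad primary code, %d bad secondary code)",
      sum(bad), sum(bad_date), sum(bad_order), sum(bad_primary), sum(bad_secondary)
    )
    if (strict) stop(msg)
    warning(msg)
  }
  stays[!bad, , drop = FALSE]
}

#' Read hospital-stay records
#'
#' Reads a stay CSV (one row per hospital stay) into a validated tibble.
#' The expected columns are `patient_id`, `entry_date`, `exit_date`
#' (ISO 8601), `primary_dx` (3-character ICD code, letter + two digits),
#' `secondary_dx` (separator-joined list, may be empty), `region`, `sex`,
#' `birth_year` and `death` (0/1 flag for in-hospital death on that stay).
#'
#' Rows violating the record invariants (unparseable dates, exit before
#' entry, malformed diagnosis codes) are dropped with a warning, or abort
#' the read when `strict = TRUE`.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict Abort on the first malformed row instead of dropping it?
#' @param sep_secondary Separator between secondary diagnosis codes
#'   (default `";"`).
#' @return A tibble with one row per stay; `secondary_dx` is a list-column
#'   of character vectors.
#' @seealso [write_stays()] for the inverse operation.
#' @export
read_stays <- function(path, strict = FALSE, sep_secondary = ";") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      entry_date = readr::col_character(),
      exit_date = readr::col_character(),
      primary_dx = readr::col_character(),
      secondary_dx = readr::col_character(),
      region = readr::col_character(),
      sex = readr::col_character(),
      birth_year = readr::col_integer(),
      death = readr::col_integer()
    ),
    progress = FALSE
  )
  expected <- c("patient_id", "entry_date", "exit_date", "primary_dx",
                "secondary_dx", "region", "sex", "birth_year", "death")
  if (!all(expected %in% names(raw))) {
    stop("stay CSV is missing columns: ",
         paste(setdiff(expected, names(raw)), collapse = ", "))
  }
  stays <- tibble::tibble(
    patient_id = raw$patient_id,
    entry_date = as.Date(raw$entry_date, format = "%Y-%m-%d"),
    exit_date = as.Date(raw$exit_date, format = "%Y-%m-%d"),
    primary_dx = raw$primary_dx,
    secondary_dx = lapply(raw$secondary_dx, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else strsplit(s, sep_secondary, fixed = TRUE)[[1]]
    }),
    region = raw$region,
    sex = raw$sex,
    birth_year = raw$birth_year,
    death = as.logical(raw$death)
  )
  validate_stays(stays, strict = strict)
}

#' Write hospital-stay records
#'
#' Writes a stay tibble (as returned by [read_stays()] or
#' [simulate_claims()]) back to the CSV dialect read by [read_stays()].
#'
#' @param stays Stay tibble.
#' @param path Output path.
#' @param sep_secondary Separator between secondary diagnosis codes.
#' @return `path`, invisibly.
#' @export
write_stays <- function(stays, path, sep_secondary = ";") {
  out <- tibble::tibble(
    patient_id = stays$patient_id,
    entry_date = format(stays$entry_date),
    exit_date = format(stays$exit_date),
    primary_dx = stays$primary_dx,
    secondary_dx = vapply(stays$secondary_dx, paste, character(1),
                          collapse = sep_secondary),
    region = stays$region,
    sex = stays$sex,
    birth_year = stays$birth_year,
    death = as.integer(stays$death)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Period index of each stay: 0 = before t0 / after t4, 1 = no-admission,
# 2 = feature, 3 = target, 4 = follow-up.  Attribution by exit (default) or
# entry date; the dataset convention is keyed on exit dates.
stay_period <- function(stays, periods, attribute = c("exit", "entry")) {
  attribute <- match.arg(attribute)
  d <- if (attribute == "exit") stays$exit_date else stays$entry_date
  findInterval(as.numeric(d),
               as.numeric(c(periods$t0, periods$t1, periods$t2, periods$t3, periods$t4)))
}

#' Select the study population
#'
#' A patient enters the study population iff they have (i) no stay in the
#' no-admission period, (ii) at least one stay in the feature period and
#' (iii) at least one stay in the target period. Each stay is attributed to
#' the period containing its exit date by default (claims data are keyed on
#' exit dates); set `attribute = "entry"` for the entry-date convention.
#'
#' @param stays Stay tibble.
#' @param periods A [study_periods()] object.
#' @param attribute Date used to attribute a stay to a period.
#' @return A sorted character vector of patient ids.
#' @export
select_study_population <- function(stays, periods, attribute = c("exit", "entry")) {
  per <- stay_period(stays, periods, attribute)
  df <- tibble::tibble(patient_id = stays$patient_id, period = per)
  flags <- df |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      none_before = !any(.data$period == 1L),
      has_feature = any(.data$period == 2L),
      has_target = any(.data$period == 3L),
      .groups = "drop"
    )
  sort(flags$patient_id[flags$none_before & flags$has_feature & flags$has_target])
}

# role-suffixed long table of (patient_id, code, period) for one stay set
stay_codes_long <- function(stays, periods, attribute = "exit") {
  per <- stay_period(stays, periods, attribute)
  n_sec <- lengths(stays$secondary_dx)
  sec <- unlist(stays$secondary_dx)
  if (is.null(sec)) sec <- character(0)
  tibble::tibble(
    patient_id = c(stays$patient_id, rep(stays$patient_id, n_sec)),
    code = c(paste0(stays$primary_dx, "p"), paste0(sec, "s")),
    period = c(per, rep(per, n_sec))
  )
}

#' Build binary diagnosis matrices
#'
#' Builds the feature-period indicator matrix `X0` and the accumulated
#' target matrix `Y` for a study population. `X0[p, d] = 1` iff patient `p`
#' received the role-suffixed code `d` (e.g. `"E66p"` primary, `"E66s"`
#' secondary) at least once during the feature period. `Y[p, d] = 1` iff
#' the code occurred at least once between the start of the feature period
#' and the end of the target period — the monotonicity assumption: once
#' diagnosed, a condition is treated as present ever after, so every `X0`
#' nonzero is also a `Y` nonzero.
#'
#' @inheritParams select_study_population
#' @param population Character vector of patient ids (typically from
#'   [select_study_population()]); patients without stays get all-zero rows.
#' @return A list with sparse logical-pattern matrices `X0` and `Y`
#'   (class `dgCMatrix`, patients x codes, dimnames set).
#' @export
build_matrices <- function(stays, population, periods, attribute = c("exit", "entry")) {
  attribute <- match.arg(attribute)
  long <- stay_codes_long(stays, periods, attribute)
  long <- long[long$patient_id %in% population, , drop = FALSE]
  feature <- long[long$period == 2L, c("patient_id", "code")]
  both <- long[long$period %in% c(2L, 3L), c("patient_id", "code")]
  population <- sort(unique(population))
  make <- function(df, codes) {
    codes <- sort(unique(codes))
    i <- match(df$patient_id, population)
    j <- match(df$code, codes)
    m <- Matrix::sparseMatrix(
      i = i, j = j, x = 1,
      dims = c(length(population), length(codes)),
      dimnames = list(population, codes)
    )
    m@x[] <- 1  # collapse duplicate triples to a binary indicator
    m
  }
  list(X0 = make(feature, feature$code), Y = make(both, both$code))
}

#' Export a sparse diagnosis matrix as coordinate triples
#'
#' Writes the nonzeros of a patient x code indicator matrix as TSV triples
#' `(patient_id, code, 1)`.
#'
#' @param m Sparse matrix from [build_matrices()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_triples <- function(m, path) {
  trip <- Matrix::summary(m)
  out <- tibble::tibble(
    patient_id = rownames(m)[trip$i],
    code = colnames(m)[trip$j],
    value = 1L
  )
  out <- dplyr::arrange(out, .data$patient_id, .data$code)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-patient demographics from stay records
#'
#' Extracts one row per patient with the demographic fields used for cohort
#' matching (sex, region, birth year), taken from the patient's first stay.
#'
#' @param stays Stay tibble.
#' @return A tibble with columns `patient_id`, `sex`, `region`, `birth_year`.
#' @export
patient_demographics <- function(stays) {
  stays |>
    dplyr::arrange(.data$patient_id, .data$entry_date) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::select("patient_id", "sex", "region", "birth_year")
}
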