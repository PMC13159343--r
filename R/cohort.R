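#' Validate and normalise a patient-level cohort table
#'
#' A cohort is a tibble with one row per patient and the columns
#' `id` (character), `margin_mm` (numeric mm, `NA` = undocumented),
#' `margin_category` (`"lt1"`, `"1to5"`, `"gt5"`, `"missing"`),
#' `rt` (logical radiotherapy exposure), `lr` (logical local recurrence,
#' `NA` = unknown), `grade` (`"G1"`, `"G2"`, `"G3"` or `NA`) and
#' `prior_external_surgery` (logical or `NA`).  `as_cohort()` checks the
#' schema, fills `margin_category` from `margin_mm` when absent, and errors
#' (naming the offending row) on inconsistencies such as a documented margin
#' that contradicts its category or a negative margin.
#'
#' @param x a data frame with at least `margin_mm`, `rt` and `lr` columns.
#' @return a validated cohort tibble.
#' @export
as_cohort <- function(x) {
  x <- as_tibble(x)
  names(x) <- tolower(names(x))
  required <- c("margin_mm", "rt", "lr")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"id" %in% names(x)) x$id <- sprintf("P%03d", seq_len(nrow(x)))
  x$id <- as.character(x$id)
  x$margin_mm <- as.numeric(x$margin_mm)
  x$rt <- parse_flag(x$rt, "rt")
  x$lr <- parse_flag(x$lr, "lr")
  if (!"grade" %in% names(x)) x$grade <- NA_character_
  x$grade <- as.character(x$grade)
  if (!"prior_external_surgery" %in% names(x)) {
    x$prior_external_surgery <- NA
  }
  x$prior_external_surgery <- parse_flag(x$prior_external_surgery,
                                         "prior_external_surgery")

  bad <- which(!is.na(x$margin_mm) & x$margin_mm < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative margin_mm at row %d", bad[1]))
  }
  bad <- which(!is.na(x$grade) & !x$grade %in% c("G1", "G2", "G3"))
  if (length(bad) > 0) {
    abort(sprintf("unknown grade token '%s' at row %d", x$grade[bad[1]], bad[1]))
  }
  derived <- margin_category_of(x$margin_mm)
  if (!"margin_category" %in% names(x) || all(is.na(x$margin_category))) {
    x$margin_category <- derived
  } else {
    x$margin_category <- as.character(x$margin_category)
    x$margin_category[is.na(x$margin_category)] <-
      derived[is.na(x$margin_category)]
    bad <- which(!x$margin_category %in% margin_levels)
    if (length(bad) > 0) {
      abort(sprintf("unknown margin_category token '%s' at row %d",
                    x$margin_category[bad[1]], bad[1]))
    }
    bad <- which(x$margin_category != derived)
    if (length(bad) > 0) {
      abort(sprintf(
        "margin_category '%s' inconsistent with margin_mm %s at row %d",
        x$margin_category[bad[1]], format(x$margin_mm[bad[1]]), bad[1]))
    }
  }
  select(x, "id", "margin_mm", "margin_category", "rt", "lr",
         "grade", "prior_external_surgery")
}

parse_flag <- function(v, what) {
  if (is.logical(v)) return(v)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "yes", "1")] <- TRUE
  out[s %in% c("false", "f", "no", "0")] <- FALSE
  bad <- which(!is.na(s) & s != "" & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("non-boolean value '%s' in column %s at row %d",
                  v[bad[1]], what, bad[1]))
  }
  out
}

#' Read a cohort from CSV
#'
#' The interchange schema has header columns `id`, `margin_mm`,
#' `margin_category`, `rt`, `lr`, `grade`, `prior_external_surgery`
#' (case-insensitive; extra columns are kept).  Empty cells are missing
#' values; flags are `true`/`false`.  The file is validated with
#' [as_cohort()], so inconsistent rows are rejected with their row number.
#'
#' @param path path to a CSV file.
#' @return a cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                         col_types = readr::cols(.default = readr::col_character()))
  as_cohort(raw)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: missing values are written as empty
#' cells, logical flags as `true`/`false`.
#'
#' @param cohort a cohort tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as_cohort(cohort)
  out$rt <- tolower(as.character(out$rt))
  out$lr <- tolower(as.character(out$lr))
  out$prior_external_surgery <- tolower(as.character(out$prior_external_surgery))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# Complete-case records: recurrence status documented.
complete_cases <- function(cohort) filter(cohort, !is.na(.data$lr))

# Records usable by the threshold scan: numeric margin and outcome both known.
scan_cases <- function(cohort) {
  filter(cohort, !is.na(.data$margin_mm), !is.na(.data$lr))
}
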