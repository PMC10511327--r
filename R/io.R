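#' Read a long-format child anthropometry measurement file
#'
#' Reads delimited text with one row per child-visit and returns a canonical
#' measurement table: sorted by cohort, child and age, with duplicate
#' same-age rows per child flagged (first parsed row kept for analysis) and
#' unparseable rows collected into a rejects report rather than crashing.
#'
#' Expected columns (after applying `col_map`): `cohort_id`, `child_id`,
#' `age_days`, and at least one of `wlz`, `laz`, `waz`; `sex` and `date`
#' (ISO-8601) are optional. Extra columns are ignored. Dates are required
#' only by seasonality operations, which refuse to run without them.
#'
#' @param path path to a delimited text file with a header.
#' @param col_map optional named character vector mapping canonical names to
#'   file column names, e.g. `c(child_id = "pid", wlz = "whz")`.
#' @param delim field delimiter (default comma).
#'
#' @return A tibble of class `we_measurements` with columns `cohort_id`,
#'   `child_id`, `sex`, `age_days`, `date`, `wlz`, `laz`, `waz`, `qc_flags`,
#'   carrying attributes `rejects` (tibble of rejected raw rows with a
#'   reason) and `n_parsed`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "cohort_id,child_id,age_days,wlz",
#'   "c1,k1,1,-0.5", "c1,k1,30,-2.5", "c1,k1,61,-1.0"
#' ), f)
#' m <- read_measurements(f)
#' child_info(m)$enrolled_at_birth
#' @export
read_measurements <- function(path, col_map = NULL, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  canonical <- c("cohort_id", "child_id", "sex", "age_days", "date",
                 "wlz", "laz", "waz")
  lookup <- stats::setNames(canonical, canonical)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), canonical)
    if (length(bad)) stop("col_map names must be canonical columns; unknown: ",
                          paste(bad, collapse = ", "))
    lookup[names(col_map)] <- unname(col_map)
  }
  required <- c("cohort_id", "child_id", "age_days")
  missing_req <- required[!lookup[required] %in% names(raw)]
  if (length(missing_req)) {
    stop("missing required column(s): ",
         paste(lookup[missing_req], collapse = ", "), call. = FALSE)
  }
  z_present <- c("wlz", "laz", "waz")[lookup[c("wlz", "laz", "waz")] %in% names(raw)]
  if (!length(z_present)) {
    stop("at least one z-score column (wlz, laz, waz) is required", call. = FALSE)
  }

  get_col <- function(nm) {
    if (lookup[[nm]] %in% names(raw)) raw[[lookup[[nm]]]] else NA_character_
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    cohort_id = get_col("cohort_id"),
    child_id = get_col("child_id"),
    sex = tolower(trimws(dplyr::coalesce(get_col("sex"), "unknown"))),
    age_days = num(get_col("age_days")),
    date = as.Date(get_col("date"), format = "%Y-%m-%d"),
    wlz = num(get_col("wlz")),
    laz = num(get_col("laz")),
    waz = num(get_col("waz"))
  )
  out$sex[!out$sex %in% c("male", "female")] <- "unknown"

  reason <- rep(NA_character_, nrow(out))
  reason[is.na(out$cohort_id) | is.na(out$child_id)] <- "missing id"
  reason[is.na(reason) & (is.na(out$age_days) | out$age_days < 0)] <- "bad age"
  all_z_missing <- is.na(out$wlz) & is.na(out$laz) & is.na(out$waz)
  reason[is.na(reason) & all_z_missing] <- "no z-score"
  rejects <- dplyr::bind_cols(raw[!is.na(reason), , drop = FALSE],
                              tibble::tibble(reject_reason = reason[!is.na(reason)]))
  out <- out[is.na(reason), , drop = FALSE]
  out$age_days <- as.integer(round(out$age_days))

  out <- dplyr::arrange(out, .data$cohort_id, .data$child_id, .data$age_days)
  dup <- duplicated(out[, c("cohort_id", "child_id", "age_days")])
  out$qc_flags <- ifelse(dup, "duplicate_age", "")

  we_log(sprintf("parsed %d rows (%d rejected, %d duplicate-age flagged) from %s",
                 nrow(out), nrow(rejects), sum(dup), path))
  structure(out,
            rejects = rejects,
            n_parsed = nrow(out),
            class = c("we_measurements", class(out)))
}

#' Canonicalize an in-memory measurement table
#'
#' Applies the same sorting, duplicate flagging and column conventions as
#' [read_measurements()] to a data frame already in memory (for example the
#' output of [simulate_cohorts()] or [generate_fixture()]).
#'
#' @param df data frame with at least `cohort_id`, `child_id`, `age_days`
#'   and one z-score column.
#' @return A `we_measurements` tibble.
#' @export
as_measurements <- function(df) {
  stopifnot(all(c("cohort_id", "child_id", "age_days") %in% names(df)))
  for (col in c("sex", "date", "wlz", "laz", "waz")) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col == "sex") "unknown" else if (col == "date") as.Date(NA) else NA_real_
    }
  }
  out <- tibble::as_tibble(df)[, c("cohort_id", "child_id", "sex", "age_days",
                                   "date", "wlz", "laz", "waz")]
  out$cohort_id <- as.character(out$cohort_id)
  out$child_id <- as.character(out$child_id)
  out$age_days <- as.integer(round(out$age_days))
  stopifnot(all(out$age_days >= 0))
  out <- dplyr::arrange(out, .data$cohort_id, .data$child_id, .data$age_days)
  dup <- duplicated(out[, c("cohort_id", "child_id", "age_days")])
  out$qc_flags <- ifelse(dup, "duplicate_age", "")
  structure(out, rejects = out[0, ], n_parsed = nrow(out),
            class = c("we_measurements", class(out)))
}

#' Per-child series metadata
#'
#' @param data a measurement table.
#' @return One row per child: first and last observed age (over retained,
#'   non-duplicate rows), number of visits, number of non-missing WLZ
#'   visits, and `enrolled_at_birth` (first retained measurement at age
#'   <= 7 days).
#' @export
child_info <- function(data) {
  retained <- analysis_rows(data)
  dplyr::summarise(
    dplyr::group_by(retained, .data$cohort_id, .data$child_id),
    first_age_days = min(.data$age_days),
    last_age_days = max(.data$age_days),
    n_visits = dplyr::n(),
    n_wlz = sum(!is.na(.data$wlz)),
    enrolled_at_birth = min(.data$age_days) <= 7,
    .groups = "drop"
  )
}

# rows entering analysis: duplicate-age rows are flagged, never used
analysis_rows <- function(data) {
  if (!"qc_flags" %in% names(data)) data$qc_flags <- ""
  data[!grepl("duplicate_age", data$qc_flags), , drop = FALSE]
}

#' Read a monthly rainfall file
#'
#' Expects columns `cohort_id`, `year`, `month` (1-12), `rain_mm`. Returns
#' one row per cohort-month averaged over the observed years: the
#' `RainfallSeries` used by the seasonality operations.
#'
#' @param path path to a delimited text file.
#' @return Tibble with columns `cohort_id`, `month`, `rain_mm` (12 rows per
#'   cohort, study-period mean monthly totals).
#' @export
read_rainfall <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("cohort_id", "year", "month", "rain_mm")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req)) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(raw$month %in% 1:12), all(raw$rain_mm >= 0, na.rm = TRUE))
  dplyr::summarise(
    dplyr::group_by(raw, .data$cohort_id, .data$month),
    rain_mm = mean(.data$rain_mm, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Write any pipeline output as tidy delimited text
#'
#' One row per stratum estimate; values round-trip losslessly through
#' [readr::read_csv()] at full printed precision.
#'
#' @param result a data frame produced by a pipeline stage.
#' @param path output file path.
#' @return `result`, invisibly.
#' @export
write_table <- function(result, path) {
  stopifnot(is.data.frame(result))
  readr::write_csv(tibble::as_tibble(result), path)
  we_log(sprintf("wrote %d rows to %s", nrow(result), path))
  invisible(result)
}
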