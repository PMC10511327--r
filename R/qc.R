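#' Default biological-plausibility bounds for z-scores
#'
#' Values strictly outside these bounds are treated as biologically
#' implausible and removed from analysis: WLZ beyond (-5, 5), LAZ beyond
#' (-6, 6), WAZ beyond (-6, 5). Values exactly at a bound are retained
#' (the exclusions are strict inequalities).
#'
#' @export
plausibility_limits <- function() {
  list(wlz = c(-5, 5), laz = c(-6, 6), waz = c(-6, 5))
}

#' Apply biological-plausibility exclusions to z-scores
#'
#' Sets implausible z-score values to missing, one indicator at a time:
#' other indicators on the same row are untouched. Flagged values are
#' recorded in `qc_flags` (codes `implausible_wlz` etc.), never silently
#' dropped, and tallied per indicator and per cohort in the returned
#' report. The filter is idempotent.
#'
#' An optional technical-error screen flags visits where length decreased
#' from the previous visit by more than `length_tech_error_cm`; it runs only
#' when a `length_cm` column is present.
#'
#' @param data a measurement table ([read_measurements()] /
#'   [as_measurements()]).
#' @param limits per-indicator bounds, as [plausibility_limits()].
#' @param length_tech_error_cm allowance (cm) for the optional
#'   length-decrease screen.
#' @return A list with `data` (filtered table) and `report` (a
#'   `QCReport`: per-cohort and total counts of excluded values per
#'   indicator, with the proportion of non-missing values excluded).
#' @examples
#' m <- generate_fixture(data.frame(child_id = "k1", age_days = c(1, 30),
#'                                  wlz = c(5.2, -1)))
#' qc <- apply_plausibility_filter(m)
#' qc$report$total
#' @export
apply_plausibility_filter <- function(data,
                                      limits = plausibility_limits(),
                                      length_tech_error_cm = 1.0) {
  stopifnot(all(c("wlz", "laz", "waz") %in% names(data)))
  if (!"qc_flags" %in% names(data)) data$qc_flags <- ""

  per_cohort <- list()
  totals <- list()
  for (ind in c("wlz", "laz", "waz")) {
    b <- limits[[ind]]
    val <- data[[ind]]
    bad <- !is.na(val) & (val < b[1] | val > b[2])   # strict: boundary kept
    n_nonmiss <- tapply(!is.na(val), data$cohort_id, sum)
    n_bad <- tapply(bad, data$cohort_id, sum)
    per_cohort[[ind]] <- tibble::tibble(
      cohort_id = names(n_nonmiss),
      indicator = ind,
      n_nonmissing = as.integer(n_nonmiss),
      n_excluded = as.integer(n_bad)
    )
    totals[[ind]] <- tibble::tibble(
      indicator = ind,
      n_nonmissing = sum(!is.na(val)),
      n_excluded = sum(bad),
      proportion_excluded = ifelse(sum(!is.na(val)) > 0,
                                   sum(bad) / sum(!is.na(val)), NA_real_)
    )
    data[[ind]][bad] <- NA_real_
    data$qc_flags[bad] <- add_flag(data$qc_flags[bad], paste0("implausible_", ind))
  }

  if ("length_cm" %in% names(data)) {
    data <- dplyr::group_by(data, .data$cohort_id, .data$child_id)
    data <- dplyr::mutate(
      data,
      .len_drop = !is.na(.data$length_cm) &
        !is.na(dplyr::lag(.data$length_cm)) &
        (dplyr::lag(.data$length_cm) - .data$length_cm) > length_tech_error_cm
    )
    data <- dplyr::ungroup(data)
    data$qc_flags[data$.len_drop] <-
      add_flag(data$qc_flags[data$.len_drop], "length_decrease")
    data$.len_drop <- NULL
  }

  report <- list(
    per_cohort = dplyr::bind_rows(per_cohort),
    total = dplyr::bind_rows(totals)
  )
  class(report) <- c("we_qc_report", class(report))
  we_log(sprintf("plausibility filter: excluded %s values",
                 paste(sprintf("%d %s", report$total$n_excluded,
                               report$total$indicator), collapse = ", ")))
  list(data = data, report = report)
}

add_flag <- function(flags, code) {
  has <- grepl(code, flags, fixed = TRUE)
  out <- flags
  out[!has] <- ifelse(nzchar(flags[!has]), paste0(flags[!has], ";", code), code)
  out
}

#' @export
print.we_qc_report <- function(x, ...) {
  cat("<QC report>\n")
  print(x$total)
  invisible(x)
}
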