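#' Walsh-Lawler rainfall seasonality index
#'
#' `index = (1/R) * sum_n |X_n - R/12|` over the 12 monthly rainfall totals
#' `X_n` with annual total `R`. The index is 0 for perfectly uniform
#' rainfall and attains its maximum 11/6 when all rain falls in a single
#' month; it is invariant to rescaling the rainfall vector.
#'
#' @param rain_mm numeric vector of 12 monthly rainfall totals (mm),
#'   January first, averaged over the study years.
#' @return The seasonality index (NA with a warning when the annual total
#'   is zero).
#' @examples
#' seasonality_index(rep(100, 12))                     # 0
#' seasonality_index(c(rep(100, 6), rep(0, 6)))        # 1
#' @export
seasonality_index <- function(rain_mm) {
  stopifnot(length(rain_mm) == 12, all(rain_mm >= 0))
  R <- sum(rain_mm)
  if (R <= 0) {
    warning("zero annual rainfall: seasonality index undefined")
    return(NA_real_)
  }
  sum(abs(rain_mm - R / 12)) / R
}

#' Seasonality class from the index
#'
#' High seasonality at index >= 0.9, medium at 0.7 <= index < 0.9, low
#' below 0.7.
#'
#' @param index seasonality index value(s).
#' @return Character vector `"high"` / `"medium"` / `"low"`.
#' @export
seasonality_class <- function(index) {
  ifelse(is.na(index), NA_character_,
         ifelse(index >= 0.9, "high",
                ifelse(index >= 0.7, "medium", "low")))
}

#' Three-month window of peak rainfall
#'
#' The consecutive three-month run (wrapping December to January) with the
#' highest mean rainfall; ties are broken by the earliest calendar start
#' month.
#'
#' @param rain_mm numeric vector of 12 monthly totals, January first.
#' @return Integer vector of the 3 months (1-12) of the peak window.
#' @examples
#' peak_rain_window(c(0, 0, 0, 0, 0, 10, 100, 10, 0, 0, 0, 0))  # Jun-Aug
#' @export
peak_rain_window <- function(rain_mm) {
  stopifnot(length(rain_mm) == 12, all(rain_mm >= 0))
  sums <- vapply(1:12, function(s) sum(rain_mm[window_months(s)]), numeric(1))
  start <- which.max(sums)               # earliest start on ties
  window_months(start)
}

window_months <- function(start, len = 3) ((start - 1 + seq_len(len) - 1) %% 12) + 1

# quarter labels anchored on the peak-rain window: the window itself, the
# three months before, the three after, and the remaining (opposite) three
rain_quarters <- function(peak_window) {
  start <- peak_window[1]
  list(
    peak = window_months(start),
    pre_peak = window_months(start - 3),
    post_peak = window_months(start + 3),
    opposite = window_months(start + 6)
  )
}

#' Mean WLZ contrasts by rainfall quarter
#'
#' Assigns each dated measurement of children under 24 months to one of
#' four three-month quarters anchored on the peak-rain window (peak, the
#' three months before, the three after, and the opposite quarter as
#' reference) and estimates mean WLZ differences against the opposite
#' quarter from an ordinary linear model on quarter indicators, unadjusted
#' for other covariates.
#'
#' @param data measurement table; rows without dates are refused.
#' @param rain_mm 12 monthly rainfall totals, January first, for the
#'   cohort's location.
#' @param max_age_days upper age limit (default 24 months).
#' @return A tibble with one row per non-reference quarter: `quarter`,
#'   `months` (e.g. `"6-8"`), `diff_wlz`, `se`, `n`, plus a reference row
#'   with `diff_wlz = 0`; quarters with no measurements are flagged
#'   `undefined`.
#' @export
quarter_contrasts <- function(data, rain_mm,
                              max_age_days = 24 * DAYS_PER_MONTH) {
  rows <- analysis_rows(data)
  rows <- rows[!is.na(rows$wlz) & rows$age_days < max_age_days, , drop = FALSE]
  if (!nrow(rows) || all(is.na(rows$date))) {
    stop("quarter_contrasts requires measurement dates; this file has none")
  }
  rows <- rows[!is.na(rows$date), , drop = FALSE]
  q <- rain_quarters(peak_rain_window(rain_mm))
  month <- as.integer(format(rows$date, "%m"))
  lab <- rep(NA_character_, length(month))
  for (nm in names(q)) lab[month %in% q[[nm]]] <- nm
  rows$quarter <- factor(lab, levels = c("opposite", "pre_peak", "peak",
                                         "post_peak"))
  present <- table(rows$quarter)
  fit_data <- rows[!is.na(rows$quarter), , drop = FALSE]
  if (present["opposite"] == 0) {
    stop("no measurements in the reference (opposite) quarter")
  }
  fit <- stats::lm(wlz ~ quarter, data = fit_data)
  cf <- summary(fit)$coefficients
  res <- tibble::tibble(
    quarter = c("opposite", "pre_peak", "peak", "post_peak"),
    months = vapply(q[c("opposite", "pre_peak", "peak", "post_peak")],
                    function(m) paste(m, collapse = "-"), character(1)),
    n = as.integer(present[c("opposite", "pre_peak", "peak", "post_peak")]),
    diff_wlz = NA_real_, se = NA_real_
  )
  res$diff_wlz[1] <- 0; res$se[1] <- 0
  for (i in 2:4) {
    term <- paste0("quarter", res$quarter[i])
    if (term %in% rownames(cf)) {
      res$diff_wlz[i] <- cf[term, "Estimate"]
      res$se[i] <- cf[term, "Std. Error"]
    }
  }
  res$undefined <- res$n == 0
  res
}

#' Mean birth WLZ by calendar month of birth
#'
#' Monthly means of WLZ at the birth measure (age <= 7 days) and mean
#' differences against January, with standard errors from a linear model on
#' month indicators.
#'
#' @param data measurement table with dates.
#' @return A tibble per calendar month: `month`, `n`, `mean_wlz`,
#'   `diff_vs_jan`, `se`; months without births carry NA and are flagged
#'   `undefined`.
#' @export
birth_month_profile <- function(data) {
  rows <- analysis_rows(data)
  rows <- rows[!is.na(rows$wlz) & rows$age_days <= 7, , drop = FALSE]
  if (!nrow(rows) || all(is.na(rows$date))) {
    stop("birth_month_profile requires dated birth measures (age <= 7 days)")
  }
  rows <- rows[!is.na(rows$date), , drop = FALSE]
  rows$month <- factor(as.integer(format(rows$date, "%m")), levels = 1:12)
  means <- tapply(rows$wlz, rows$month, mean)
  counts <- table(rows$month)
  res <- tibble::tibble(month = 1:12, n = as.integer(counts),
                        mean_wlz = as.numeric(means),
                        diff_vs_jan = NA_real_, se = NA_real_)
  observed <- levels(droplevels(rows$month))
  if ("1" %in% observed && length(observed) > 1) {
    fit <- stats::lm(wlz ~ month, data = droplevels(rows))
    cf <- summary(fit)$coefficients
    res$diff_vs_jan[1] <- 0
    res$se[1] <- 0
    for (m in setdiff(observed, "1")) {
      term <- paste0("month", m)
      if (term %in% rownames(cf)) {
        res$diff_vs_jan[res$month == as.integer(m)] <- cf[term, "Estimate"]
        res$se[res$month == as.integer(m)] <- cf[term, "Std. Error"]
      }
    }
  }
  res$undefined <- res$n == 0
  res
}

#' Per-cohort seasonality summary
#'
#' Combines the index, class and peak window for each cohort in a rainfall
#' table (as returned by [read_rainfall()] or [generate_rainfall()]).
#'
#' @param rainfall tibble with `cohort_id`, `month`, `rain_mm` (12 rows per
#'   cohort).
#' @return A tibble per cohort: `seasonal_index`, `class`, `peak_window`
#'   (string `"m1-m2-m3"`), `annual_total_mm`.
#' @export
seasonality_summary <- function(rainfall) {
  pieces <- split(rainfall, rainfall$cohort_id)
  out <- lapply(pieces, function(d) {
    d <- d[order(d$month), ]
    stopifnot(identical(as.integer(d$month), 1:12))
    idx <- seasonality_index(d$rain_mm)
    tibble::tibble(
      cohort_id = d$cohort_id[1],
      seasonal_index = idx,
      class = seasonality_class(idx),
      peak_window = paste(peak_rain_window(d$rain_mm), collapse = "-"),
      annual_total_mm = sum(d$rain_mm)
    )
  })
  dplyr::bind_rows(out)
}
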