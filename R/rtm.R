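#' Estimate regression-to-the-mean parameters at an age stratum
#'
#' For a given baseline age and lag, pairs each child's WLZ measurement
#' nearest the baseline age with the measurement nearest baseline + lag
#' (each within a matching window), then estimates the population mean at
#' baseline and the between-age correlation from all paired children --
#' not only the threshold-selected ones, which would bias the correlation.
#'
#' @param data measurement table.
#' @param baseline_age_days baseline age (days).
#' @param lag_days follow-up lag (days; default 3 months).
#' @param window_days half-width of the matching window around each target
#'   age.
#' @param min_pairs minimum number of paired children required.
#' @return A list of class `we_rtm_params`: `mu` (population mean at
#'   baseline), `r` (between-age correlation), `n_pairs`,
#'   `baseline_age_days`, `lag_days`.
#' @export
estimate_rtm_params <- function(data, baseline_age_days,
                                lag_days = 3 * DAYS_PER_MONTH,
                                window_days = DAYS_PER_MONTH,
                                min_pairs = 20) {
  rows <- analysis_rows(data)
  rows <- rows[!is.na(rows$wlz), , drop = FALSE]
  pick <- function(d, target) {
    ok <- abs(d$age_days - target) <= window_days
    if (!any(ok)) return(NA_real_)
    d$wlz[ok][which.min(abs(d$age_days[ok] - target))]
  }
  pieces <- split(rows[, c("age_days", "wlz")],
                  paste(rows$cohort_id, rows$child_id, sep = "\r"))
  base <- vapply(pieces, pick, numeric(1), target = baseline_age_days)
  foll <- vapply(pieces, pick, numeric(1),
                 target = baseline_age_days + lag_days)
  ok <- !is.na(base) & !is.na(foll)
  if (sum(ok) < min_pairs) {
    stop(sprintf(
      "only %d paired children at baseline %.0f d + lag %.0f d (need >= %d)",
      sum(ok), baseline_age_days, lag_days, min_pairs))
  }
  structure(
    list(mu = mean(base[ok]), r = stats::cor(base[ok], foll[ok]),
         n_pairs = sum(ok), baseline_age_days = baseline_age_days,
         lag_days = lag_days),
    class = "we_rtm_params"
  )
}

#' @export
print.we_rtm_params <- function(x, ...) {
  cat(sprintf(
    "<RTM parameters> mu = %.3f, r = %.3f (n = %d pairs, baseline %.0f d, lag %.0f d)\n",
    x$mu, x$r, x$n_pairs, x$baseline_age_days, x$lag_days))
  invisible(x)
}

#' Expected follow-up mean under regression to the mean
#'
#' The classical linear RTM expectation under bivariate normality: a group
#' selected with mean `selected_mean` at baseline is expected to have mean
#' `mu + r * (selected_mean - mu)` at follow-up, where `mu` is the
#' population mean and `r` the between-age correlation. The RTM effect is
#' `(1 - r) * (mu - selected_mean)`; observed improvement beyond it is
#' catch-up growth rather than an artefact of selection.
#'
#' @param params an `we_rtm_params` object (or list with `mu` and `r`).
#' @param selected_mean baseline mean of the threshold-selected group.
#' @return A one-row tibble: `expected_mean`, `rtm_effect`, `mu`, `r`,
#'   `selected_mean`.
#' @examples
#' p <- list(mu = -0.5, r = 0.6)
#' expected_mean_after_rtm(p, selected_mean = -2.5)
#' @export
expected_mean_after_rtm <- function(params, selected_mean) {
  stopifnot(is.numeric(params$mu), is.numeric(params$r),
            abs(params$r) <= 1)
  expected <- params$mu + params$r * (selected_mean - params$mu)
  tibble::tibble(
    expected_mean = expected,
    rtm_effect = (1 - params$r) * (params$mu - selected_mean),
    mu = params$mu, r = params$r, selected_mean = selected_mean
  )
}

#' Expected versus observed follow-up means for wasted children, by age
#'
#' Runs the RTM computation over a grid of baseline ages: at each age the
#' cohort mean and between-age correlation are estimated from all paired
#' children, the mean of the sub-threshold (wasted) group is plugged into
#' the RTM expectation, and the observed follow-up mean of that group is
#' reported alongside.
#'
#' @param data measurement table (single cohort; subset beforehand for
#'   per-cohort results).
#' @param baseline_ages_days vector of baseline ages (days).
#' @param threshold selection threshold (default -2, i.e. wasted).
#' @inheritParams estimate_rtm_params
#' @return A tibble per baseline age: `mu`, `r`, `selected_mean`,
#'   `expected_mean`, `observed_mean`, `rtm_effect`, `n_pairs`,
#'   `n_selected`; ages with too few pairs or no selected children are
#'   skipped with a message.
#' @export
rtm_expected_vs_observed <- function(data, baseline_ages_days,
                                     threshold = -2,
                                     lag_days = 3 * DAYS_PER_MONTH,
                                     window_days = DAYS_PER_MONTH,
                                     min_pairs = 20) {
  rows <- analysis_rows(data)
  rows <- rows[!is.na(rows$wlz), , drop = FALSE]
  pieces <- split(rows[, c("age_days", "wlz")],
                  paste(rows$cohort_id, rows$child_id, sep = "\r"))
  pick <- function(d, target) {
    ok <- abs(d$age_days - target) <= window_days
    if (!any(ok)) return(NA_real_)
    d$wlz[ok][which.min(abs(d$age_days[ok] - target))]
  }
  out <- list()
  for (a in baseline_ages_days) {
    base <- vapply(pieces, pick, numeric(1), target = a)
    foll <- vapply(pieces, pick, numeric(1), target = a + lag_days)
    ok <- !is.na(base) & !is.na(foll)
    sel <- ok & base < threshold
    if (sum(ok) < min_pairs || !any(sel)) {
      we_log(sprintf("skipping baseline %.0f d: %d pairs, %d selected",
                     a, sum(ok), sum(sel)))
      next
    }
    mu <- mean(base[ok]); r <- stats::cor(base[ok], foll[ok])
    sm <- mean(base[sel])
    exp_row <- expected_mean_after_rtm(list(mu = mu, r = r), sm)
    out[[length(out) + 1L]] <- tibble::tibble(
      baseline_age_days = a, mu = mu, r = r, selected_mean = sm,
      expected_mean = exp_row$expected_mean,
      observed_mean = mean(foll[sel]),
      rtm_effect = exp_row$rtm_effect,
      n_pairs = sum(ok), n_selected = sum(sel)
    )
  }
  dplyr::bind_rows(out)
}
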