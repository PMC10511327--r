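indicator_condition <- function(rows, indicator, cfg) {
  switch(indicator,
    wasting = list(ok = !is.na(rows$wlz), hit = !is.na(rows$wlz) &
                     rows$wlz < cfg$wasting_cutoff),
    severe_wasting = list(ok = !is.na(rows$wlz), hit = !is.na(rows$wlz) &
                            rows$wlz < cfg$severe_cutoff),
    stunting = list(ok = !is.na(rows$laz), hit = !is.na(rows$laz) &
                      rows$laz < -2),
    underweight = list(ok = !is.na(rows$waz), hit = !is.na(rows$waz) &
                         rows$waz < -2),
    concurrent_ws = list(ok = !is.na(rows$wlz) & !is.na(rows$laz),
                         hit = !is.na(rows$wlz) & !is.na(rows$laz) &
                           rows$wlz < cfg$wasting_cutoff & rows$laz < -2),
    stop("unknown indicator: ", indicator)
  )
}

#' Age-stratified point prevalence
#'
#' For each age stratum, children with at least one qualifying measurement
#' within `window_months` months on either side of the target age form the
#' denominator; a child counts as prevalent if any visit in the window
#' meets the condition. Concurrent wasting-stunting requires WLZ < -2 and
#' LAZ < -2 at the same visit.
#'
#' @param data a QC-filtered measurement table.
#' @param indicator one of `"wasting"`, `"severe_wasting"`, `"stunting"`,
#'   `"underweight"`, `"concurrent_ws"`.
#' @param age_months vector of target ages (months).
#' @param cfg an [analysis_config()].
#' @param window_months half-width of the measurement window (defaults to
#'   the configured prevalence window).
#' @return A tibble per cohort and age: `statistic`, `age_target_months`,
#'   `n_children`, `n_events`, `estimate`, binomial `se`, and `undefined`
#'   where no children fall in the window.
#' @export
point_prevalence <- function(data, indicator = "wasting", age_months = 6,
                             cfg = analysis_config(),
                             window_months = cfg$prevalence_window_months) {
  rows <- analysis_rows(data)
  out <- list()
  for (a in age_months) {
    t0 <- a * DAYS_PER_MONTH
    w <- window_months * DAYS_PER_MONTH
    inwin <- rows$age_days >= t0 - w & rows$age_days <= t0 + w
    cond <- indicator_condition(rows, indicator, cfg)
    sub <- tibble::tibble(cohort_id = rows$cohort_id,
                          child_id = rows$child_id,
                          ok = inwin & cond$ok, hit = inwin & cond$hit)
    per_child <- dplyr::summarise(
      dplyr::group_by(sub, .data$cohort_id, .data$child_id),
      ok = any(.data$ok), hit = any(.data$hit), .groups = "drop"
    )
    per_child <- per_child[per_child$ok, , drop = FALSE]
    est <- dplyr::summarise(
      dplyr::group_by(per_child, .data$cohort_id),
      n_children = dplyr::n(), n_events = sum(.data$hit), .groups = "drop"
    )
    est$statistic <- indicator
    est$age_target_months <- a
    out[[length(out) + 1L]] <- est
  }
  res <- dplyr::bind_rows(out)
  res$undefined <- res$n_children == 0
  res$estimate <- ifelse(res$undefined, NA_real_, res$n_events / res$n_children)
  res$se <- proportion_se(res$n_events, res$n_children)
  res[, c("cohort_id", "statistic", "age_target_months", "n_children",
          "n_events", "estimate", "se", "undefined")]
}

# binomial SE with a Wilson-variance fallback at 0/1 so pooling weights
# stay finite
proportion_se <- function(x, n) {
  p <- ifelse(n > 0, x / n, NA_real_)
  se <- sqrt(p * (1 - p) / n)
  boundary <- !is.na(p) & (x == 0 | x == n) & n > 0
  if (any(boundary)) {
    pw <- (x[boundary] + 2) / (n[boundary] + 4)   # Agresti-Coull centre
    se[boundary] <- sqrt(pw * (1 - pw) / (n[boundary] + 4))
  }
  se
}

#' Cumulative incidence of wasting since birth
#'
#' Proportion of children who have ever had an episode onset at or before
#' the target age, among children with at least one WLZ measurement at or
#' before that age.
#'
#' @param data measurement table.
#' @param episodes output of [classify_episodes()].
#' @param up_to_age_days target age in days (vectorised).
#' @return A tibble per cohort and age with `n_children`, `n_events`,
#'   `estimate`, `se`.
#' @export
cumulative_incidence <- function(data, episodes, up_to_age_days) {
  rows <- analysis_rows(data)
  rows <- rows[!is.na(rows$wlz), , drop = FALSE]
  out <- list()
  for (a in up_to_age_days) {
    denom <- dplyr::distinct(rows[rows$age_days <= a,
                                  c("cohort_id", "child_id")])
    ev <- dplyr::distinct(episodes[episodes$onset_age_days <= a,
                                   c("cohort_id", "child_id")])
    ev$event <- TRUE
    d <- dplyr::left_join(denom, ev, by = c("cohort_id", "child_id"))
    d$event[is.na(d$event)] <- FALSE
    est <- dplyr::summarise(dplyr::group_by(d, .data$cohort_id),
                            n_children = dplyr::n(),
                            n_events = sum(.data$event), .groups = "drop")
    est$up_to_age_days <- a
    out[[length(out) + 1L]] <- est
  }
  res <- dplyr::bind_rows(out)
  res$estimate <- ifelse(res$n_children > 0, res$n_events / res$n_children,
                         NA_real_)
  res$se <- proportion_se(res$n_events, res$n_children)
  res[, c("cohort_id", "up_to_age_days", "n_children", "n_events",
          "estimate", "se")]
}

#' Incidence proportion over an age window
#'
#' Proportion of children at risk at the window start (observed at that
#' age, not wasted and not inside a washout tail) who have an episode onset
#' within the window. Children wasted at the start are excluded from both
#' numerator and denominator.
#'
#' @param data measurement table.
#' @param episodes output of [classify_episodes()].
#' @param age_window `c(lo, hi)` in days.
#' @param cfg the [analysis_config()] used for the episodes.
#' @return A tibble per cohort with `n_at_risk`, `n_onsets`, `estimate`,
#'   `se`, `undefined`.
#' @export
incidence_proportion <- function(data, episodes, age_window,
                                 cfg = analysis_config()) {
  stopifnot(length(age_window) == 2, age_window[2] > age_window[1])
  lo <- age_window[1]; hi <- age_window[2]
  info <- child_info(data)
  info <- info[info$n_wlz > 0, , drop = FALSE]
  obs <- info[info$first_age_days <= lo & info$last_age_days >= lo, , drop = FALSE]

  key <- function(d) paste(d$cohort_id, d$child_id, sep = "\r")
  not_at_risk_at_lo <- episodes$onset_age_days <= lo &
    (episodes$censored | episodes$recovery_age_days + cfg$washout_days > lo)
  excluded <- unique(key(episodes[not_at_risk_at_lo, , drop = FALSE]))
  obs <- obs[!key(obs) %in% excluded, , drop = FALSE]

  hit_eps <- episodes[episodes$onset_age_days >= lo &
                        episodes$onset_age_days < hi, , drop = FALSE]
  obs$event <- key(obs) %in% key(hit_eps)
  res <- dplyr::summarise(dplyr::group_by(obs, .data$cohort_id),
                          n_at_risk = dplyr::n(),
                          n_onsets = sum(.data$event), .groups = "drop")
  res$undefined <- res$n_at_risk == 0
  res$estimate <- ifelse(res$undefined, NA_real_, res$n_onsets / res$n_at_risk)
  res$se <- proportion_se(res$n_onsets, res$n_at_risk)
  res
}

#' Persistent wasting
#'
#' A child is persistently wasted when at least `persistent_fraction` of
#' their non-missing WLZ measurements (at least
#' `min_measurements_persistent` of them) fall below the cutoff;
#' `persistent_strict = TRUE` in the configuration switches the boundary to
#' a strict inequality. Children with fewer measurements are excluded from
#' the denominator.
#'
#' @param data measurement table.
#' @param cfg an [analysis_config()].
#' @param severe use the severe-wasting cutoff instead.
#' @return A tibble per cohort with `n_children`, `n_persistent`,
#'   `estimate`, `se`.
#' @export
persistent_wasting <- function(data, cfg = analysis_config(), severe = FALSE) {
  cutoff <- if (severe) cfg$severe_cutoff else cfg$wasting_cutoff
  rows <- analysis_rows(data)
  rows <- rows[!is.na(rows$wlz), , drop = FALSE]
  per_child <- dplyr::summarise(
    dplyr::group_by(rows, .data$cohort_id, .data$child_id),
    n = dplyr::n(), frac = mean(.data$wlz < cutoff), .groups = "drop"
  )
  per_child <- per_child[per_child$n >= cfg$min_measurements_persistent, ,
                         drop = FALSE]
  persistent <- if (cfg$persistent_strict) {
    per_child$frac > cfg$persistent_fraction
  } else {
    per_child$frac >= cfg$persistent_fraction
  }
  per_child$persistent <- persistent
  res <- dplyr::summarise(dplyr::group_by(per_child, .data$cohort_id),
                          n_children = dplyr::n(),
                          n_persistent = sum(.data$persistent),
                          .groups = "drop")
  res$estimate <- ifelse(res$n_children > 0,
                         res$n_persistent / res$n_children, NA_real_)
  res$se <- proportion_se(res$n_persistent, res$n_children)
  res
}

faltering_categories <- c(
  "never_faltered", "recovered", "wasted_only", "stunted_only",
  "underweight_only", "wasted_and_underweight", "stunted_and_underweight",
  "wasted_stunted_underweight"
)

#' Growth-faltering state partition at an age stratum
#'
#' Assigns each child at an age stratum to one mutually exclusive category
#' from current status (any qualifying visit in the +/- window) and history
#' (visits before the window): never faltered; recovered (not currently
#' wasted/stunted/underweight but previously any of them); or a current
#' combination. Children currently both wasted and stunted are classified
#' `wasted_stunted_underweight` (wasted and stunted children are also
#' underweight). Proportions are rescaled to sum exactly to 1.
#'
#' @param data measurement table with WLZ, LAZ and WAZ.
#' @param age_months target age (single value).
#' @param cfg an [analysis_config()].
#' @param window_months half-width of the stratum window in months.
#' @return A tibble per cohort and category with `proportion` and
#'   `n_children`.
#' @export
faltering_partition <- function(data, age_months, cfg = analysis_config(),
                                window_months = cfg$prevalence_window_months) {
  stopifnot(length(age_months) == 1)
  rows <- analysis_rows(data)
  t0 <- age_months * DAYS_PER_MONTH
  w <- window_months * DAYS_PER_MONTH
  rows$wasted <- !is.na(rows$wlz) & rows$wlz < cfg$wasting_cutoff
  rows$stunted <- !is.na(rows$laz) & rows$laz < -2
  rows$under <- !is.na(rows$waz) & rows$waz < -2
  rows$any_z <- !is.na(rows$wlz) | !is.na(rows$laz) | !is.na(rows$waz)
  inwin <- rows$age_days >= t0 - w & rows$age_days <= t0 + w
  before <- rows$age_days < t0 - w

  df <- tibble::tibble(
    cohort_id = rows$cohort_id, child_id = rows$child_id,
    present = inwin & rows$any_z,
    cur_w = inwin & rows$wasted, cur_s = inwin & rows$stunted,
    cur_u = inwin & rows$under,
    hist = before & (rows$wasted | rows$stunted | rows$under)
  )
  per_child <- dplyr::summarise(
    dplyr::group_by(df, .data$cohort_id, .data$child_id),
    present = any(.data$present), cur_w = any(.data$cur_w),
    cur_s = any(.data$cur_s), cur_u = any(.data$cur_u),
    hist = any(.data$hist), .groups = "drop"
  )
  per_child <- per_child[per_child$present, , drop = FALSE]
  cat <- with(per_child, ifelse(
    !cur_w & !cur_s & !cur_u, ifelse(hist, "recovered", "never_faltered"),
    ifelse(cur_w & cur_s, "wasted_stunted_underweight",
      ifelse(cur_w & cur_u, "wasted_and_underweight",
        ifelse(cur_s & cur_u, "stunted_and_underweight",
          ifelse(cur_w, "wasted_only",
            ifelse(cur_s, "stunted_only", "underweight_only")))))))
  per_child$category <- factor(cat, levels = faltering_categories)
  res <- dplyr::count(per_child, .data$cohort_id, .data$category,
                      .drop = FALSE, name = "n")
  res <- dplyr::group_by(res, .data$cohort_id)
  res <- dplyr::mutate(res, n_children = sum(.data$n),
                       proportion = .data$n / sum(.data$n))
  res <- dplyr::ungroup(res)
  res$age_target_months <- age_months
  res$category <- as.character(res$category)
  res[, c("cohort_id", "age_target_months", "category", "n", "n_children",
          "proportion")]
}

#' Relative risk from 2x2 counts
#'
#' Risk ratio with a log-scale Wald confidence interval. When either event
#' count is zero, 0.5 is added to all four cells (continuity correction).
#'
#' @param n_event_exposed,n_exposed events and total in the exposed group.
#' @param n_event_unexposed,n_unexposed events and total in the unexposed
#'   group.
#' @param conf_level confidence level.
#' @return A one-row tibble: `rr`, `ci_lo`, `ci_hi`, risks per group, and
#'   whether a continuity correction was applied.
#' @examples
#' relative_risk(30, 100, 15, 100)$rr  # 2
#' @export
relative_risk <- function(n_event_exposed, n_exposed,
                          n_event_unexposed, n_unexposed,
                          conf_level = 0.95) {
  stopifnot(n_exposed > 0, n_unexposed > 0,
            n_event_exposed >= 0, n_event_unexposed >= 0,
            n_event_exposed <= n_exposed, n_event_unexposed <= n_unexposed)
  a <- n_event_exposed; n1 <- n_exposed
  b <- n_event_unexposed; n0 <- n_unexposed
  corrected <- a == 0 || b == 0
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; n1 <- n1 + 0.5; n0 <- n0 + 0.5
  }
  rr <- (a / n1) / (b / n0)
  se_log <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n0)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    rr = rr,
    ci_lo = exp(log(rr) - zq * se_log),
    ci_hi = exp(log(rr) + zq * se_log),
    risk_exposed = n_event_exposed / n_exposed,
    risk_unexposed = n_event_unexposed / n_unexposed,
    continuity_corrected = corrected
  )
}

#' Loess smoother for age curves (plotting aid)
#'
#' A light wrapper used for descriptive mean-by-age figures; it carries no
#' confidence-interval machinery.
#'
#' @param data measurement table.
#' @param indicator z-score column to smooth.
#' @param span loess span.
#' @param grid_days ages at which to evaluate the smooth.
#' @return A tibble `age_days`, `fitted`.
#' @export
smooth_age_curve <- function(data, indicator = "wlz", span = 0.75,
                             grid_days = seq(0, 730, by = 15)) {
  rows <- analysis_rows(data)
  rows <- rows[!is.na(rows[[indicator]]), , drop = FALSE]
  fit <- stats::loess(rows[[indicator]] ~ rows$age_days, span = span,
                      degree = 2)
  tibble::tibble(age_days = grid_days,
                 fitted = stats::predict(fit, newdata = grid_days))
}
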