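#' Classify wasting (or severe-wasting) episodes from a z-score series
#'
#' Transforms each child's WLZ series into discrete episodes using midpoint
#' conventions: an episode's onset is halfway between the last measurement
#' at or above the cutoff and the first below it; recovery is halfway
#' between the last measurement below the cutoff and the first at or above
#' it, provided the child then remains at or above the cutoff for at least
#' `washout_days` (a relapse sooner continues the same episode). A child
#' still below the cutoff at the last measurement carries a censored
#' episode, ended administratively at the last measurement age.
#'
#' Children wasted at their first WLZ measurement are handled by enrollment
#' type: a birth measure (age <= 7 days) gives `onset_kind = "at_birth"`
#' with onset at that age; a later first measurement gives
#' `onset_kind = "at_enrollment"` with onset halfway between birth and the
#' first measurement. All other onsets are `"interval"`.
#'
#' Missing-WLZ visits are skipped; midpoints bracket the nearest non-missing
#' neighbours. Gaps longer than 90 days between successive WLZ measurements
#' trigger a logged warning (no maximum-gap exclusion is applied).
#'
#' @param data a measurement table ([as_measurements()] and QC-filtered).
#' @param cfg an [analysis_config()].
#' @param condition `"wasting"` (WLZ < `wasting_cutoff`) or
#'   `"severe_wasting"` (WLZ < `severe_cutoff`).
#'
#' @return A tibble with one row per episode: `cohort_id`, `child_id`,
#'   `episode_id`, `condition`, `onset_age_days`, `onset_kind`,
#'   `recovery_age_days` (NA when censored), `censored`, `duration_days`
#'   (NA when censored), `born_wasted` (child wasted at a birth measure),
#'   `first_obs_age_days`, `last_obs_age_days` (span of non-missing WLZ).
#' @examples
#' m <- generate_fixture(data.frame(
#'   child_id = "k1", age_days = c(40, 70, 100, 130),
#'   wlz = c(-1.5, -2.5, -1.5, -1.5)))
#' classify_episodes(m, analysis_config())$duration_days  # 30
#' @export
classify_episodes <- function(data, cfg = analysis_config(),
                              condition = c("wasting", "severe_wasting")) {
  condition <- match.arg(condition)
  cutoff <- cutoff_for(cfg, condition)
  rows <- analysis_rows(data)
  rows <- rows[!is.na(rows$wlz), , drop = FALSE]
  if (!nrow(rows)) return(empty_episodes(condition))

  key <- paste(rows$cohort_id, rows$child_id, sep = "\r")
  pieces <- split(seq_len(nrow(rows)), key)
  out <- vector("list", length(pieces))
  long_gap <- 0L
  for (i in seq_along(pieces)) {
    idx <- pieces[[i]]
    age <- rows$age_days[idx]
    z <- rows$wlz[idx]
    if (length(age) > 1 && any(diff(age) > 90)) long_gap <- long_gap + 1L
    eps <- classify_child(age, z, cutoff, cfg$washout_days, cfg$recovery_rule)
    if (is.null(eps)) next
    eps$cohort_id <- rows$cohort_id[idx[1]]
    eps$child_id <- rows$child_id[idx[1]]
    eps$born_wasted <- age[1] <= 7 && z[1] < cfg$wasting_cutoff
    eps$first_obs_age_days <- age[1]
    eps$last_obs_age_days <- age[length(age)]
    out[[i]] <- eps
  }
  if (long_gap > 0) {
    we_log(sprintf("%d children have measurement gaps > 90 days", long_gap),
           level = "warn")
  }
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) return(empty_episodes(condition))
  out$condition <- condition
  out <- dplyr::group_by(out, .data$cohort_id, .data$child_id)
  out <- dplyr::mutate(out, episode_id = dplyr::row_number())
  out <- dplyr::ungroup(out)
  out[, c("cohort_id", "child_id", "episode_id", "condition",
          "onset_age_days", "onset_kind", "recovery_age_days", "censored",
          "duration_days", "born_wasted", "first_obs_age_days",
          "last_obs_age_days")]
}

empty_episodes <- function(condition = "wasting") {
  tibble::tibble(
    cohort_id = character(), child_id = character(), episode_id = integer(),
    condition = character(), onset_age_days = numeric(),
    onset_kind = character(), recovery_age_days = numeric(),
    censored = logical(), duration_days = numeric(), born_wasted = logical(),
    first_obs_age_days = numeric(), last_obs_age_days = numeric()
  )
}

# Single-child classifier on the (age, wlz) pairs of non-missing visits.
# Works on the run-length encoding of the below-cutoff indicator; the latent
# wasted/non-wasted status switches at midpoints between measurements of
# opposite status. An above-cutoff spell shorter than the washout (in latent
# time) does not end the episode. A trailing above-cutoff spell is accepted
# as recovery unless the two-measurement rule demands a second confirming
# measurement that is absent.
classify_child <- function(age, z, cutoff, washout, rule) {
  below <- z < cutoff
  if (!any(below)) return(NULL)
  n <- length(age)
  r <- rle(below)
  K <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-K] + 1L)
  mids <- if (K > 1) (age[ends[-K]] + age[starts[-1]]) / 2 else numeric(0)
  t_start <- c(age[1], mids)
  t_end <- c(mids, age[n])

  sustained <- function(k) {
    # above-cutoff run k ends the preceding episode?
    if (k == K) {                       # trailing spell: no relapse observed
      rule != "two_measurements" || r$lengths[k] >= 2
    } else {
      ok <- (t_end[k] - t_start[k]) >= washout
      if (rule == "two_measurements") ok <- ok && r$lengths[k] >= 2
      ok
    }
  }

  episodes <- list()
  k <- if (r$values[1]) 1L else 2L      # first below run
  while (k <= K) {
    onset_run <- k
    # extend across non-sustained interior above spells
    while (k + 1L < K && !sustained(k + 1L)) k <- k + 2L
    last_below <- k
    if (onset_run == 1L) {
      if (age[1] <= 7) {
        onset <- age[1]; kind <- "at_birth"
      } else {
        onset <- age[1] / 2; kind <- "at_enrollment"
      }
    } else {
      onset <- t_start[onset_run]; kind <- "interval"
    }
    if (last_below == K) {              # below at end of series
      rec <- NA_real_; cens <- TRUE
    } else if (last_below + 1L == K && !sustained(K)) {
      rec <- NA_real_; cens <- TRUE     # unconfirmed trailing recovery
    } else {
      rec <- t_end[last_below]; cens <- FALSE
    }
    episodes[[length(episodes) + 1L]] <- tibble::tibble(
      onset_age_days = onset, onset_kind = kind,
      recovery_age_days = rec, censored = cens,
      duration_days = if (cens) NA_real_ else rec - onset
    )
    if (cens) break                     # censored episode runs to series end
    k <- last_below + 2L
  }
  dplyr::bind_rows(episodes)
}

#' Person-time at risk of incident wasting
#'
#' Partitions each child's observed span (first to last non-missing WLZ
#' measurement) into at-risk and not-at-risk intervals. A child is not at
#' risk from an episode's onset until `washout_days` after its recovery;
#' censored episodes remove all time through the end of the series. At-risk
#' and not-at-risk days sum exactly to the observed span.
#'
#' @param data the measurement table used for [classify_episodes()].
#' @param episodes output of [classify_episodes()] on the same data.
#' @param cfg the same [analysis_config()].
#' @return A tibble of intervals: `cohort_id`, `child_id`,
#'   `start_age_days`, `end_age_days`, `at_risk`.
#' @export
person_time_at_risk <- function(data, episodes, cfg = analysis_config()) {
  rows <- analysis_rows(data)
  rows <- rows[!is.na(rows$wlz), , drop = FALSE]
  span <- dplyr::summarise(
    dplyr::group_by(rows, .data$cohort_id, .data$child_id),
    first = min(.data$age_days), last = max(.data$age_days), .groups = "drop"
  )
  ep_by_child <- split(episodes, paste(episodes$cohort_id, episodes$child_id,
                                       sep = "\r"))
  out <- vector("list", nrow(span))
  for (i in seq_len(nrow(span))) {
    key <- paste(span$cohort_id[i], span$child_id[i], sep = "\r")
    lo <- span$first[i]; hi <- span$last[i]
    eps <- ep_by_child[[key]]
    blocks <- if (is.null(eps) || !nrow(eps)) {
      matrix(numeric(0), ncol = 2)
    } else {
      end <- ifelse(eps$censored, hi, pmin(eps$recovery_age_days +
                                             cfg$washout_days, hi))
      cbind(pmax(eps$onset_age_days, lo), end)
    }
    out[[i]] <- child_intervals(lo, hi, blocks, span$cohort_id[i],
                                span$child_id[i])
  }
  dplyr::bind_rows(out)
}

child_intervals <- function(lo, hi, blocks, cohort_id, child_id) {
  if (nrow(blocks)) {
    blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
    # episodes are separated by >= washout so blocks cannot overlap, but be
    # safe about zero-length and clipped intervals
    blocks <- blocks[blocks[, 2] > blocks[, 1], , drop = FALSE]
  }
  starts <- c(lo, blocks[, 2])
  ends <- c(blocks[, 1], hi)
  pieces <- list()
  for (j in seq_along(starts)) {
    if (ends[j] > starts[j]) {
      pieces[[length(pieces) + 1L]] <- c(starts[j], ends[j], TRUE)
    }
    if (j <= nrow(blocks)) {
      pieces[[length(pieces) + 1L]] <- c(blocks[j, 1], blocks[j, 2], FALSE)
    }
  }
  if (!length(pieces)) {
    return(tibble::tibble(cohort_id = character(), child_id = character(),
                          start_age_days = numeric(), end_age_days = numeric(),
                          at_risk = logical()))
  }
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  tibble::tibble(cohort_id = cohort_id, child_id = child_id,
                 start_age_days = m[, 1], end_age_days = m[, 2],
                 at_risk = as.logical(m[, 3]))
}

#' Incidence rate of wasting per 1,000 child-days at risk
#'
#' Counts episode onsets inside an age window and divides by the at-risk
#' person-days intersecting the window, per cohort. The confidence interval
#' is an exact Poisson interval on the onset count, scaled by person-time.
#'
#' @param episodes output of [classify_episodes()].
#' @param risk_intervals output of [person_time_at_risk()].
#' @param age_window `c(lo, hi)` in days; onsets with `lo <= onset < hi`
#'   count.
#' @param exclude_onset_kinds onset kinds dropped from the numerator (e.g.
#'   `c("at_birth", "at_enrollment")` for the postnatal-onset sensitivity
#'   analysis).
#' @param per rate denominator (default 1,000 child-days).
#' @param conf_level confidence level for the Poisson interval.
#' @return A tibble per cohort: onsets, at-risk days, `rate` (per `per`
#'   child-days), `ci_lo`, `ci_hi`, and `undefined` flagging cohorts with
#'   zero at-risk days.
#' @export
incidence_rate <- function(episodes, risk_intervals, age_window,
                           exclude_onset_kinds = character(),
                           per = 1000, conf_level = 0.95) {
  stopifnot(length(age_window) == 2, age_window[2] > age_window[1])
  lo <- age_window[1]; hi <- age_window[2]
  eps <- episodes[!episodes$onset_kind %in% exclude_onset_kinds, , drop = FALSE]
  eps <- eps[eps$onset_age_days >= lo & eps$onset_age_days < hi, , drop = FALSE]
  onsets <- dplyr::count(eps, .data$cohort_id, name = "n_onsets")

  ri <- risk_intervals[risk_intervals$at_risk, , drop = FALSE]
  ri$days <- pmax(0, pmin(ri$end_age_days, hi) - pmax(ri$start_age_days, lo))
  days <- dplyr::summarise(dplyr::group_by(ri, .data$cohort_id),
                           at_risk_days = sum(.data$days), .groups = "drop")

  res <- dplyr::full_join(days, onsets, by = "cohort_id")
  res$n_onsets[is.na(res$n_onsets)] <- 0L
  res$at_risk_days[is.na(res$at_risk_days)] <- 0
  res$undefined <- res$at_risk_days <= 0
  ci <- t(vapply(seq_len(nrow(res)), function(i) {
    if (res$undefined[i]) return(c(NA_real_, NA_real_, NA_real_))
    x <- res$n_onsets[i]; pt <- res$at_risk_days[i]
    int <- stats::poisson.test(x, conf.level = conf_level)$conf.int
    c(per * x / pt, per * int[1] / pt, per * int[2] / pt)
  }, numeric(3)))
  res$rate <- ci[, 1]; res$ci_lo <- ci[, 2]; res$ci_hi <- ci[, 3]
  res[, c("cohort_id", "n_onsets", "at_risk_days", "rate", "ci_lo", "ci_hi",
          "undefined")]
}

#' Proportion of episodes recovered within 30/60/90 days of onset
#'
#' For each horizon, the numerator is the uncensored episodes whose duration
#' is at most the horizon. The default denominator keeps episodes that
#' either recovered within the horizon or were observed for at least the
#' horizon after onset, so episodes administratively censored with short
#' follow-up do not deflate recovery; `denominator = "all"` uses every
#' episode.
#'
#' @param episodes output of [classify_episodes()].
#' @param horizons days since onset (sorted internally).
#' @param denominator `"sufficient_followup"` (default) or `"all"`.
#' @return A tibble per cohort and horizon with counts, `proportion`, and a
#'   binomial `se`; cohorts with an empty denominator are flagged
#'   `undefined`.
#' @export
recovery_proportions <- function(episodes, horizons = c(30, 60, 90),
                                 denominator = c("sufficient_followup", "all")) {
  denominator <- match.arg(denominator)
  horizons <- sort(horizons)
  if (!nrow(episodes)) {
    return(tibble::tibble(cohort_id = character(), horizon_days = numeric(),
                          n_recovered = integer(), n_denominator = integer(),
                          proportion = numeric(), se = numeric(),
                          undefined = logical()))
  }
  followup <- episodes$last_obs_age_days - episodes$onset_age_days
  out <- list()
  for (h in horizons) {
    rec <- !episodes$censored & episodes$duration_days <= h
    denom <- if (denominator == "all") rep(TRUE, nrow(episodes)) else
      (rec | followup >= h)
    d <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(cohort_id = episodes$cohort_id,
                                     rec = rec & denom, denom = denom),
                      .data$cohort_id),
      n_recovered = sum(.data$rec), n_denominator = sum(.data$denom),
      .groups = "drop"
    )
    d$horizon_days <- h
    out[[length(out) + 1L]] <- d
  }
  res <- dplyr::bind_rows(out)
  res$undefined <- res$n_denominator == 0
  res$proportion <- ifelse(res$undefined, NA_real_,
                           res$n_recovered / res$n_denominator)
  res$se <- ifelse(res$undefined, NA_real_,
                   sqrt(pmax(res$proportion * (1 - res$proportion), 0) /
                          pmax(res$n_denominator, 1)))
  dplyr::arrange(res[, c("cohort_id", "horizon_days", "n_recovered",
                         "n_denominator", "proportion", "se", "undefined")],
                 .data$cohort_id, .data$horizon_days)
}

#' Median episode duration per cohort
#'
#' The median of uncensored durations, reported only when fewer than half
#' of a cohort's episodes are censored (the duration of censored episodes
#' is unknown, so a median dominated by them would be meaningless).
#'
#' @param episodes output of [classify_episodes()].
#' @return A tibble per cohort: `n_episodes`, `n_censored`,
#'   `median_duration_days` (NA when undefined) and `defined`.
#' @export
median_duration <- function(episodes) {
  if (!nrow(episodes)) {
    return(tibble::tibble(cohort_id = character(), n_episodes = integer(),
                          n_censored = integer(),
                          median_duration_days = numeric(),
                          defined = logical()))
  }
  dplyr::summarise(
    dplyr::group_by(episodes, .data$cohort_id),
    n_episodes = dplyr::n(),
    n_censored = sum(.data$censored),
    defined = n_censored / n_episodes < 0.5,
    median_duration_days = ifelse(
      defined, stats::median(.data$duration_days[!.data$censored]), NA_real_),
    .groups = "drop"
  )[, c("cohort_id", "n_episodes", "n_censored", "median_duration_days",
        "defined")]
}
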