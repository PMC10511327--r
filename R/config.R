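#' Analysis configuration
#'
#' Bundles the tunable parameters of the episode engine and the summary
#' statistics. Defaults follow the conventions used throughout the package:
#' wasting below -2 z, severe wasting below -3 z, a 60-day washout both for
#' confirming recovery and for the return to at-risk person-time, recovery
#' horizons at 30/60/90 days, and a persistent-wasting rule of at least 50%
#' of measurements below the cutoff among children with four or more
#' measurements.
#'
#' @param wasting_cutoff z-score threshold below which a child is wasted.
#' @param severe_cutoff z-score threshold for severe wasting; must be below
#'   `wasting_cutoff`.
#' @param washout_days days a child must remain at or above the cutoff for an
#'   episode to count as recovered, and during which a recovered child does
#'   not yet contribute person-time at risk. Sensitivity values 30 and 90.
#' @param prevalence_window_months half-width, in months, of the measurement
#'   window around an age stratum used by cross-sectional statistics.
#' @param persistent_fraction minimum fraction of a child's measurements
#'   below the cutoff to classify the child as persistently wasted.
#' @param persistent_strict if `TRUE`, require strictly more than
#'   `persistent_fraction`; the default keeps a child exactly at the
#'   fraction (e.g. 3 of 6 measurements) classified as persistent.
#' @param min_measurements_persistent minimum number of non-missing WLZ
#'   measurements for a child to enter the persistent-wasting denominator.
#' @param recovery_horizons_days horizons (days since onset) at which
#'   recovery proportions are reported.
#' @param recovery_rule `"span"` (default) confirms recovery when the
#'   above-cutoff spell lasts at least `washout_days` before any relapse (a
#'   spell still above the cutoff when observation ends is taken as
#'   recovered); `"two_measurements"` additionally requires the
#'   above-cutoff run to contain at least two measurements.
#' @param rng_seed integer seed recorded alongside the configuration.
#'
#' @return A list of class `we_config`.
#' @examples
#' cfg <- analysis_config(washout_days = 30)
#' cfg$washout_days
#' @export
analysis_config <- function(wasting_cutoff = -2,
                            severe_cutoff = -3,
                            washout_days = 60,
                            prevalence_window_months = 1,
                            persistent_fraction = 0.5,
                            persistent_strict = FALSE,
                            min_measurements_persistent = 4L,
                            recovery_horizons_days = c(30, 60, 90),
                            recovery_rule = c("span", "two_measurements"),
                            rng_seed = 1L) {
  recovery_rule <- match.arg(recovery_rule)
  stopifnot(
    is.numeric(wasting_cutoff), is.numeric(severe_cutoff),
    severe_cutoff < wasting_cutoff, wasting_cutoff < 0,
    washout_days > 0,
    prevalence_window_months > 0,
    persistent_fraction > 0, persistent_fraction <= 1,
    min_measurements_persistent >= 1,
    all(recovery_horizons_days > 0)
  )
  structure(
    list(
      wasting_cutoff = wasting_cutoff,
      severe_cutoff = severe_cutoff,
      washout_days = washout_days,
      prevalence_window_months = prevalence_window_months,
      persistent_fraction = persistent_fraction,
      persistent_strict = isTRUE(persistent_strict),
      min_measurements_persistent = as.integer(min_measurements_persistent),
      recovery_horizons_days = sort(recovery_horizons_days),
      recovery_rule = recovery_rule,
      rng_seed = as.integer(rng_seed)
    ),
    class = "we_config"
  )
}

#' @export
print.we_config <- function(x, ...) {
  cat("<wasting analysis configuration>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Read an analysis configuration from a YAML file
#'
#' The file may contain any subset of the [analysis_config()] fields
#' (unknown keys are rejected); missing fields take their defaults.
#'
#' @param path path to a YAML key-value file.
#' @return A `we_config` list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading configuration files requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, raw)
}

cutoff_for <- function(cfg, condition = c("wasting", "severe_wasting")) {
  condition <- match.arg(condition)
  if (condition == "wasting") cfg$wasting_cutoff else cfg$severe_cutoff
}
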