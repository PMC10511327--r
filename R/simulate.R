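#' Simulation configuration for synthetic longitudinal cohorts
#'
#' Defines the data-generating process the synthetic cohorts follow:
#' monthly visits from enrollment to 24 months with day-level jitter, a
#' piecewise-linear mean z-score age curve, child-level random intercepts,
#' AR(1) within-child residuals with marginal standard deviations matching
#' the within-child variability typical of monthly anthropometry (0.76 WLZ,
#' 0.64 LAZ, 0.52 WAZ in total for the blended WAZ), a sinusoidal seasonal
#' term on WLZ with its trough in the peak-rainfall month, optional
#' birth-month WLZ offsets, geometric attrition, and optional injection of
#' implausible values for QC testing. WAZ is a fixed linear blend
#' `0.55*WLZ + 0.55*LAZ` plus bounded noise, so a child wasted and stunted
#' at a visit is always underweight at that visit.
#'
#' @param n_cohorts number of cohorts.
#' @param n_children children per cohort.
#' @param regions region labels recycled across cohorts.
#' @param enroll_age_months cohort enrollment age (0 = birth cohort),
#'   recycled; late-enrolled cohorts start their schedule at this month.
#' @param followup_months last scheduled visit month.
#' @param visit_jitter_days uniform day jitter applied to scheduled visits.
#' @param start_date,birth_span_days births are uniform over
#'   `[start_date, start_date + birth_span_days)`.
#' @param wlz_curve,laz_curve piecewise-linear control points
#'   (`list(months=, values=)`) for the mean age curves.
#' @param wlz_child_sd,laz_child_sd child random-intercept SDs.
#' @param wlz_resid_sd,laz_resid_sd marginal SDs of the AR(1) residuals.
#' @param ar1 AR(1) coefficient of the within-child residuals.
#' @param waz_blend coefficients of WLZ and LAZ in the WAZ blend.
#' @param waz_noise_sd,waz_noise_bound SD and truncation bound of the WAZ
#'   blend noise (the bound preserves the wasted-and-stunted implies
#'   underweight implication).
#' @param seasonal_amplitude amplitude (z) of the sinusoidal WLZ seasonal
#'   term; the term equals `-amplitude` in the peak-rain month.
#' @param rain_profile rainfall profile per cohort (recycled): `"uniform"`,
#'   `"single_peak"` or `"monsoon"`.
#' @param rain_peak_month peak month per cohort (recycled).
#' @param rain_concentration concentration of the single-peak profile.
#' @param birth_month_offsets length-12 WLZ offset by calendar month of
#'   birth.
#' @param attrition_hazard per-month probability of dropping out after each
#'   attended visit.
#' @param implausible_rate per-row probability of replacing WLZ with an
#'   implausible value (for QC tests).
#' @return A list of class `we_sim_config`.
#' @export
sim_config <- function(n_cohorts = 3,
                       n_children = 500,
                       regions = c("South Asia", "Africa", "Latin America"),
                       enroll_age_months = 0,
                       followup_months = 24,
                       visit_jitter_days = 3,
                       start_date = as.Date("2010-01-01"),
                       birth_span_days = 730,
                       wlz_curve = list(months = c(0, 3, 12, 24),
                                        values = c(-0.5, -0.25, -1.0, -0.85)),
                       laz_curve = list(months = c(0, 6, 24),
                                        values = c(-0.4, -0.9, -1.6)),
                       wlz_child_sd = 0.5,
                       laz_child_sd = 0.6,
                       wlz_resid_sd = 0.76,
                       laz_resid_sd = 0.64,
                       ar1 = 0.5,
                       waz_blend = c(0.55, 0.55),
                       waz_noise_sd = 0.15,
                       waz_noise_bound = 0.2,
                       seasonal_amplitude = 0.2,
                       rain_profile = "single_peak",
                       rain_peak_month = c(7, 8, 1),
                       rain_concentration = 1.5,
                       birth_month_offsets = rep(0, 12),
                       attrition_hazard = 0.02,
                       implausible_rate = 0) {
  cfg <- list(
    n_cohorts = as.integer(n_cohorts), n_children = as.integer(n_children),
    regions = rep_len(regions, n_cohorts),
    enroll_age_months = rep_len(enroll_age_months, n_cohorts),
    followup_months = followup_months,
    visit_jitter_days = visit_jitter_days,
    start_date = as.Date(start_date), birth_span_days = birth_span_days,
    wlz_curve = wlz_curve, laz_curve = laz_curve,
    wlz_child_sd = wlz_child_sd, laz_child_sd = laz_child_sd,
    wlz_resid_sd = wlz_resid_sd, laz_resid_sd = laz_resid_sd,
    ar1 = ar1, waz_blend = waz_blend, waz_noise_sd = waz_noise_sd,
    waz_noise_bound = waz_noise_bound,
    seasonal_amplitude = seasonal_amplitude,
    rain_profile = rep_len(rain_profile, n_cohorts),
    rain_peak_month = rep_len(rain_peak_month, n_cohorts),
    rain_concentration = rain_concentration,
    birth_month_offsets = birth_month_offsets,
    attrition_hazard = attrition_hazard,
    implausible_rate = implausible_rate
  )
  problems <- c(
    if (cfg$n_children < 1) "n_children must be >= 1",
    if (cfg$wlz_child_sd < 0 || cfg$laz_child_sd < 0) "child SDs must be >= 0",
    if (cfg$wlz_resid_sd <= 0 || cfg$laz_resid_sd <= 0) "residual SDs must be > 0",
    if (abs(cfg$ar1) >= 1) "ar1 must be in (-1, 1)",
    if (cfg$attrition_hazard < 0 || cfg$attrition_hazard >= 1)
      "attrition_hazard must be in [0, 1)",
    if (length(cfg$birth_month_offsets) != 12)
      "birth_month_offsets must have length 12",
    if (cfg$implausible_rate < 0 || cfg$implausible_rate > 1)
      "implausible_rate must be in [0, 1]"
  )
  if (length(problems)) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "we_sim_config")
}

piecewise_curve <- function(curve, age_months) {
  stats::approx(curve$months, curve$values, xout = age_months, rule = 2)$y
}

# sinusoidal seasonal term, evaluated on the calendar month: trough
# (-amplitude) in the peak-rain month
seasonal_term <- function(month, peak_month, amplitude) {
  -amplitude * cos(2 * pi * (month - peak_month) / 12)
}

#' Generate a monthly rainfall profile
#'
#' @param profile `"uniform"`, `"single_peak"` or `"monsoon"`.
#' @param peak_month calendar month of the rainfall peak.
#' @param concentration concentration of the single-peak profile (0 gives a
#'   uniform profile; larger values concentrate rain around the peak month
#'   and increase the seasonality index monotonically; `Inf` puts all rain
#'   in the peak month).
#' @param total_mm annual total.
#' @return Numeric vector of 12 monthly totals, January first.
#' @export
generate_rainfall <- function(profile = c("uniform", "single_peak", "monsoon"),
                              peak_month = 7, concentration = 1.5,
                              total_mm = 1200) {
  profile <- match.arg(profile)
  x <- switch(profile,
    uniform = rep(1, 12),
    single_peak = {
      if (is.infinite(concentration)) {
        v <- numeric(12); v[peak_month] <- 1; v
      } else {
        exp(concentration * cos(2 * pi * ((1:12) - peak_month) / 12))
      }
    },
    monsoon = {
      base <- c(5, 5, 10, 30, 80, 150, 250, 250, 150, 60, 20, 10)
      # rotate so the heaviest month lands on peak_month
      shift <- (peak_month - which.max(base)) %% 12
      base[((seq_len(12) - 1 - shift) %% 12) + 1]
    }
  )
  total_mm * x / sum(x)
}

#' Simulate multi-cohort longitudinal anthropometry with known truth
#'
#' Draws synthetic cohorts from the process described in [sim_config()] and
#' returns the measurement table, a per-visit truth table (wasted /
#' severely wasted / stunted / underweight status obtained by thresholding
#' the emitted z-scores, plus the dropout age), and the per-cohort rainfall
#' table. Identical seed and configuration give identical output.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A list: `measurements` (a `we_measurements` tibble), `truth`
#'   (per-visit statuses and `lost_after_age_days`), `rainfall`
#'   (`cohort_id`, `month`, `rain_mm`), `config`.
#' @examples
#' sim <- simulate_cohorts(sim_config(n_cohorts = 1, n_children = 20), seed = 7)
#' nrow(sim$measurements)
#' @export
simulate_cohorts <- function(cfg = sim_config(), seed = 1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  meas <- list()
  truth <- list()
  rainfall <- list()
  for (ci in seq_len(cfg$n_cohorts)) {
    cohort_id <- sprintf("cohort_%02d", ci)
    rain <- generate_rainfall(cfg$rain_profile[ci],
                              peak_month = cfg$rain_peak_month[ci],
                              concentration = cfg$rain_concentration)
    rainfall[[ci]] <- tibble::tibble(cohort_id = cohort_id, month = 1:12,
                                     rain_mm = rain)
    g <- simulate_one_cohort(cfg, ci, cohort_id)
    meas[[ci]] <- g$meas
    truth[[ci]] <- g$truth
  }
  measurements <- as_measurements(dplyr::bind_rows(meas))
  truth <- dplyr::bind_rows(truth)
  meta <- tibble::tibble(
    cohort_id = sprintf("cohort_%02d", seq_len(cfg$n_cohorts)),
    region = cfg$regions,
    enroll_age_months = cfg$enroll_age_months,
    rain_peak_month = cfg$rain_peak_month
  )
  list(measurements = measurements, truth = truth,
       rainfall = dplyr::bind_rows(rainfall), cohort_meta = meta,
       config = cfg)
}

simulate_one_cohort <- function(cfg, ci, cohort_id) {
  n <- cfg$n_children
  months <- seq(cfg$enroll_age_months[ci], cfg$followup_months)
  T <- length(months)
  birth_date <- cfg$start_date + floor(stats::runif(n, 0, cfg$birth_span_days))
  birth_month <- as.integer(format(birth_date, "%m"))
  sex <- sample(c("male", "female"), n, replace = TRUE)

  # visit ages (days): monthly schedule with jitter; the first visit of a
  # birth cohort is the birth measure, within a few days of birth
  sched <- round(months * DAYS_PER_MONTH)
  jit <- matrix(round(stats::runif(n * T, -cfg$visit_jitter_days,
                                   cfg$visit_jitter_days)), n, T)
  age <- sweep(jit, 2, sched, "+")
  if (months[1] == 0) age[, 1] <- sample(0:3, n, replace = TRUE)
  age[age < 0] <- 0
  # enforce strictly increasing ages per child
  for (j in 2:T) {
    bad <- age[, j] <= age[, j - 1]
    age[bad, j] <- age[bad, j - 1] + 1
  }

  # attrition: geometric number of attended visits
  attended <- if (cfg$attrition_hazard > 0) {
    pmin(1L + stats::rgeom(n, cfg$attrition_hazard), T)
  } else rep(T, n)

  b_w <- stats::rnorm(n, 0, cfg$wlz_child_sd)
  b_l <- stats::rnorm(n, 0, cfg$laz_child_sd)
  e_w <- ar1_matrix(n, T, cfg$ar1, cfg$wlz_resid_sd)
  e_l <- ar1_matrix(n, T, cfg$ar1, cfg$laz_resid_sd)

  date <- matrix(rep(birth_date, T), n, T) + age
  vis_month <- matrix(as.integer(format(as.Date(as.vector(date),
                                                origin = "1970-01-01"),
                                        "%m")), n, T)
  mu_w <- matrix(piecewise_curve(cfg$wlz_curve, as.vector(age) / DAYS_PER_MONTH),
                 n, T)
  mu_l <- matrix(piecewise_curve(cfg$laz_curve, as.vector(age) / DAYS_PER_MONTH),
                 n, T)
  seas <- seasonal_term(vis_month, cfg$rain_peak_month[ci],
                        cfg$seasonal_amplitude)
  bm_off <- cfg$birth_month_offsets[birth_month]

  wlz <- mu_w + seas + bm_off + b_w + e_w
  laz <- mu_l + b_l + e_l
  noise <- matrix(rtrunc_norm(n * T, cfg$waz_noise_sd, cfg$waz_noise_bound),
                  n, T)
  waz <- cfg$waz_blend[1] * wlz + cfg$waz_blend[2] * laz + noise

  keep <- col(age) <= attended[row(age)]
  injected <- matrix(FALSE, n, T)
  if (cfg$implausible_rate > 0) {
    injected <- matrix(stats::runif(n * T) < cfg$implausible_rate, n, T) & keep
    wlz[injected] <- sample(c(-1, 1), sum(injected), replace = TRUE) *
      stats::runif(sum(injected), 5.5, 7)
  }

  child_id <- sprintf("%s_c%04d", cohort_id, seq_len(n))
  idx <- which(keep)
  meas <- tibble::tibble(
    cohort_id = cohort_id,
    child_id = child_id[row(age)[idx]],
    sex = sex[row(age)[idx]],
    age_days = as.integer(age[idx]),
    date = as.Date(as.vector(date)[idx], origin = "1970-01-01"),
    wlz = wlz[idx], laz = laz[idx], waz = waz[idx]
  )
  truth <- tibble::tibble(
    cohort_id = cohort_id,
    child_id = child_id[row(age)[idx]],
    age_days = as.integer(age[idx]),
    true_wasted = wlz[idx] < -2,
    true_severe_wasted = wlz[idx] < -3,
    true_stunted = laz[idx] < -2,
    true_underweight = waz[idx] < -2,
    injected_implausible = injected[idx],
    lost_after_age_days = vapply(row(age)[idx], function(i) {
      as.numeric(age[i, attended[i]])
    }, numeric(1))
  )
  list(meas = meas, truth = truth)
}

# stationary AR(1) rows: marginal SD = sd, lag-1 correlation = rho
ar1_matrix <- function(n, T, rho, sd) {
  e <- matrix(0, n, T)
  e[, 1] <- stats::rnorm(n, 0, sd)
  if (T > 1) {
    for (j in 2:T) {
      e[, j] <- rho * e[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(n, 0, sd)
    }
  }
  e
}

# mean-zero normal noise truncated to [-bound, bound] (rejection sampling)
rtrunc_norm <- function(n, sd, bound) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > bound
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > bound
  }
  x
}

#' Build a deterministic measurement fixture from a blueprint
#'
#' Passes an explicit per-child list of (age, z-score) pairs straight into
#' the canonical measurement format, for unit tests and worked examples.
#'
#' @param blueprint data frame with `child_id`, `age_days`, `wlz` and
#'   optionally `laz`, `waz`, `cohort_id`, `date`, `sex`; ages must be
#'   strictly increasing within each child.
#' @return A `we_measurements` tibble (header-only when the blueprint is
#'   empty).
#' @examples
#' generate_fixture(data.frame(child_id = "k1", age_days = c(40, 70),
#'                             wlz = c(-1.5, -2.5)))
#' @export
generate_fixture <- function(blueprint) {
  bp <- tibble::as_tibble(blueprint)
  if (!nrow(bp)) {
    return(as_measurements(tibble::tibble(
      cohort_id = character(), child_id = character(), age_days = integer(),
      wlz = numeric())))
  }
  stopifnot(all(c("child_id", "age_days") %in% names(bp)))
  if (!"cohort_id" %in% names(bp)) bp$cohort_id <- "fixture"
  inc <- tapply(bp$age_days, paste(bp$cohort_id, bp$child_id, sep = "\r"),
                function(a) all(diff(a) > 0))
  if (!all(inc)) stop("blueprint ages must be strictly increasing per child")
  as_measurements(bp)
}
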