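# Independent brute-force oracle for episode classification.
#
# Replays the threshold/washout rules literally on a half-day grid: each
# grid time takes the wasting status of the nearest measurement (ties to
# the later one, so the latent status switches exactly at the midpoint
# between measurements of opposite status), below-cutoff runs are merged
# across above-cutoff spells shorter than the washout, and a trailing
# above-cutoff spell counts as recovery. Kept deliberately separate from
# the package's run-length-encoding classifier.
oracle_episodes <- function(age_days, wlz, cutoff = -2, washout = 60) {
  keep <- !is.na(wlz)
  age <- age_days[keep]
  z <- wlz[keep]
  empty <- data.frame(onset_age_days = numeric(0), onset_kind = character(0),
                      recovery_age_days = numeric(0), censored = logical(0),
                      duration_days = numeric(0))
  n <- length(age)
  if (n == 0 || !any(z < cutoff)) return(empty)

  grid <- seq(age[1], age[n], by = 0.5)
  mids <- if (n > 1) (age[-1] + age[-n]) / 2 else numeric(0)
  nearest <- findInterval(grid, mids) + 1L   # tie at a midpoint -> later
  below <- z[nearest] < cutoff

  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  run <- data.frame(below = r$values,
                    t_start = grid[starts],
                    t_end = grid[ends] + 0.5)
  run$t_end[nrow(run)] <- age[n]

  K <- nrow(run)
  episodes <- empty
  k <- if (run$below[1]) 1L else 2L
  while (k <= K) {
    onset_run <- k
    while (k + 1L < K && !run$below[k + 1L] &&
           (run$t_end[k + 1L] - run$t_start[k + 1L]) < washout) {
      k <- k + 2L
    }
    if (onset_run == 1L) {
      if (age[1] <= 7) {
        onset <- age[1]; kind <- "at_birth"
      } else {
        onset <- age[1] / 2; kind <- "at_enrollment"
      }
    } else {
      onset <- run$t_start[onset_run]; kind <- "interval"
    }
    if (k == K) {
      rec <- NA_real_; cens <- TRUE
    } else {
      rec <- run$t_end[k]; cens <- FALSE
    }
    episodes <- rbind(episodes, data.frame(
      onset_age_days = onset, onset_kind = kind, recovery_age_days = rec,
      censored = cens,
      duration_days = if (cens) NA_real_ else rec - onset))
    if (cens) break
    k <- k + 2L
  }
  episodes
}

# random z-score series for property tests: monthly-ish spacing, mean near
# the wasting cutoff so crossings are common, occasional missing values
random_series <- function(n_max = 30) {
  n <- sample(2:n_max, 1)
  start <- sample(c(0:5, 20:120), 1)
  age <- start + cumsum(c(0, sample(15:45, n - 1, replace = TRUE)))
  z <- rnorm(n, mean = -1.7, sd = 0.9)
  z[runif(n) < 0.08] <- NA
  if (all(is.na(z))) z[1] <- -1
  data.frame(age_days = age, wlz = z)
}

expect_episodes_equal <- function(got, want, info = NULL) {
  testthat::expect_equal(nrow(got), nrow(want), info = info)
  if (nrow(want) == 0) return(invisible(TRUE))
  testthat::expect_equal(got$onset_age_days, want$onset_age_days,
                         tolerance = 1e-9, info = info)
  testthat::expect_equal(got$onset_kind, want$onset_kind, info = info)
  testthat::expect_equal(got$censored, want$censored, info = info)
  testthat::expect_equal(got$recovery_age_days, want$recovery_age_days,
                         tolerance = 1e-9, info = info)
  testthat::expect_equal(got$duration_days, want$duration_days,
                         tolerance = 1e-9, info = info)
  invisible(TRUE)
}

# worked-example series used across tests: not wasted at 40 d, wasted at
# 70 d, recovered by 100 d with a confirming measurement at 130 d
worked_example_fixture <- function() {
  generate_fixture(data.frame(
    child_id = "k1",
    age_days = c(40, 70, 100, 130),
    wlz = c(-1.5, -2.5, -1.5, -1.5)
  ))
}
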