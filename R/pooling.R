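#' Pool cohort-specific estimates (two-stage meta-analysis)
#'
#' Second stage of the two-stage individual-participant meta-analysis:
#' cohort estimates with standard errors are pooled with a random-effects
#' model (restricted maximum likelihood for the between-cohort variance
#' tau^2, DerSimonian-Laird on non-convergence) or, as a sensitivity
#' analysis, a fixed-effects inverse-variance model. Heterogeneity is
#' reported as I^2 = max(0, (Q - df)/Q) x 100.
#'
#' Proportions are pooled on the logit scale by default and back-transformed
#' (delta-method standard errors); `scale = "linear"` pools on the raw
#' scale. Boundary estimates (0 or 1) are nudged by half an event when `n`
#' is supplied, so their logit is finite.
#'
#' @param estimates a data frame with columns `estimate` and `se` (one row
#'   per cohort); optional columns `cohort_id` and `n` (denominator, used
#'   only for boundary handling on the logit scale).
#' @param method `"random_reml"` (default), `"random_dl"` or `"fixed"`.
#' @param scale `"logit"` for proportions, `"linear"` otherwise.
#' @param conf_level confidence level.
#' @return A one-row tibble: `estimate`, `ci_lo`, `ci_hi`, `tau2`, `i2`,
#'   `method`, `scale`, `n_cohorts`, `passthrough` (TRUE when a single
#'   cohort was returned unpooled).
#' @examples
#' est <- data.frame(estimate = c(0.10, 0.14, 0.12), se = c(0.01, 0.02, 0.015))
#' pool_estimates(est, method = "fixed", scale = "linear")
#' @export
pool_estimates <- function(estimates,
                           method = c("random_reml", "random_dl", "fixed"),
                           scale = c("logit", "linear"),
                           conf_level = 0.95) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  est <- tibble::as_tibble(estimates)
  stopifnot(all(c("estimate", "se") %in% names(est)))
  keep <- is.finite(est$estimate) & is.finite(est$se) & est$se >= 0
  if (any(!keep)) {
    warning(sum(!keep), " cohort(s) dropped for non-finite estimate or SE")
    est <- est[keep, , drop = FALSE]
  }
  if (!nrow(est)) stop("no cohorts with finite estimates to pool")

  if (scale == "logit") {
    p <- est$estimate
    if (any(p < 0 | p > 1)) stop("logit-scale pooling requires proportions in [0, 1]")
    boundary <- p == 0 | p == 1
    if (any(boundary)) {
      if (!"n" %in% names(est)) {
        stop("boundary proportions (0 or 1) need an 'n' column for logit pooling")
      }
      nb <- est$n[boundary]
      p[boundary] <- (p[boundary] * nb + 0.5) / (nb + 1)
      est$se[boundary] <- sqrt(p[boundary] * (1 - p[boundary]) / nb)
    }
    yi <- stats::qlogis(p)
    sei <- est$se / (p * (1 - p))      # delta method
    back <- stats::plogis
  } else {
    yi <- est$estimate
    sei <- est$se
    back <- identity
  }

  if (nrow(est) == 1) {
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    return(tibble::tibble(
      estimate = back(yi), ci_lo = back(yi - zq * sei),
      ci_hi = back(yi + zq * sei), tau2 = 0, i2 = 0,
      method = method, scale = scale, n_cohorts = 1L, passthrough = TRUE
    ))
  }

  mf_method <- switch(method, random_reml = "REML", random_dl = "DL",
                      fixed = "FE")
  fit <- tryCatch(
    metafor::rma(yi = yi, sei = sei, method = mf_method,
                 level = conf_level * 100),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) && method == "random_reml") {
    fit <- metafor::rma(yi = yi, sei = sei, method = "DL",
                        level = conf_level * 100)
    method <- "random_dl"
  }
  if (is.null(fit)) {
    fit <- metafor::rma(yi = yi, sei = sei, method = mf_method,
                        level = conf_level * 100)
  }
  tibble::tibble(
    estimate = back(as.numeric(fit$beta)),
    ci_lo = back(fit$ci.lb),
    ci_hi = back(fit$ci.ub),
    tau2 = if (mf_method == "FE") 0 else as.numeric(fit$tau2),
    i2 = as.numeric(fit$I2),
    method = method, scale = scale,
    n_cohorts = nrow(est), passthrough = FALSE
  )
}

#' Pool per-cohort medians by the unweighted median of medians
#'
#' @param cohort_medians numeric vector of cohort medians; NA (undefined)
#'   entries are excluded before pooling.
#' @return The plain median of the finite cohort medians.
#' @examples
#' pool_median_of_medians(c(35, 42, 60))  # 42
#' @export
pool_median_of_medians <- function(cohort_medians) {
  x <- cohort_medians[is.finite(cohort_medians)]
  if (!length(x)) stop("no finite cohort medians to pool")
  stats::median(x)
}

#' Pool a table of per-cohort estimates stratum by stratum
#'
#' Convenience wrapper around [pool_estimates()] for the per-cohort tables
#' produced by the summary operations: pools within each combination of the
#' given stratum columns, omitting cohorts with no eligible children in a
#' stratum.
#'
#' @param per_cohort a per-cohort table with `estimate` and `se` columns.
#' @param strata character vector of stratum column names (e.g.
#'   `"age_target_months"`).
#' @inheritParams pool_estimates
#' @return One row per stratum with the [pool_estimates()] columns.
#' @export
pool_by_stratum <- function(per_cohort, strata,
                            method = "random_reml", scale = "logit",
                            conf_level = 0.95) {
  df <- tibble::as_tibble(per_cohort)
  if ("undefined" %in% names(df)) df <- df[!df$undefined, , drop = FALSE]
  df <- df[is.finite(df$estimate), , drop = FALSE]
  keys <- df[, strata, drop = FALSE]
  split_idx <- split(seq_len(nrow(df)), keys, drop = TRUE)
  out <- lapply(split_idx, function(idx) {
    res <- pool_estimates(df[idx, , drop = FALSE], method = method,
                          scale = scale, conf_level = conf_level)
    dplyr::bind_cols(df[idx[1], strata, drop = FALSE], res)
  })
  dplyr::bind_rows(out)
}
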