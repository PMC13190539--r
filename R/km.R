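#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] into a tidy step-function curve. Ties between
#' deaths and censorings at the same time follow the standard convention
#' (deaths precede censorings in the risk set). The median is the smallest
#' observed time with `S(t) <= 0.5`, `NA` if the curve never reaches 0.5.
#'
#' @param times Positive observation times (months).
#' @param events Event indicators (1 death, 0 censored).
#' @param group Optional label attached to the curve.
#' @return An object of class `km_curve`: `steps` (tibble: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`), `median`, `n`, `n_events`,
#'   `max_time`, `group`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))$median
km_estimate <- function(times, events, group = NULL) {
  if (length(times) < 1 || any(times <= 0)) {
    abort("times must be positive and non-empty.", class = "methtier_input_error")
  }
  sf <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  steps <- tibble::tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, survival = sf$surv
  )
  med <- steps$time[steps$survival <= 0.5][1]
  out <- list(steps = steps, median = if (is.na(med)) NA_real_ else med,
              n = length(times), n_events = sum(events),
              max_time = max(times), group = group)
  class(out) <- "km_curve"
  out
}

#' Survival probabilities at fixed horizons
#'
#' Reads the right-continuous Kaplan-Meier step function at the requested
#' horizons. Horizons beyond the last observed time carry the last estimate
#' forward with an `extrapolated` flag.
#'
#' @param curve A [km_estimate()] curve.
#' @param horizons Positive horizons in months.
#' @return Tibble with `horizon`, `survival`, `extrapolated`.
#' @export
survival_rates <- function(curve, horizons) {
  if (any(horizons < 0)) {
    abort("Horizons must be non-negative.", class = "methtier_input_error")
  }
  s <- vapply(horizons, function(h) {
    past <- curve$steps$survival[curve$steps$time <= h]
    if (length(past) == 0) 1.0 else past[length(past)]
  }, numeric(1))
  tibble::tibble(horizon = horizons, survival = s,
                 extrapolated = horizons > curve$max_time)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison via [survival::survdiff()]: at every distinct
#' event time the expected events per group come from the hypergeometric
#' mean, the statistic is `(O - E)^2 / V` with `V` the summed hypergeometric
#' variances, and the p-value is the chi-square(1) upper tail.
#'
#' @param times_a,events_a Times and event indicators of group A.
#' @param times_b,events_b Times and event indicators of group B.
#' @return A list of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    abort("Both groups must be non-empty.", class = "methtier_input_error")
  }
  if (sum(events_a) + sum(events_b) == 0) {
    abort("Log-rank test needs at least one event.",
          class = "methtier_degenerate_test")
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi <- unname(sd_fit$chisq)
  if (!is.finite(chi)) {
    abort("Degenerate log-rank comparison (zero variance of the observed-minus-expected statistic).",
          class = "methtier_degenerate_test")
  }
  out <- list(chi_square = chi, df = 1L,
              p_value = pchisq(chi, df = 1, lower.tail = FALSE),
              observed = unname(sd_fit$obs), expected = unname(sd_fit$exp))
  class(out) <- "logrank_result"
  out
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (df = 1), p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Survival description of the three methylation tiers
#'
#' Classifies the cohort with the three-tier rule and returns per-tier
#' Kaplan-Meier curves, medians, fixed-horizon survival rates, and all
#' pairwise log-rank tests among non-empty tiers (unadjusted p-values; a
#' Bonferroni column is available via `adjust`).
#'
#' @param cohort Validated cohort tibble.
#' @param rule A [derive_three_tier()] rule.
#' @param horizons Months at which survival rates are evaluated.
#' @param adjust If `TRUE`, adds Bonferroni-adjusted p-values.
#' @return A list of class `tier_survival_report`: `tiers` (tibble: `tier`,
#'   `n`, `n_events`, `median_os`), `curves` (named list of `km_curve`),
#'   `rates` (tibble: `tier`, `horizon`, `survival`, `extrapolated`),
#'   `tests` (tibble of pairwise log-rank results), `rule`.
#' @export
three_tier_survival_report <- function(cohort, rule, horizons = c(12, 24, 60),
                                       adjust = FALSE) {
  assert_nonempty_cohort(cohort, "three_tier_survival_report")
  tier <- classify_three_tier(cohort$mean_meth, rule)
  lv <- levels(tier)
  present <- lv[lv %in% unique(as.character(tier))]
  curves <- lapply(present, function(g) {
    sel <- tier == g
    km_estimate(cohort$os_months[sel], cohort$event[sel], group = g)
  })
  names(curves) <- present
  tier_counts <- as.integer(table(tier))
  tier_events <- vapply(lv, function(g) sum(cohort$event[tier == g]), numeric(1))
  tiers <- tibble::tibble(
    tier = factor(lv, levels = lv),
    n = tier_counts,
    n_events = unname(tier_events),
    median_os = vapply(lv, function(g)
      if (g %in% present) curves[[g]]$median else NA_real_, numeric(1))
  )
  rates <- purrr::map_dfr(present, function(g) {
    dplyr::mutate(survival_rates(curves[[g]], horizons), tier = g,
                  .before = 1)
  })
  tests <- NULL
  if (length(present) >= 2) {
    pairs <- utils::combn(present, 2, simplify = FALSE)
    tests <- purrr::map_dfr(pairs, function(pr) {
      a <- tier == pr[1]; b <- tier == pr[2]
      lr <- logrank_test(cohort$os_months[a], cohort$event[a],
                         cohort$os_months[b], cohort$event[b])
      tibble::tibble(group_a = pr[1], group_b = pr[2],
                     chi_square = lr$chi_square, p_value = lr$p_value)
    })
    if (adjust) tests$p_bonferroni <- pmin(1, tests$p_value * nrow(tests))
  } else {
    warn("Fewer than two non-empty tiers: no pairwise survival comparisons.")
  }
  out <- list(tiers = tiers, curves = curves, rates = rates, tests = tests,
              rule = rule)
  class(out) <- "tier_survival_report"
  out
}

#' @export
print.tier_survival_report <- function(x, ...) {
  print(x$rule)
  print(x$tiers)
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}

#' @rdname km_estimate
#' @param x A `km_curve` object.
#' @param ... Unused.
#' @export
tidy.km_curve <- function(x, ...) {
  dplyr::mutate(x$steps, group = x$group %||% NA_character_)
}

#' @rdname km_estimate
#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, median = x$median,
                 max_time = x$max_time)
}
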