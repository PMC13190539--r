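#' Cross-validation folds stratified by event status
#'
#' Assigns each patient to one of `n_folds` folds by seeded random shuffling
#' within deaths and within censored patients separately, so every training
#' split contains events.
#'
#' @param event Event indicator vector.
#' @param n_folds Number of folds.
#' @param cv_seed Seed for the fold assignment.
#' @return Integer vector of fold ids in 1..n_folds.
#' @export
make_cv_folds <- function(event, n_folds = 5, cv_seed = 1L) {
  n <- length(event)
  folds <- integer(n)
  with_local_seed(cv_seed, {
    for (g in unique(event)) {
      idx <- which(event == g)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

#' Survival-informed threshold scan
#'
#' Scans candidate integer methylation cut-offs (default 1..25%), refitting
#' the adjusted log-logistic AFT model under `n_folds`-fold cross-validation
#' at each candidate and scoring by the out-of-fold concordance index. The
#' fold assignment is formed once (stratified by event status) and shared
#' across all candidates. A candidate whose dichotomy is all one class in any
#' training fold is recorded as invalid and excluded from selection. The
#' selected cut-off attains the maximal mean out-of-fold C; ties break toward
#' the lowest candidate (the conservative direction: a lower "unmethylated"
#' threshold withholds the methylated label from fewer patients).
#'
#' @param cohort Validated cohort tibble.
#' @param marker Methylation column to dichotomize (`value > cutoff` =
#'   methylated, so the selected `c` has the "unmethylated = value <= c"
#'   reading).
#' @param candidates Integer candidate cut-offs in percent.
#' @param n_folds Number of CV folds.
#' @param cv_seed Seed for the fold assignment.
#' @param score `"fold_mean"` (mean of per-fold C, default) or `"pooled"`
#'   (C on pooled out-of-fold predictions).
#' @param folds Optional precomputed fold assignment (shared across markers).
#' @return An object of class `threshold_scan`: `scan` (tibble: `candidate`,
#'   `n_methylated`, `c_mean`, `c_pooled`, `valid`, `c_folds` list-column),
#'   `selected_cutoff`, `selected_c`, `folds`, `cv_seed`, `n_folds`,
#'   `marker`, `score`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n = 300, seed = 11))
#' scan <- scan_thresholds(sim$cohort, cv_seed = 1)
#' scan$selected_cutoff
scan_thresholds <- function(cohort, marker = "mean_meth", candidates = 1:25,
                            n_folds = 5, cv_seed = 1L,
                            score = c("fold_mean", "pooled"), folds = NULL) {
  score <- match.arg(score)
  assert_nonempty_cohort(cohort, "scan_thresholds")
  if (!marker %in% names(cohort)) {
    abort(paste0("Marker column not found: ", marker),
          class = "methtier_design_error")
  }
  if (sum(cohort$event) < n_folds) {
    abort(paste0("Threshold scan needs at least ", n_folds, " events."),
          class = "methtier_insufficient_events")
  }
  if (is.null(folds)) folds <- make_cv_folds(cohort$event, n_folds, cv_seed)
  base <- aft_design(cohort, cutoff = NULL)  # covariates without methylation
  values <- as.numeric(cohort[[marker]])
  time <- base$time; event <- base$event

  rows <- purrr::map(candidates, function(cand) {
    meth <- as.numeric(values > cand)
    x <- cbind(`(Intercept)` = 1, methylated = meth,
               base$x[, -1, drop = FALSE])
    degenerate <- any(vapply(seq_len(n_folds), function(k) {
      tr <- meth[folds != k]
      length(unique(tr)) < 2
    }, logical(1)))
    if (degenerate) {
      return(tibble::tibble(candidate = cand, n_methylated = sum(meth),
                            c_mean = NA_real_, c_pooled = NA_real_,
                            valid = FALSE, c_folds = list(rep(NA_real_, n_folds))))
    }
    eta_oof <- numeric(length(time))
    c_folds <- vapply(seq_len(n_folds), function(k) {
      tr <- folds != k
      keep <- c(TRUE, apply(x[tr, -1, drop = FALSE], 2,
                            function(col) length(unique(col)) > 1))
      fit <- fit_loglogistic(time[tr], event[tr], x[tr, keep, drop = FALSE])
      eta <- drop(x[!tr, keep, drop = FALSE] %*% fit$beta)
      eta_oof[!tr] <<- eta
      concordance_index(time[!tr], event[!tr], eta)$c_index
    }, numeric(1))
    tibble::tibble(candidate = cand, n_methylated = sum(meth),
                   c_mean = mean(c_folds),
                   c_pooled = concordance_index(time, event, eta_oof)$c_index,
                   valid = TRUE, c_folds = list(c_folds))
  }) |> dplyr::bind_rows()

  if (!any(rows$valid)) {
    abort("No valid candidate cut-off: every candidate produced a one-class dichotomy in some training fold.",
          class = "methtier_no_valid_threshold")
  }
  score_col <- if (score == "fold_mean") rows$c_mean else rows$c_pooled
  valid_idx <- which(rows$valid)
  sel <- valid_idx[which.max(score_col[valid_idx])]
  out <- list(scan = rows,
              selected_cutoff = rows$candidate[sel],
              selected_c = score_col[sel],
              folds = folds, cv_seed = cv_seed, n_folds = n_folds,
              marker = marker, score = score)
  class(out) <- "threshold_scan"
  out
}

#' Supervised cut-off estimate from a threshold scan
#'
#' @param scan A [scan_thresholds()] result.
#' @return A `meth_cutoff` object with `method = "supervised"`.
#' @export
supervised_cutoff <- function(scan) {
  out <- list(value_pct = as.numeric(scan$selected_cutoff),
              value_pct_rounded = as.integer(scan$selected_cutoff),
              log_value = log(scan$selected_cutoff),
              method = "supervised",
              diagnostics = scan)
  class(out) <- "meth_cutoff"
  out
}

#' Compare the CpG mean against each individual CpG
#'
#' Runs the threshold scan for `mean_meth` and for each of `cpg76..cpg79`
#' with one shared fold assignment, and reports each marker's best
#' cross-validated concordance index and its difference from the mean-marker
#' C in percentage points.
#'
#' @inheritParams scan_thresholds
#' @return An object of class `cpg_comparison`: `comparison` (tibble:
#'   `marker`, `selected_cutoff`, `best_c`, `diff_pp`), `folds`, `scans`.
#' @export
compare_markers <- function(cohort, cv_seed = 1L, candidates = 1:25,
                            n_folds = 5, score = c("fold_mean", "pooled")) {
  score <- match.arg(score)
  require_cpg_columns(cohort)
  folds <- make_cv_folds(cohort$event, n_folds, cv_seed)
  markers <- c("mean_meth", .cpg_cols)
  scans <- purrr::map(markers, function(m) {
    scan_thresholds(cohort, marker = m, candidates = candidates,
                    n_folds = n_folds, cv_seed = cv_seed, score = score,
                    folds = folds)
  })
  names(scans) <- markers
  best <- vapply(scans, function(s) s$selected_c, numeric(1))
  comparison <- tibble::tibble(
    marker = markers,
    selected_cutoff = vapply(scans, function(s) s$selected_cutoff, numeric(1)),
    best_c = unname(best),
    diff_pp = 100 * (unname(best) - best[["mean_meth"]])
  )
  out <- list(comparison = comparison, folds = folds, scans = scans)
  class(out) <- "cpg_comparison"
  out
}

#' Three-tier classification rule from the two cut-offs
#'
#' Combines the supervised (lower) and unsupervised (upper) cut-offs into the
#' three-tier rule: unmethylated when `mean_meth <= lower`, methylated when
#' `mean_meth >= upper`, gray zone strictly in between. If the supervised
#' cut-off is not below the unsupervised one the gray zone is empty and the
#' rule collapses to the single unsupervised threshold (with a notice).
#'
#' @param unsupervised Upper cut-off: a `meth_cutoff` or a number (percent);
#'   for a mixture-derived estimate the half-up-rounded integer is used.
#' @param supervised Lower cut-off: a `meth_cutoff` or a number (percent).
#' @return An object of class `three_tier_rule`: `lower`, `upper`,
#'   `collapsed`.
#' @export
derive_three_tier <- function(unsupervised, supervised) {
  as_cut <- function(x) {
    if (inherits(x, "meth_cutoff")) x$value_pct_rounded else as.numeric(x)
  }
  upper <- as_cut(unsupervised)
  lower <- as_cut(supervised)
  collapsed <- lower >= upper
  if (collapsed) {
    inform(sprintf("Supervised cut-off (%g) is not below the unsupervised cut-off (%g): empty gray zone, collapsing to a single threshold at %g.",
                   lower, upper, upper))
  }
  out <- list(lower = lower, upper = upper, collapsed = collapsed)
  class(out) <- "three_tier_rule"
  out
}

#' Classify methylation values under a three-tier rule
#'
#' @param values Methylation percentages.
#' @param rule A [derive_three_tier()] rule.
#' @return Factor with levels `unmethylated`, `gray_zone`, `methylated`;
#'   every value maps to exactly one tier.
#' @export
classify_three_tier <- function(values, rule) {
  values <- as.numeric(values)
  tier <- if (rule$collapsed) {
    ifelse(values >= rule$upper, "methylated", "unmethylated")
  } else {
    dplyr::case_when(
      values <= rule$lower ~ "unmethylated",
      values >= rule$upper ~ "methylated",
      .default = "gray_zone"
    )
  }
  factor(tier, levels = c("unmethylated", "gray_zone", "methylated"))
}

#' @export
print.three_tier_rule <- function(x, ...) {
  if (x$collapsed) {
    cat(sprintf("Two-tier rule (collapsed gray zone): methylated at >= %g%%\n", x$upper))
  } else {
    cat(sprintf("Three-tier rule: unmethylated <= %g%%, gray zone (%g, %g)%%, methylated >= %g%%\n",
                x$lower, x$lower, x$upper, x$upper))
  }
  invisible(x)
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Threshold scan on %s (%d candidates, %d-fold CV, seed %d)\n",
              x$marker, nrow(x$scan), x$n_folds, x$cv_seed))
  cat(sprintf("Selected cut-off: %d%% (mean out-of-fold C = %.4f)\n",
              x$selected_cutoff, x$selected_c))
  invisible(x)
}

#' @rdname scan_thresholds
#' @param x A `threshold_scan` object.
#' @param ... Unused.
#' @export
tidy.threshold_scan <- function(x, ...) {
  dplyr::select(x$scan, -"c_folds")
}

#' @rdname scan_thresholds
#' @export
glance.threshold_scan <- function(x, ...) {
  tibble::tibble(selected_cutoff = x$selected_cutoff, selected_c = x$selected_c,
                 n_valid = sum(x$scan$valid), n_folds = x$n_folds,
                 cv_seed = x$cv_seed, marker = x$marker, score = x$score)
}

#' @rdname compare_markers
#' @param x A `cpg_comparison` object.
#' @param ... Unused.
#' @export
tidy.cpg_comparison <- function(x, ...) x$comparison
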