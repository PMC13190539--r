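#' Overlap between the mixture labelling and the supervised cut-off
#'
#' Among patients assigned to the methylated mixture component (posterior
#' probability above 0.5 under the fitted mixture), the fraction whose mean
#' methylation exceeds the supervised lower cut-off, i.e. who are not
#' labelled truly unmethylated by the supervised rule. The complement
#' direction — the fraction of supervised non-unmethylated patients that the
#' mixture assigns to the methylated component — is reported alongside, as
#' either reading of "identified by" may be wanted.
#'
#' @param cohort Validated cohort tibble.
#' @param fit A [fit_bnmm()] object for `mean_meth`.
#' @param rule A [derive_three_tier()] rule (its `lower` cut-off is used).
#' @return A list: `bnmm_captured_by_supervised`,
#'   `supervised_captured_by_bnmm`, `n_bnmm_methylated`,
#'   `n_above_supervised`.
#' @export
overlap_statistic <- function(cohort, fit, rule) {
  post <- posterior_methylated(fit, cohort$mean_meth)
  bnmm_meth <- post > 0.5
  above <- cohort$mean_meth > rule$lower
  if (!any(bnmm_meth)) {
    abort("No patient is assigned to the methylated mixture component; the overlap statistic is undefined.",
          class = "methtier_undefined_statistic")
  }
  list(
    bnmm_captured_by_supervised = mean(above[bnmm_meth]),
    supervised_captured_by_bnmm = if (any(above)) mean(bnmm_meth[above]) else NA_real_,
    n_bnmm_methylated = sum(bnmm_meth),
    n_above_supervised = sum(above)
  )
}

#' Run the full three-tier cut-off pipeline
#'
#' End-to-end orchestration: load or simulate a cohort, fit the log-scale
#' normal mixture and take its intersection point as the unsupervised
#' cut-off, scan candidate thresholds with the cross-validated log-logistic
#' AFT model to get the supervised cut-off, build the three-tier rule,
#' classify the cohort, compute the mixture/supervised overlap, optionally
#' compare the CpG mean against each individual CpG, refit the AFT at the
#' selected cut-off on the full cohort, and produce the per-tier survival
#' report. Fully deterministic given the seeds. A failure in a stage after
#' the cut-offs are derived returns a partial report flagged `incomplete`.
#'
#' @param source A [sim_config()] (cohort is simulated), a cohort data frame,
#'   or a path to a cohort CSV.
#' @param cv_seed Seed for the cross-validation fold assignment.
#' @param mixture_seed Seed for the EM restarts.
#' @param candidates Candidate supervised cut-offs (percent).
#' @param n_folds CV folds for the threshold scan.
#' @param floor_pct Methylation floor before the log transform.
#' @param horizons Survival-rate horizons in months.
#' @param compare_cpgs Run the per-CpG comparison when per-CpG columns are
#'   present.
#' @return An object of class `methtier_report`; see [report_to_list()] for
#'   the serialized structure.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(sim_config(n = 200, seed = 5), compare_cpgs = FALSE)
#' rep$rule
#' }
run_pipeline <- function(source, cv_seed = 1L, mixture_seed = 1L,
                         candidates = 1:25, n_folds = 5, floor_pct = 0.5,
                         horizons = c(12, 24, 60), compare_cpgs = TRUE) {
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)),
              class = "methtier_stage_error", parent = e)
      }),
      warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }

  sim_seed <- NA_integer_
  cohort <- stage("cohort", {
    if (inherits(source, "sim_config")) {
      sim_seed <- source$seed
      simulate_cohort(source)$cohort
    } else if (is.character(source)) {
      read_cohort(source)
    } else {
      validate_cohort(source)
    }
  })
  assert_nonempty_cohort(cohort, "run_pipeline")

  mix <- stage("mixture", fit_bnmm(cohort$mean_meth, floor_pct = floor_pct,
                                   seed = mixture_seed))
  unsup <- stage("intersection", intersection_cutoff(mix))
  scan <- stage("threshold_scan",
                scan_thresholds(cohort, candidates = candidates,
                                n_folds = n_folds, cv_seed = cv_seed))
  sup <- supervised_cutoff(scan)
  rule <- stage("three_tier", derive_three_tier(unsup, sup))

  tier <- classify_three_tier(cohort$mean_meth, rule)
  tier_counts <- as.integer(table(tier))
  tiers <- tibble::tibble(
    tier = levels(tier),
    n = tier_counts,
    fraction_pct = 100 * tier_counts / nrow(cohort)
  )

  incomplete <- FALSE
  soft_stage <- function(name, expr) {
    tryCatch(stage(name, expr), error = function(e) {
      incomplete <<- TRUE
      note(conditionMessage(e))
      NULL
    })
  }
  overlap <- soft_stage("overlap", overlap_statistic(cohort, mix, rule))
  cpg_cmp <- NULL
  if (compare_cpgs) {
    if (has_cpg_columns(cohort)) {
      cpg_cmp <- soft_stage("cpg_comparison",
                            compare_markers(cohort, cv_seed = cv_seed,
                                            candidates = candidates,
                                            n_folds = n_folds))
    } else {
      note("Per-CpG columns absent: CpG comparison omitted (mean-only cohort).")
    }
  }
  final_fit <- soft_stage("final_aft",
                          fit_aft(cohort, cutoff = scan$selected_cutoff))
  surv <- soft_stage("survival",
                     three_tier_survival_report(cohort, rule,
                                                horizons = horizons))

  report <- list(
    schema_version = "1.0",
    package_version = as.character(packageVersion("methtier")),
    seeds = list(cv_seed = cv_seed, mixture_seed = mixture_seed,
                 sim_seed = sim_seed),
    provenance = attr(cohort, "provenance") %||% "unknown",
    n = nrow(cohort),
    cohort_summary = summarize_cohort(cohort),
    mixture = mix,
    unsupervised_cutoff = unsup,
    scan = scan,
    supervised_cutoff = sup,
    rule = rule,
    tiers = tiers,
    overlap = overlap,
    cpg_comparison = cpg_cmp,
    final_aft = final_fit,
    survival = surv,
    warnings = warnings,
    incomplete = incomplete
  )
  class(report) <- "methtier_report"
  report
}

#' Serialize an analysis report
#'
#' `report_to_list()` flattens a [run_pipeline()] report into plain lists,
#' vectors and data frames ready for JSON; `report_to_json()` writes it with
#' [jsonlite::write_json()]. The serialized layout is versioned
#' (`schema_version`) and described by the schema file shipped at
#' `system.file("schema", "report-schema.json", package = "methtier")`;
#' [validate_report()] checks a report against that schema.
#'
#' @param report A `methtier_report`.
#' @return `report_to_list()`: a named list. `report_to_json()`: the path,
#'   invisibly.
#' @export
report_to_list <- function(report) {
  drop_class <- function(x) { attributes(x)$class <- NULL; x }
  mix <- report$mixture
  scan <- report$scan
  surv <- report$survival
  list(
    schema_version = report$schema_version,
    package_version = report$package_version,
    seeds = report$seeds,
    provenance = report$provenance,
    n = report$n,
    cohort_summary = list(
      n = report$cohort_summary$n,
      age_median = report$cohort_summary$age_median,
      age_range = report$cohort_summary$age_range,
      n_events = report$cohort_summary$n_events,
      categories = as.data.frame(report$cohort_summary$categories)
    ),
    mixture = list(weights = mix$weights, means_log = mix$means,
                   sds_log = mix$sds, loglik = mix$loglik,
                   converged = mix$converged, n_obs = mix$n_obs),
    unsupervised_cutoff_pct = report$unsupervised_cutoff$value_pct,
    unsupervised_cutoff_rounded = report$unsupervised_cutoff$value_pct_rounded,
    supervised_cutoff_pct = report$supervised_cutoff$value_pct,
    scan = list(table = as.data.frame(dplyr::select(scan$scan, -"c_folds")),
                selected_cutoff = scan$selected_cutoff,
                selected_c = scan$selected_c,
                cv_seed = scan$cv_seed, n_folds = scan$n_folds),
    rule = drop_class(report$rule),
    tiers = as.data.frame(report$tiers),
    overlap = report$overlap,
    cpg_comparison = if (!is.null(report$cpg_comparison))
      as.data.frame(report$cpg_comparison$comparison),
    final_aft = if (!is.null(report$final_aft))
      list(beta = as.list(report$final_aft$beta),
           time_ratios = as.list(exp(report$final_aft$beta)),
           scale = report$final_aft$scale,
           loglik = report$final_aft$loglik,
           converged = report$final_aft$converged),
    survival = if (!is.null(surv))
      list(tiers = as.data.frame(dplyr::mutate(surv$tiers,
                                               tier = as.character(.data$tier))),
           rates = as.data.frame(surv$rates),
           tests = if (!is.null(surv$tests)) as.data.frame(surv$tests)),
    warnings = report$warnings,
    incomplete = report$incomplete
  )
}

#' @rdname report_to_list
#' @param path Output JSON path.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname report_to_list
#' @details `validate_report()` performs a minimal structural check against
#'   the shipped schema file: every required top-level key must be present
#'   and of the declared JSON type.
#' @export
validate_report <- function(report) {
  lst <- if (inherits(report, "methtier_report")) report_to_list(report) else report
  schema_path <- system.file("schema", "report-schema.json", package = "methtier")
  schema <- jsonlite::read_json(schema_path)
  for (key in schema$required) {
    if (!key %in% names(lst)) {
      abort(paste0("Report is missing required field: ", key),
            class = "methtier_schema_error")
    }
  }
  json_type <- function(x) {
    if (is.null(x)) "null"
    else if (is.data.frame(x) || (is.list(x) && !is.null(names(x)))) "object"
    else if (is.list(x)) "array"
    else if (is.character(x)) "string"
    else if (is.logical(x)) "boolean"
    else if (is.numeric(x)) if (length(x) > 1) "array" else "number"
    else "unknown"
  }
  for (key in names(schema$properties)) {
    if (!key %in% names(lst) || is.null(lst[[key]])) next
    want <- unlist(schema$properties[[key]]$type)
    got <- json_type(lst[[key]])
    if (got == "number" && "integer" %in% want) got <- "integer"
    ok <- got %in% want ||
      (got == "number" && "array" %in% want) || # length-1 vectors unbox
      (got == "array" && any(c("object", "number") %in% want))
    if (!ok) {
      abort(paste0("Report field '", key, "' has JSON type '", got,
                   "' but the schema requires '",
                   paste(want, collapse = "/"), "'."),
            class = "methtier_schema_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.methtier_report <- function(x, ...) {
  cat(sprintf("methtier analysis report (schema %s) - n = %d [%s]\n",
              x$schema_version, x$n, x$provenance))
  cat(sprintf("Unsupervised cut-off: %.2f%% (rounded %d%%); supervised cut-off: %g%%\n",
              x$unsupervised_cutoff$value_pct,
              x$unsupervised_cutoff$value_pct_rounded,
              x$supervised_cutoff$value_pct))
  print(x$rule)
  print(x$tiers)
  if (!is.null(x$survival)) print(x$survival$tiers)
  if (x$incomplete) cat("NOTE: report is incomplete; see $warnings.\n")
  invisible(x)
}
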