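#' Cohort table schema
#'
#' A cohort is an ordinary tibble with one row per patient. The canonical
#' columns are `patient_id`, `cpg76`, `cpg77`, `cpg78`, `cpg79`, `mean_meth`,
#' `age`, `sex`, `preop_ps`, `resection`, `os_months`, `event`. Methylation
#' values are percentages in \[0, 100\]; `os_months` is overall survival in
#' months from primary surgery; `event` is 1 for an observed death and 0 for
#' censoring at last follow-up. The per-CpG columns may be absent
#' ("mean-only" exports), in which case per-CpG operations raise an error but
#' the mean-based pipeline runs.
#'
#' @name cohort-schema
#' @keywords internal
NULL

.cohort_cols <- c("patient_id", "cpg76", "cpg77", "cpg78", "cpg79",
                  "mean_meth", "age", "sex", "preop_ps", "resection",
                  "os_months", "event")
.cpg_cols <- c("cpg76", "cpg77", "cpg78", "cpg79")
.resection_levels <- c("GTR", "NTR", "STR", "biopsy")
.sex_levels <- c("male", "female")

has_cpg_columns <- function(data) all(.cpg_cols %in% names(data))

require_cpg_columns <- function(data) {
  if (!has_cpg_columns(data)) {
    abort("Per-CpG columns (cpg76..cpg79) are absent from this cohort; only mean_meth operations are available.",
          class = "methtier_missing_per_cpg")
  }
  invisible(data)
}

#' Validate a cohort table
#'
#' Checks every row against the schema invariants: methylation percentages in
#' \[0, 100\], `age > 0`, `sex` in male/female, `preop_ps` in 0..4,
#' `resection` one of GTR/NTR/STR/biopsy, `os_months > 0`, `event` in 0/1,
#' unique `patient_id`, and agreement of `mean_meth` with the arithmetic mean
#' of the four CpG values (within `mean_tol`, which by default admits inputs
#' whose mean was rounded externally). A missing `mean_meth` is recomputed
#' from the CpG columns.
#'
#' Validation is total: every input row is either kept or listed exactly once
#' in the rejection summary (attached as `attr(, "rejections")`) with a
#' reason code.
#'
#' @param data A data frame following the cohort schema.
#' @param strict If `TRUE`, any invalid row is an error; otherwise invalid
#'   rows are dropped and summarized.
#' @param mean_tol Absolute tolerance for `mean_meth` vs the mean of the CpG
#'   columns (default 0.51, admitting integer-rounded means).
#' @return A validated tibble in canonical column order with attributes
#'   `rejections` (tibble: `row`, `patient_id`, `reason`) and `provenance`.
#' @export
validate_cohort <- function(data, strict = FALSE, mean_tol = 0.51) {
  data <- tibble::as_tibble(data)
  names(data) <- tolower(names(data))
  mandatory <- setdiff(.cohort_cols, c(.cpg_cols, "mean_meth"))
  missing_cols <- setdiff(mandatory, names(data))
  if (!has_cpg_columns(data) && !"mean_meth" %in% names(data)) {
    missing_cols <- c(missing_cols, "mean_meth")
  }
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "methtier_schema_error")
  }
  if (!"mean_meth" %in% names(data)) data$mean_meth <- NA_real_

  data <- data |>
    dplyr::mutate(
      patient_id = as.character(.data$patient_id),
      sex = .match_level(tolower(as.character(.data$sex)), .sex_levels),
      resection = .match_level(as.character(.data$resection), .resection_levels),
      dplyr::across(dplyr::any_of(c(.cpg_cols, "mean_meth", "age",
                                    "os_months", "event", "preop_ps")),
                    as.numeric)
    )

  cpg <- if (has_cpg_columns(data)) as.matrix(data[.cpg_cols]) else NULL
  if (!is.null(cpg)) {
    cpg_mean <- rowMeans(cpg)
    fill <- is.na(data$mean_meth)
    data$mean_meth[fill] <- cpg_mean[fill]
  }

  reason <- rep(NA_character_, nrow(data))
  flag <- function(bad, code) {
    bad[is.na(bad)] <- TRUE
    ifelse(is.na(reason) & bad, code, reason)
  }
  if (!is.null(cpg)) {
    reason <- flag(apply(cpg < 0 | cpg > 100 | is.na(cpg), 1, any), "cpg_out_of_range")
    reason <- flag(abs(data$mean_meth - rowMeans(cpg)) > mean_tol, "mean_meth_mismatch")
  }
  reason <- flag(data$mean_meth < 0 | data$mean_meth > 100, "mean_meth_out_of_range")
  reason <- flag(!(data$age > 0), "nonpositive_age")
  reason <- flag(is.na(data$sex), "unknown_sex")
  reason <- flag(!(data$preop_ps %in% 0:4), "preop_ps_out_of_range")
  reason <- flag(is.na(data$resection), "unknown_resection")
  reason <- flag(!(data$os_months > 0), "nonpositive_os")
  reason <- flag(!(data$event %in% c(0, 1)), "event_not_binary")
  reason <- flag(duplicated(data$patient_id), "duplicate_patient_id")

  rejections <- tibble::tibble(
    row = which(!is.na(reason)),
    patient_id = data$patient_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  if (strict && nrow(rejections) > 0) {
    abort(paste0(nrow(rejections), " row(s) violate the cohort schema; first: row ",
                 rejections$row[1], " (", rejections$reason[1], ")"),
          class = "methtier_validation_error")
  }
  keep_cols <- intersect(.cohort_cols, names(data))
  out <- data[is.na(reason), keep_cols]
  attr(out, "rejections") <- rejections
  attr(out, "provenance") <- attr(data, "provenance") %||% "in-memory data frame"
  out
}

.match_level <- function(x, levels) {
  levels[match(tolower(x), tolower(levels))]
}

assert_nonempty_cohort <- function(cohort, context = "analysis") {
  if (is.null(cohort) || nrow(cohort) == 0) {
    abort(paste0("Empty cohort: no valid records available for ", context, "."),
          class = "methtier_empty_cohort")
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads a patient table in the canonical schema (see [validate_cohort()]);
#' column names are matched case-insensitively and extra columns are
#' ignored. Rows failing validation are dropped (non-strict) or fatal
#' (strict); the rejection summary is attached as an attribute.
#'
#' @param path Path to a CSV file.
#' @inheritParams validate_cohort
#' @return A validated cohort tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cohort(sim_config(n = 20, seed = 1))$cohort, f)
#' read_cohort(f)
read_cohort <- function(path, strict = FALSE, mean_tol = 0.51) {
  if (!file.exists(path)) {
    abort(paste0("Cohort file not found: ", path), class = "methtier_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- validate_cohort(raw, strict = strict, mean_tol = mean_tol)
  attr(out, "provenance") <- paste0("file:", path)
  out
}

#' Write a cohort CSV
#'
#' Writes the cohort in canonical column order. Reading the file back with
#' [read_cohort()] reproduces all fields (numeric values to at least 6
#' significant digits).
#'
#' @param cohort A validated cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(.cohort_cols, names(cohort))
  readr::write_csv(cohort[cols], path, progress = FALSE)
  invisible(path)
}

#' Summarize a cohort
#'
#' Basic demographic/clinical summary: size, median and range of age and
#' follow-up, number of deaths, and counts with percentages for sex,
#' preoperative ECOG performance status and extent of resection.
#'
#' @param cohort A validated cohort tibble.
#' @return A list of class `cohort_summary` with elements `n`, `age_median`,
#'   `age_range`, `n_events`, `os_median_months`, and `categories`, a tibble
#'   with columns `variable`, `level`, `n`, `pct`.
#' @export
summarize_cohort <- function(cohort) {
  assert_nonempty_cohort(cohort, "summarize_cohort")
  cat_tbl <- function(var, levels) {
    x <- factor(as.character(cohort[[var]]), levels = as.character(levels))
    tibble::tibble(variable = var, level = as.character(levels),
                   n = as.integer(table(x)),
                   pct = 100 * as.integer(table(x)) / nrow(cohort))
  }
  out <- list(
    n = nrow(cohort),
    age_median = median(cohort$age),
    age_range = range(cohort$age),
    n_events = sum(cohort$event),
    os_median_months = median(cohort$os_months),
    categories = dplyr::bind_rows(
      cat_tbl("sex", .sex_levels),
      cat_tbl("preop_ps", 0:4),
      cat_tbl("resection", .resection_levels)
    )
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d deaths)\n", x$n, x$n_events))
  cat(sprintf("Age: median %.0f (range %.0f-%.0f); median follow-up %.1f months\n",
              x$age_median, x$age_range[1], x$age_range[2], x$os_median_months))
  print(x$categories, n = nrow(x$categories))
  invisible(x)
}
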