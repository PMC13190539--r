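test_that("fold assignment is seeded, stratified and balanced", {
  event <- rep(c(1, 0), c(70, 30))
  f1 <- make_cv_folds(event, 5, cv_seed = 4)
  f2 <- make_cv_folds(event, 5, cv_seed = 4)
  expect_identical(f1, f2)
  for (k in 1:5) expect_gt(sum(event[f1 == k]), 0)  # events in every fold
  expect_true(all(abs(table(f1) - 20) <= 2))
})

test_that("a constant marker yields no valid threshold", {
  co <- validate_cohort(toy_cohort(30, mean_meth = rep(12, 30)))
  expect_error(scan_thresholds(co, cv_seed = 1),
               class = "methtier_no_valid_threshold")
})

test_that("too few events is an explicit error", {
  co <- toy_cohort(10)
  co$event <- c(1, rep(0, 9))
  expect_error(scan_thresholds(validate_cohort(co), cv_seed = 1),
               class = "methtier_insufficient_events")
})

test_that("the scan is deterministic under a fixed cv_seed", {
  sim <- simulate_cohort(sim_config(n = 200, seed = 12))
  a <- scan_thresholds(sim$cohort, cv_seed = 3)
  b <- scan_thresholds(sim$cohort, cv_seed = 3)
  expect_identical(a$scan, b$scan)
  expect_identical(a$selected_cutoff, b$selected_cutoff)
  expect_identical(a$folds, b$folds)
})

test_that("a sharp generative dichotomy at 10% is recovered", {
  co <- sharp_cohort(n = 1500, seed = 41, threshold = 10, effect = 0.9)
  scan <- scan_thresholds(co, cv_seed = 1)
  expect_lte(abs(scan$selected_cutoff - 10), 2)
})

test_that("ties in the score break toward the lowest candidate", {
  # values only at 2% and 20%: candidates 2..19 give identical dichotomies,
  # hence identical scores; the selected cut-off must be the lowest of them
  withr::with_seed(5, {
    mm <- sample(c(2, 20), 80, TRUE)
  })
  co <- validate_cohort(toy_cohort(80, mean_meth = mm))
  scan <- scan_thresholds(co, cv_seed = 2)
  valid <- scan$scan$candidate[scan$scan$valid]
  expect_identical(sort(valid), 2:19)
  top <- valid[scan$scan$c_mean[scan$scan$valid] ==
                 max(scan$scan$c_mean[scan$scan$valid])]
  expect_identical(scan$selected_cutoff, min(top))
  expect_true(length(top) >= 2)  # the tie is real
})

test_that("marker comparison shares one fold assignment and zeroes the mean diff", {
  sim <- simulate_cohort(sim_config(n = 250, seed = 19))
  cmp <- compare_markers(sim$cohort, cv_seed = 6)
  expect_equal(cmp$comparison$diff_pp[cmp$comparison$marker == "mean_meth"], 0)
  for (s in cmp$scans) expect_identical(s$folds, cmp$folds)
})

test_that("when every CpG equals the mean all comparison differences vanish", {
  co <- validate_cohort(toy_cohort(120,
    mean_meth = withr::with_seed(3, sample(c(2:6, 20:35), 120, TRUE))))
  cmp <- compare_markers(co, cv_seed = 9)
  expect_true(all(cmp$comparison$diff_pp == 0))
  expect_true(all(cmp$comparison$selected_cutoff ==
                    cmp$comparison$selected_cutoff[1]))
})

test_that("per-CpG noise keeps any single CpG from beating the mean materially", {
  # noisy per-CpG reads: averaging four CpGs cancels noise, so no individual
  # CpG should outperform the mean marker by more than Monte-Carlo slack
  sim <- simulate_cohort(sim_config(n = 800, seed = 73, cpg_noise_sd = 0.6))
  cmp <- compare_markers(sim$cohort, cv_seed = 5)
  expect_true(all(cmp$comparison$diff_pp <= 1.0))
})

test_that("three-tier rule reproduces the published classification semantics", {
  rule <- derive_three_tier(11, 8)
  expect_false(rule$collapsed)
  cls <- classify_three_tier(c(8, 9, 11), rule)
  expect_equal(as.character(cls), c("unmethylated", "gray_zone", "methylated"))
})

test_that("a non-positive gray zone collapses to a single threshold", {
  expect_message(rule <- derive_three_tier(11, 12), "gray zone")
  expect_true(rule$collapsed)
  cls <- classify_three_tier(c(10.5, 11, 12), rule)
  expect_equal(as.character(cls), c("unmethylated", "methylated", "methylated"))
  expect_false(any(cls == "gray_zone"))
})

test_that("every methylation value maps to exactly one tier", {
  grid <- seq(0, 100, by = 0.25)
  for (rule in list(derive_three_tier(11, 8),
                    suppressMessages(derive_three_tier(11, 11)))) {
    cls <- classify_three_tier(grid, rule)
    expect_false(anyNA(cls))
    expect_equal(length(cls), length(grid))
  }
})

test_that("cut-off objects carry both estimates into the rule", {
  fit <- make_bnmm(c(0.5, 0.5), c(0, 2), c(1, 1))
  unsup <- intersection_cutoff(fit)  # e ~ 2.718 -> rounds to 3
  rule <- derive_three_tier(unsup, 2)
  expect_equal(rule$upper, 3)
  expect_equal(rule$lower, 2)
})

test_that("under a null methylation effect no candidate dominates selection", {
  sel <- vapply(1:20, function(s) {
    sim <- simulate_cohort(sim_config(n = 250, seed = 500 + s, b_meth = 0))
    scan_thresholds(sim$cohort, cv_seed = s)$selected_cutoff
  }, numeric(1))
  expect_gt(dplyr::n_distinct(sel), 5)       # selections scatter
  expect_lt(max(table(sel)) / 20, 0.35)      # no systematic edge preference
})
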