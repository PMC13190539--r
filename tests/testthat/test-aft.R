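test_that("log-logistic log-likelihood matches hand-computable cases", {
  # single censored observation at its predicted median: log S = -log 2
  expect_equal(loglogistic_loglik(log(5), 1, matrix(1), 5, 0), -log(2))

  # three-observation toy against the term-by-term oracle
  x <- matrix(1, nrow = 3)
  t3 <- c(2, 5, 7); e3 <- c(1, 1, 0)
  expect_equal(loglogistic_loglik(log(4), 1, x, t3, e3),
               oracle_loglogistic_loglik(log(4), 1, x, t3, e3))

  # reordering observations leaves the sum unchanged
  o <- c(3, 1, 2)
  expect_equal(loglogistic_loglik(log(4), 1, x, t3[o], e3[o]),
               loglogistic_loglik(log(4), 1, x, t3, e3))

  expect_error(loglogistic_loglik(0, 1, matrix(1), -1, 1),
               class = "methtier_domain_error")
})

test_that("intercept-only maximum likelihood recovers truth within 2%", {
  withr::with_seed(55, {
    t <- exp(3 + 0.4 * rlogis(5000))
  })
  core <- methtier:::fit_loglogistic(t, rep(1, 5000), matrix(1, 5000))
  expect_lt(abs(core$beta[1] - 3) / 3, 0.02)
  expect_lt(abs(core$scale - 0.4) / 0.4, 0.02)
})

test_that("the fit agrees with an independent censored-regression fitter", {
  sim <- simulate_cohort(sim_config(n = 600, seed = 9))
  fit <- fit_aft(sim$cohort, cutoff = 10)
  sr <- survival::survreg(
    survival::Surv(os_months, event) ~ I(mean_meth > 10) +
      I((age - 60) / 10) + preop_ps +
      factor(resection, levels = c("GTR", "NTR", "STR", "biopsy")),
    data = sim$cohort, dist = "loglogistic")
  expect_equal(unname(fit$beta), unname(coef(sr)), tolerance = 1e-4)
  expect_equal(fit$scale, sr$scale, tolerance = 1e-4)
  expect_equal(fit$loglik, sr$loglik[2], tolerance = 1e-6)
})

test_that("doubling survival times shifts only the intercept, by log 2", {
  sim <- simulate_cohort(sim_config(n = 800, seed = 17,
                                    censor_min = 1e5, censor_max = 2e5))
  expect_true(all(sim$cohort$event == 1))  # effectively uncensored
  f1 <- fit_aft(sim$cohort, cutoff = 10)
  doubled <- dplyr::mutate(sim$cohort, os_months = os_months * 2)
  f2 <- fit_aft(doubled, cutoff = 10)
  expect_equal(f2$beta[["(Intercept)"]] - f1$beta[["(Intercept)"]], log(2),
               tolerance = 1e-6)
  expect_equal(f2$beta[-1], f1$beta[-1], tolerance = 1e-6)
  expect_equal(f2$scale, f1$scale, tolerance = 1e-6)
})

test_that("the methylation effect is recovered on a default simulated cohort", {
  cfg <- sim_config(n = 2000, seed = 23)
  sim <- simulate_cohort(cfg)
  fit <- fit_aft(sim$cohort, cutoff = 10)  # near the generating intersection
  expect_lt(abs(fit$beta[["methylated"]] - cfg$b_meth), 0.1)
})

test_that("fitting without events is an error", {
  co <- toy_cohort(6)
  co$event <- 0
  expect_error(fit_aft(validate_cohort(co), cutoff = 10),
               class = "methtier_no_events")
})

test_that("the linear predictor follows the design contract", {
  sim <- simulate_cohort(sim_config(n = 120, seed = 3))
  fit <- fit_aft(sim$cohort, cutoff = 10)
  ref <- tibble::tibble(patient_id = "x", mean_meth = 5, age = 60,
                        preop_ps = 0, resection = "GTR", sex = "male",
                        os_months = 10, event = 1)
  expect_equal(linear_predictor(fit, ref), fit$beta[["(Intercept)"]])
  ref_m <- dplyr::mutate(ref, mean_meth = 50)
  expect_equal(linear_predictor(fit, ref_m) - linear_predictor(fit, ref),
               fit$beta[["methylated"]])
  # training-design consistency at the optimum
  eta <- linear_predictor(fit, sim$cohort)
  des <- aft_design(sim$cohort, cutoff = 10)
  expect_equal(eta, drop(des$x %*% fit$beta))
})

test_that("concordance handles perfect, reversed and hand-enumerated cases", {
  t4 <- c(1, 2, 3, 4); e4 <- rep(1, 4)
  expect_equal(concordance_index(t4, e4, c(0.1, 0.2, 0.3, 0.4))$c_index, 1.0)
  expect_equal(concordance_index(t4, e4, c(0.4, 0.3, 0.2, 0.1))$c_index, 0.0)

  tt <- c(2, 4, 4, 6); ee <- c(1, 1, 0, 1); pp <- c(1.0, 2.0, 2.0, 1.5)
  ora <- oracle_concordance(tt, ee, pp)
  got <- concordance_index(tt, ee, pp)
  expect_equal(got$n_comparable_pairs, 5)
  expect_equal(got$c_index, ora$c_index)
  expect_equal(got$n_concordant, ora$n_concordant)
  expect_equal(got$n_tied, ora$n_tied)

  expect_error(concordance_index(c(1, 2), c(0, 0), c(1, 2)),
               class = "methtier_no_pairs")
})

test_that("concordance equals the exhaustive oracle on random censored data", {
  withr::with_seed(66, {
    for (k in 1:30) {
      n <- sample(5:60, 1)
      t <- sample(1:15, n, TRUE)            # heavy ties
      e <- rbinom(n, 1, 0.7)
      p <- sample(seq(0, 2, by = 0.25), n, TRUE)  # tied predictions
      if (sum(e) == 0) next
      ora <- oracle_concordance(t, e, p)
      if (ora$n_pairs == 0) next
      got <- concordance_index(t, e, p)
      expect_identical(got$n_comparable_pairs, ora$n_pairs)
      expect_equal(got$c_index, ora$c_index)
    }
  })
})

test_that("concordance is invariant under strictly increasing transforms", {
  withr::with_seed(77, {
    t <- rexp(50, 0.1); e <- rbinom(50, 1, 0.8); p <- rnorm(50)
  })
  a <- concordance_index(t, e, p)$c_index
  expect_equal(concordance_index(t, e, exp(p))$c_index, a)
  expect_equal(concordance_index(t, e, 3 * p + 7)$c_index, a)
})

test_that("concordance agrees with the survival package on censored data", {
  withr::with_seed(88, {
    t <- sample(1:20, 100, TRUE); e <- rbinom(100, 1, 0.6)
    p <- sample(seq(0, 3, 0.5), 100, TRUE)
  })
  cs <- survival::concordance(survival::Surv(t, e) ~ p)
  expect_equal(concordance_index(t, e, p)$c_index, cs$concordance)
})
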