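test_that("EM recovers a well-separated two-cluster structure", {
  withr::with_seed(101, {
    x <- c(exp(rnorm(500, log(2), 0.3)), exp(rnorm(500, log(30), 0.3)))
  })
  fit <- fit_bnmm(pmin(x, 100), seed = 1)
  expect_lt(abs(fit$weights[1] - 0.5), 0.05)
  expect_lt(abs(fit$weights[2] - 0.5), 0.05)
  expect_lt(abs(fit$means[1] - log(2)), 0.1)
  expect_lt(abs(fit$means[2] - log(30)), 0.1)
})

test_that("EM recovers mixture parameters within 5% relative error at n = 5000", {
  w <- c(0.6, 0.4); mu <- c(1.0, 3.2); s <- c(0.5, 0.6)
  withr::with_seed(202, {
    cls <- rbinom(5000, 1, w[2])
    x <- exp(rnorm(5000, mu[cls + 1], s[cls + 1]))
  })
  fit <- fit_bnmm(pmin(x, 100), seed = 1)
  expect_lt(abs(fit$weights[1] - w[1]) / w[1], 0.05)
  expect_lt(abs(fit$means[1] - mu[1]) / abs(mu[1]), 0.05)
  expect_lt(abs(fit$means[2] - mu[2]) / abs(mu[2]), 0.05)
  expect_lt(abs(fit$sds[1] - s[1]) / s[1], 0.05)
  expect_lt(abs(fit$sds[2] - s[2]) / s[2], 0.05)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::with_seed(303, {
    x <- c(exp(rnorm(400, 1.1, 0.5)), exp(rnorm(300, 3.4, 0.5)))
  })
  fit <- fit_bnmm(pmin(x, 100), seed = 2)
  mc <- mclust::Mclust(log(pmax(pmin(x, 100), 0.5)), G = 2,
                       modelNames = "V", verbose = FALSE)
  ord <- order(mc$parameters$mean)
  expect_equal(fit$means, unname(mc$parameters$mean[ord]), tolerance = 0.02)
  expect_equal(fit$weights, mc$parameters$pro[ord], tolerance = 0.02)
})

test_that("degenerate inputs raise a degeneracy error", {
  expect_error(fit_bnmm(rep(5, 50)), class = "methtier_degenerate_fit")
  expect_error(fit_bnmm(c(1, 2, 3)), class = "methtier_input_error")
  expect_error(fit_bnmm(c(rep(10, 20), 150)), class = "methtier_input_error")
})

test_that("the EM log-likelihood trace is non-decreasing", {
  for (s in 1:5) {
    withr::with_seed(s, {
      x <- c(exp(rnorm(150, 1, 0.6)), exp(rnorm(150, 3.3, 0.6)))
    })
    fit <- fit_bnmm(pmin(x, 100), seed = s)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("the fit is invariant to the ordering of the input", {
  withr::with_seed(42, {
    x <- pmin(c(exp(rnorm(200, 1, 0.5)), exp(rnorm(200, 3.4, 0.5))), 100)
    xp <- sample(x)
  })
  a <- fit_bnmm(x, seed = 9)
  b <- fit_bnmm(xp, seed = 9)
  expect_equal(a$means, b$means, tolerance = 1e-8)
  expect_equal(a$weights, b$weights, tolerance = 1e-8)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-8)
})

test_that("the symmetric equal-variance intersection is the exact midpoint", {
  cut <- intersection_cutoff(make_bnmm(c(0.5, 0.5), c(0, 2), c(1, 1)))
  expect_equal(cut$log_value, 1)
  expect_equal(cut$value_pct, exp(1))
  expect_equal(cut$value_pct_rounded, 3)
})

test_that("raising the first component weight moves the intersection right", {
  sym <- intersection_cutoff(make_bnmm(c(0.5, 0.5), c(0, 2), c(1, 1)))
  skew <- intersection_cutoff(make_bnmm(c(0.7, 0.3), c(0, 2), c(1, 1)))
  expect_gt(skew$log_value, sym$log_value)
  # extreme weights push the crossing past the second mean: reported as
  # a no-intersection error rather than an out-of-interval cut-off
  expect_error(intersection_cutoff(make_bnmm(c(0.9, 0.1), c(0, 2), c(1, 1))),
               class = "methtier_no_intersection")
})

test_that("the quadratic intersection matches the density sign-scan oracle", {
  fit <- make_bnmm(c(0.6, 0.4), c(1.0, 3.0), c(0.5, 1.0))
  cut <- intersection_cutoff(fit)
  expect_equal(cut$log_value,
               oracle_intersection(fit$weights, fit$means, fit$sds),
               tolerance = 1e-5)

  withr::with_seed(7, {
    done <- 0
    while (done < 20) {
      w1 <- runif(1, 0.2, 0.8)
      mu <- sort(runif(2, 0, 4)); if (diff(mu) < 0.5) next
      s <- runif(2, 0.3, 1.2)
      ora <- oracle_intersection(c(w1, 1 - w1), mu, s)
      got <- tryCatch(
        intersection_cutoff(make_bnmm(c(w1, 1 - w1), mu, s))$log_value,
        error = function(e) NA_real_)
      if (is.na(ora)) {
        expect_true(is.na(got))  # both agree there is no crossing
      } else {
        expect_equal(got, ora, tolerance = 1e-5)
      }
      done <- done + 1
    }
  })
})

test_that("no-intersection cases raise a diagnostic error", {
  # dominant first component: weighted density never crosses between means
  expect_error(intersection_cutoff(make_bnmm(c(0.999, 0.001), c(1, 1.6),
                                             c(1.5, 0.01))),
               class = "methtier_no_intersection")
})

test_that("on simulated cohorts the cut-off lies between the component medians", {
  cfg <- sim_config(n = 2000, seed = 31)
  sim <- simulate_cohort(cfg)
  cut <- intersection_cutoff(fit_bnmm(sim$cohort$mean_meth, seed = 1))
  expect_gt(cut$value_pct, exp(cfg$mu_log[1]))
  expect_lt(cut$value_pct, exp(cfg$mu_log[2]))
})

test_that("mixture tidiers expose sorted components and fit diagnostics", {
  withr::with_seed(11, {
    x <- pmin(c(exp(rnorm(100, 1, 0.5)), exp(rnorm(100, 3.4, 0.5))), 100)
  })
  fit <- fit_bnmm(x, seed = 1)
  td <- tidy(fit)
  expect_equal(td$component, c("unmethylated", "methylated"))
  expect_lt(td$mean_log[1], td$mean_log[2])
  expect_equal(sum(td$weight), 1)
  expect_true(glance(fit)$converged)
})
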