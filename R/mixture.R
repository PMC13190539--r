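#' Fit a two-component normal mixture to log methylation
#'
#' Fits a bimodal normal mixture model (BNMM) to natural-log-transformed
#' methylation percentages by expectation-maximization. Values are floored at
#' `floor_pct` before the log transform (fully unmethylated assay reads can
#' report 0%). EM is run from `n_starts` initializations — a quantile split
#' at the median plus seeded random perturbations — and the best
#' log-likelihood fit is returned with components sorted by mean, so
#' component 1 is the unmethylated mode and component 2 the methylated mode.
#'
#' @param values Methylation percentages in \[0, 100\] (at least 10).
#' @param floor_pct Lower floor applied before the log transform.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Maximum EM iterations per start.
#' @param n_starts Number of initializations.
#' @param seed Seed for the random restarts.
#' @return An object of class `bnmm_fit`: `weights`, `means`, `sds` (log
#'   scale, components sorted by ascending mean), `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `n_obs`, `floor_pct`.
#' @export
#' @examples
#' x <- c(exp(rnorm(200, 1, 0.5)), exp(rnorm(200, 3.4, 0.5)))
#' fit <- fit_bnmm(pmin(x, 100), seed = 1)
#' tidy(fit)
fit_bnmm <- function(values, floor_pct = 0.5, tol = 1e-8, max_iter = 1000,
                     n_starts = 10, seed = 1L) {
  values <- as.numeric(values)
  if (length(values) < 10) {
    abort("fit_bnmm needs at least 10 values.", class = "methtier_input_error")
  }
  if (any(!is.finite(values)) || any(values < 0 | values > 100)) {
    abort("Methylation values must be finite and in [0, 100].",
          class = "methtier_input_error")
  }
  x <- log(pmax(values, floor_pct))
  n <- length(x)
  if (sd(x) < 1e-12) {
    abort("Degenerate input: all values identical after flooring; a two-component mixture cannot be fitted. Provide more varied data or fewer components.",
          class = "methtier_degenerate_fit")
  }

  starts <- vector("list", n_starts)
  lower <- x[x <= median(x)]
  upper <- x[x > median(x)]
  if (length(upper) == 0) upper <- lower
  starts[[1]] <- list(pi = length(lower) / n,
                      mu = c(mean(lower), mean(upper)),
                      sigma = pmax(c(sd(lower), sd(upper)), 0.05, na.rm = TRUE))
  if (n_starts > 1) {
    with_local_seed(seed, {
      for (k in 2:n_starts) {
        q <- sort(runif(2, 0.05, 0.95))
        starts[[k]] <- list(pi = runif(1, 0.25, 0.75),
                            mu = as.numeric(quantile(x, q)),
                            sigma = sd(x) * runif(2, 0.3, 1.2))
      }
    })
  }

  best <- NULL
  for (st in starts) {
    run <- em_two_normal(x, st, tol = tol, max_iter = max_iter)
    if (is.null(run)) next
    if (is.null(best) || run$loglik > best$loglik ||
        (run$loglik == best$loglik && run$mu[1] < best$mu[1])) best <- run
  }
  if (is.null(best)) {
    abort("All EM starts collapsed (component sd below 1e-6 or weight below 1/n). Provide more data or fewer components.",
          class = "methtier_degenerate_fit")
  }
  ord <- order(best$mu)
  fit <- list(weights = best$pi[ord], means = best$mu[ord],
              sds = best$sigma[ord], loglik = best$loglik,
              loglik_trace = best$trace, n_iter = best$n_iter,
              converged = best$converged, n_obs = n, floor_pct = floor_pct)
  class(fit) <- "bnmm_fit"
  fit
}

# one EM run; returns NULL on collapse
em_two_normal <- function(x, start, tol, max_iter) {
  n <- length(x)
  pi2 <- c(start$pi, 1 - start$pi)
  mu <- start$mu
  sigma <- pmax(start$sigma, 1e-3)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d1 <- pi2[1] * dnorm(x, mu[1], sigma[1])
    d2 <- pi2[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    g <- d1 / tot
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1 || n2 < 1) return(NULL)
    pi2 <- c(n1, n2) / n
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sigma <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                    sum((1 - g) * (x - mu[2])^2) / n2))
    if (any(sigma < 1e-6)) return(NULL)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(pi = pi2, mu = mu, sigma = sigma, loglik = trace[length(trace)],
       trace = trace, n_iter = length(trace), converged = converged)
}

#' Posterior probability of the methylated mixture component
#'
#' @param fit A [fit_bnmm()] object.
#' @param values Methylation percentages.
#' @return Posterior probability that each value belongs to the
#'   higher-methylation component.
#' @export
posterior_methylated <- function(fit, values) {
  x <- log(pmax(as.numeric(values), fit$floor_pct))
  d1 <- fit$weights[1] * dnorm(x, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * dnorm(x, fit$means[2], fit$sds[2])
  d2 / (d1 + d2)
}

#' Unsupervised cut-off: intersection of the mixture components
#'
#' Solves `w1 * N(x; mu1, s1^2) = w2 * N(x; mu2, s2^2)` on the log scale for
#' the crossing point between the component means. With unequal component
#' variances the condition is a quadratic in `x` and the root inside the open
#' interval `(mu1, mu2)` is taken; with equal variances the solution is
#' linear. The cut-off is back-transformed to the percentage scale and the
#' convention is `mean_meth >= cutoff` = methylated. Both the raw percentage
#' and its half-up integer rounding are reported.
#'
#' @param fit A [fit_bnmm()] object with distinct component means.
#' @return An object of class `meth_cutoff`: `value_pct` (raw),
#'   `value_pct_rounded`, `log_value`, `method = "unsupervised"`, and
#'   `diagnostics` (the mixture fit).
#' @export
intersection_cutoff <- function(fit) {
  mu <- fit$means; s <- fit$sds; w <- fit$weights
  if (abs(mu[1] - mu[2]) < 1e-10) {
    abort("Mixture component means coincide; no intersection cut-off.",
          class = "methtier_no_intersection")
  }
  # w1*N1(x) = w2*N2(x)  <=>  A x^2 + B x + C = 0 on the log density scale
  A <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  B <- mu[1] / s[1]^2 - mu[2] / s[2]^2
  C <- mu[2]^2 / (2 * s[2]^2) - mu[1]^2 / (2 * s[1]^2) +
    log(w[1] * s[2] / (w[2] * s[1]))
  if (abs(A) < 1e-12) {
    roots <- -C / B
  } else {
    disc <- B^2 - 4 * A * C
    roots <- if (disc < 0) numeric(0) else
      (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside) == 0) {
    mid <- mean(mu)
    ratio <- log(w[1] * dnorm(mid, mu[1], s[1])) -
      log(w[2] * dnorm(mid, mu[2], s[2]))
    abort(paste0("No intersection of the weighted component densities between the component means (log density ratio at midpoint: ",
                 signif(ratio, 4), "); one component dominates throughout."),
          class = "methtier_no_intersection")
  }
  x_star <- min(inside)
  out <- list(value_pct = exp(x_star),
              value_pct_rounded = round_half_up(exp(x_star)),
              log_value = x_star,
              method = "unsupervised",
              diagnostics = fit)
  class(out) <- "meth_cutoff"
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' @export
print.bnmm_fit <- function(x, ...) {
  cat("Two-component normal mixture on log methylation\n")
  cat(sprintf("  n = %d, loglik = %.3f, %d EM iterations, converged: %s\n",
              x$n_obs, x$loglik, x$n_iter, x$converged))
  print(tidy(x))
  invisible(x)
}

#' @export
print.meth_cutoff <- function(x, ...) {
  cat(sprintf("%s methylation cut-off: %.3f%% (rounded: %d%%)\n",
              x$method, x$value_pct, x$value_pct_rounded))
  invisible(x)
}

#' @rdname fit_bnmm
#' @param x A `bnmm_fit` object.
#' @param ... Unused.
#' @export
tidy.bnmm_fit <- function(x, ...) {
  tibble::tibble(
    component = c("unmethylated", "methylated"),
    weight = x$weights, mean_log = x$means, sd_log = x$sds,
    median_pct = exp(x$means)
  )
}

#' @rdname fit_bnmm
#' @export
glance.bnmm_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, n_obs = x$n_obs)
}
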