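#' Build the accelerated-failure-time design for a methylation cut-off
#'
#' Assembles the design matrix of the adjusted survival model: a dichotomized
#' methylation indicator (`marker > cutoff`, so "unmethylated" means at or
#' below the cut-off), age standardized as `(age - 60)/10`, preoperative ECOG
#' performance status as a numeric ordinal term, and extent of resection
#' treatment-coded with gross-total resection (GTR) as reference.
#'
#' @param data Cohort tibble (see [validate_cohort()]).
#' @param cutoff Integer/numeric cut-off in percent; `NULL` omits the
#'   methylation term (covariate-only model).
#' @param marker Column dichotomized by `cutoff` (default `mean_meth`).
#' @return A list of class `aft_design`: `x` (design matrix with intercept),
#'   `time`, `event`, `terms`.
#' @export
aft_design <- function(data, cutoff = NULL, marker = "mean_meth") {
  assert_nonempty_cohort(data, "aft_design")
  needed <- c("os_months", "event", "age", "preop_ps", "resection",
              if (!is.null(cutoff)) marker)
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0) {
    abort(paste0("Design needs column(s): ", paste(miss, collapse = ", ")),
          class = "methtier_design_error")
  }
  res <- factor(data$resection, levels = .resection_levels)
  x <- cbind(
    `(Intercept)` = 1,
    if (!is.null(cutoff)) cbind(methylated = as.numeric(data[[marker]] > cutoff)),
    age_std = (data$age - 60) / 10,
    preop_ps = as.numeric(data$preop_ps),
    resectionNTR = as.numeric(res == "NTR"),
    resectionSTR = as.numeric(res == "STR"),
    resectionbiopsy = as.numeric(res == "biopsy")
  )
  if (anyNA(x) || anyNA(data$os_months) || anyNA(data$event)) {
    abort("Design contains missing values.", class = "methtier_design_error")
  }
  out <- list(x = x, time = as.numeric(data$os_months),
              event = as.integer(data$event), terms = colnames(x))
  class(out) <- "aft_design"
  out
}

# numerically stable log(1 + exp(z))
log1pexp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

#' Log-logistic AFT log-likelihood
#'
#' Censored log-likelihood of the log-logistic accelerated failure time
#' model. With `z_i = (log t_i - x_i' beta) / sigma`, an observed death
#' contributes the log density `z - 2 log(1 + e^z) - log(sigma t)` and a
#' censored observation the log survival `-log(1 + e^z)`.
#'
#' @param beta Coefficient vector matching the columns of `x`.
#' @param sigma Positive scale on the log-time axis.
#' @param x Design matrix (including intercept).
#' @param time Positive survival/censoring times.
#' @param event 1 = death observed, 0 = censored.
#' @return The summed log-likelihood (a scalar).
#' @export
loglogistic_loglik <- function(beta, sigma, x, time, event) {
  if (any(time <= 0)) {
    abort("Survival times must be positive.", class = "methtier_domain_error")
  }
  if (sigma <= 0) abort("sigma must be positive.", class = "methtier_domain_error")
  x <- as.matrix(x)
  z <- (log(time) - drop(x %*% beta)) / sigma
  sum(ifelse(event == 1,
             z - 2 * log1pexp(z) - log(sigma) - log(time),
             -log1pexp(z)))
}

# core censored ML fit over (beta, log sigma) with analytic gradient
fit_loglogistic <- function(time, event, x, init = NULL, tol = 1e-6,
                            max_iter = 200) {
  x <- as.matrix(x)
  if (any(time <= 0)) {
    abort("Survival times must be positive.", class = "methtier_domain_error")
  }
  if (sum(event) < 1) {
    abort("At least one observed event is required to fit the AFT model.",
          class = "methtier_no_events")
  }
  if (qr(x)$rank < ncol(x)) {
    abort("Design matrix is rank deficient.", class = "methtier_design_error")
  }
  p <- ncol(x)
  logt <- log(time)
  if (is.null(init)) {
    init <- c(median(logt), rep(0, p - 1), 0)  # (beta, log sigma)
  }
  ev <- event == 1
  nll <- function(theta) {
    z <- (logt - drop(x %*% theta[1:p])) / exp(theta[p + 1])
    -(sum(z[ev] - 2 * log1pexp(z[ev]) - theta[p + 1] - logt[ev]) +
        sum(-log1pexp(z[!ev])))
  }
  ngr <- function(theta) {
    sigma <- exp(theta[p + 1])
    z <- (logt - drop(x %*% theta[1:p])) / sigma
    f <- plogis(z)
    d_eta <- ifelse(ev, (2 * f - 1) / sigma, f / sigma)
    d_ls <- sum(ifelse(ev, z * (2 * f - 1) - 1, z * f))
    -c(drop(crossprod(x, d_eta)), d_ls)
  }
  opt <- optim(init, nll, ngr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  grad_ok <- function(o) o$convergence == 0 &&
    max(abs(ngr(o$par))) < tol * (1 + abs(o$value))
  if (!grad_ok(opt)) {
    # BFGS can stop on a flat relative value change with the gradient not
    # yet polished; one warm restart settles regular fits, while genuinely
    # separated likelihoods keep drifting and stay flagged
    opt <- optim(opt$par, nll, ngr, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-12))
  }
  converged <- grad_ok(opt)
  if (!converged) {
    warn("Log-logistic AFT fit did not reach gradient convergence; estimates may sit on an unbounded likelihood (separation).")
  }
  beta <- setNames(opt$par[1:p], colnames(x))
  list(beta = beta, scale = exp(opt$par[p + 1]), loglik = -opt$value,
       converged = converged, n = length(time), n_events = sum(event))
}

#' Fit the adjusted log-logistic AFT model at a methylation cut-off
#'
#' Maximum-likelihood fit of the log-logistic accelerated failure time model
#' with the design of [aft_design()]: dichotomized methylation adjusted for
#' age, extent of resection and preoperative performance status.
#' Optimization is quasi-Newton (BFGS) over `(beta, log sigma)` with analytic
#' gradients. Coefficients are on the log-time scale, so `exp(beta)` is a
#' survival-time ratio.
#'
#' @inheritParams aft_design
#' @param init Optional starting values `c(beta, log sigma)`.
#' @param tol Relative gradient tolerance declaring convergence.
#' @param max_iter Maximum BFGS iterations.
#' @return An object of class `loglogistic_aft`: named `beta`, `scale`,
#'   `loglik`, `converged`, `n`, `n_events`, plus the `cutoff`, `marker` and
#'   `terms` used.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n = 200, seed = 3))
#' fit <- fit_aft(sim$cohort, cutoff = 9)
#' tidy(fit)
fit_aft <- function(data, cutoff = NULL, marker = "mean_meth", init = NULL,
                    tol = 1e-6, max_iter = 200) {
  des <- aft_design(data, cutoff = cutoff, marker = marker)
  fit <- fit_loglogistic(des$time, des$event, des$x, init = init,
                         tol = tol, max_iter = max_iter)
  fit$cutoff <- cutoff
  fit$marker <- marker
  fit$terms <- des$terms
  class(fit) <- "loglogistic_aft"
  fit
}

#' Linear predictor of a fitted AFT model
#'
#' Computes `eta = x' beta` for new patients; under the accelerated failure
#' time convention a higher `eta` predicts longer survival.
#'
#' @param fit A [fit_aft()] object.
#' @param data Cohort rows with the columns the fit used.
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(fit, data) {
  des <- aft_design(data, cutoff = fit$cutoff, marker = fit$marker)
  if (!identical(colnames(des$x), names(fit$beta))) {
    abort("Design terms do not match the fitted model.",
          class = "methtier_design_error")
  }
  drop(des$x %*% fit$beta)
}

#' Harrell's concordance index
#'
#' Proportion of comparable patient pairs for which the predicted and
#' observed survival orderings agree. A pair is comparable when the patient
#' with the shorter observed time had an event, or when times are tied and
#' exactly one patient had an event (the event-bearer counted as the earlier
#' death). The pair is concordant when the longer-surviving patient has a
#' strictly higher prediction; tied predictions count 0.5.
#'
#' @param times Observed times.
#' @param events Event indicators (1 death, 0 censored).
#' @param predictions Linear predictors where larger means longer predicted
#'   survival.
#' @return A list of class `concordance_result`: `c_index`,
#'   `n_comparable_pairs`, `n_concordant`, `n_tied`.
#' @export
concordance_index <- function(times, events, predictions) {
  n <- length(times)
  if (length(events) != n || length(predictions) != n) {
    abort("times, events and predictions must have equal length.",
          class = "methtier_input_error")
  }
  n_pairs <- n_conc <- 0
  n_tied <- 0
  for (i in which(events == 1)) {
    cmp <- (times > times[i]) | (times == times[i] & events == 0)
    cmp[i] <- FALSE
    n_pairs <- n_pairs + sum(cmp)
    n_conc <- n_conc + sum(predictions[cmp] > predictions[i])
    n_tied <- n_tied + sum(predictions[cmp] == predictions[i])
  }
  if (n_pairs == 0) {
    abort("No comparable pairs (e.g. all observations censored).",
          class = "methtier_no_pairs")
  }
  out <- list(c_index = (n_conc + 0.5 * n_tied) / n_pairs,
              n_comparable_pairs = n_pairs,
              n_concordant = n_conc, n_tied = n_tied)
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f (%d comparable pairs, %d concordant, %d tied)\n",
              x$c_index, x$n_comparable_pairs, x$n_concordant, x$n_tied))
  invisible(x)
}

#' @export
print.loglogistic_aft <- function(x, ...) {
  cat("Log-logistic AFT model")
  if (!is.null(x$cutoff)) cat(sprintf(" (methylated = %s > %g%%)", x$marker, x$cutoff))
  cat(sprintf("\n  n = %d (%d events), scale = %.4f, loglik = %.3f\n",
              x$n, x$n_events, x$scale, x$loglik))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_aft
#' @param x A `loglogistic_aft` object.
#' @param ... Unused.
#' @export
tidy.loglogistic_aft <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 time_ratio = exp(unname(x$beta)))
}

#' @rdname fit_aft
#' @export
glance.loglogistic_aft <- function(x, ...) {
  tibble::tibble(scale = x$scale, loglik = x$loglik, converged = x$converged,
                 n = x$n, n_events = x$n_events)
}
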