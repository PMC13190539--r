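# Independent oracles used across the suite. These deliberately use naive
# formulations (exhaustive loops, grid scans, term-by-term sums) so they
# share no code path with the package implementation.

# exhaustive comparable-pair concordance (Harrell's rules)
oracle_concordance <- function(time, event, pred) {
  n <- length(time)
  np <- nc <- nt <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (time[j] > time[i]) ||
        (time[j] == time[i] && event[j] == 0)
      if (!comparable) next
      np <- np + 1
      if (pred[j] > pred[i]) nc <- nc + 1
      else if (pred[j] == pred[i]) nt <- nt + 1
    }
  }
  list(c_index = (nc + 0.5 * nt) / np, n_pairs = np,
       n_concordant = nc, n_tied = nt)
}

# two-group log-rank chi-square from a hand-built O/E/V table
oracle_logrank <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb)
  grp <- rep(0:1, c(length(ta), length(tb)))
  O <- E <- V <- 0
  for (tk in sort(unique(time[event == 1]))) {
    at_risk <- time >= tk
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 0)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & grp == 0)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(chi_square = chi, p_value = pchisq(chi, 1, lower.tail = FALSE))
}

# sign-change scan of the weighted component density difference at 1e-6
# resolution (coarse bracket, then a 1e-6-step scan inside the bracket)
oracle_intersection <- function(w, mu, s) {
  f <- function(x) w[1] * dnorm(x, mu[1], s[1]) - w[2] * dnorm(x, mu[2], s[2])
  xs <- seq(mu[1], mu[2], by = 1e-3)
  d <- f(xs)
  i <- which(d[-length(d)] > 0 & d[-1] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  fine <- seq(xs[i], xs[i + 1], by = 1e-6)
  df <- f(fine)
  j <- which(df[-length(df)] > 0 & df[-1] <= 0)[1]
  fine[j]
}

# log-logistic log-likelihood assembled observation by observation
oracle_loglogistic_loglik <- function(beta, sigma, x, time, event) {
  total <- 0
  for (i in seq_along(time)) {
    z <- (log(time[i]) - sum(x[i, ] * beta)) / sigma
    total <- total + if (event[i] == 1) {
      z - 2 * log(1 + exp(z)) - log(sigma) - log(time[i])
    } else {
      -log(1 + exp(z))
    }
  }
  total
}

# construct a mixture-fit object directly from parameters
make_bnmm <- function(w, mu, s, floor_pct = 0.5) {
  structure(list(weights = w, means = mu, sds = s, loglik = NA_real_,
                 loglik_trace = numeric(0), n_iter = 0L, converged = TRUE,
                 n_obs = 0L, floor_pct = floor_pct),
            class = "bnmm_fit")
}

# small hand-writable cohort
toy_cohort <- function(n = 6, mean_meth = NULL) {
  mm <- mean_meth %||% seq(2, 30, length.out = n)
  tibble::tibble(
    patient_id = paste0("T", seq_len(n)),
    cpg76 = mm, cpg77 = mm, cpg78 = mm, cpg79 = mm,
    mean_meth = mm,
    age = seq(45, 75, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    preop_ps = rep(0:2, length.out = n),
    resection = rep(c("GTR", "NTR", "STR", "biopsy"), length.out = n),
    os_months = seq(5, 30, length.out = n),
    event = rep(c(1, 1, 0), length.out = n)
  )
}

# cohort whose survival depends sharply on mean_meth exceeding `threshold`
sharp_cohort <- function(n, seed, threshold = 10, effect = 0.9,
                         sigma = 0.5) {
  base <- simulate_cohort(sim_config(n = n, seed = seed))$cohort
  withr::with_seed(seed + 1000L, {
    eta <- 2.6 + effect * (base$mean_meth > threshold) -
      0.1 * (base$age - 60) / 10 - 0.15 * base$preop_ps
    lat <- exp(eta + sigma * rlogis(n))
    cens <- runif(n, 44, 116)
    base$os_months <- pmin(lat, cens)
    base$event <- as.integer(lat <= cens)
  })
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a
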