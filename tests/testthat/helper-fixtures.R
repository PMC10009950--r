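# shared fixtures and independent reference implementations

# minimal cohort data frame: n subjects with benign covariates and
# marker values placing everyone in A-T-N- unless overridden
make_cohort_df <- function(n = 6L, ...) {
  df <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    age = seq(65, 75, length.out = n),
    sex = rep_len(c(0, 1), n),
    education = 14 + 3 * sin(seq_len(n)),
    ticv = 1400 + 60 * cos(2 * seq_len(n)),
    wmh = 2 + (seq_len(n) %% 5),
    abeta_ratio = rep(0.11, n),
    ptau = rep(40, n),
    ttau = rep(300, n),
    hippocampal_volume = rep(3100, n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

# outcome vector with given means per ACH position, groups repeated
# blockwise; returns list(y, groups)
planted_outcome <- function(means, n_per = 5L, sd = 0,
                            states = ad_continuum_states()) {
  groups <- rep(states, each = n_per)
  mu <- rep(means, each = n_per)
  y <- mu + if (sd > 0) stats::rnorm(length(mu), 0, sd) else 0
  list(y = y, groups = groups)
}

# reference Benjamini-Hochberg step-up: independent of the package path
ref_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  crit <- ps <= seq_len(m) / m * q
  k <- if (any(crit)) max(which(crit)) else 0L
  rejected <- logical(m)
  if (k > 0L) rejected[o[seq_len(k)]] <- TRUE
  qv <- rev(cummin(rev(ps * m / seq_len(m))))
  qvalues <- numeric(m)
  qvalues[o] <- pmin(qv, 1)
  list(rejected = rejected, qvalues = qvalues)
}

# analytic equal-posterior boundary of a two-component Gaussian mixture,
# solved by root finding on the log-density difference (independent of
# the package's internal routine)
analytic_mixture_cutoff <- function(mu, sig, w) {
  f <- function(x) {
    log(w[1]) + stats::dnorm(x, mu[1], sig[1], log = TRUE) -
      log(w[2]) - stats::dnorm(x, mu[2], sig[2], log = TRUE)
  }
  stats::uniroot(f, c(mu[1], mu[2]), tol = 1e-12)$root
}

# exhaustive active-set oracle for the monotone fit: brute force over all
# 2^3 patterns of pinned successive differences, each solved by lm()
oracle_monotone_sse <- function(y, X, Z = NULL) {
  best <- Inf
  for (code in 0:7) {
    active <- c(2, 3, 4)[as.logical(bitwAnd(code, c(1L, 2L, 4L)))]
    free <- setdiff(1:4, active)
    Xp <- cbind(X[, free, drop = FALSE], Z)
    fit <- stats::lm.fit(Xp, y)
    beta <- numeric(4)
    beta[free] <- fit$coefficients[seq_along(free)]
    if (any(beta[2:4] > 1e-10, na.rm = TRUE)) next
    best <- min(best, sum(fit$residuals^2))
  }
  best
}
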