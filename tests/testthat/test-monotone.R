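ach <- conversion_paths()[["ACH"]]

test_that("the design codes first-group mean plus successive differences", {
  po <- planted_outcome(c(4, 3, 2, 1), n_per = 5L)
  des <- build_design(po$groups, ach)
  expect_equal(dim(des$X), c(20L, 4L))
  expect_equal(des$counts, rep(5L, 4L))
  # column g indicates position >= g, so mean of group g = sum(beta[1:g])
  expect_equal(des$X[1L, ], c(1, 0, 0, 0))
  expect_equal(des$X[20L, ], c(1, 1, 1, 1))
  # subjects outside the sequence's states are excluded and counted
  groups2 <- c(po$groups, "A-T+N-")
  des2 <- build_design(groups2, ach)
  expect_equal(des2$n_excluded, 1L)
  expect_length(des2$included, 20L)
  # centered covariates
  des3 <- build_design(po$groups, ach,
                       covariates = data.frame(age = rnorm(20, 70, 5)))
  expect_lt(abs(sum(des3$Z[, 1L])), 1e-10)
  expect_error(build_design(rep(ach$states, times = c(5, 5, 5, 2)), ach),
               "A\\+T\\+N\\+")
})

test_that("already-monotone data is fit exactly with inactive constraints", {
  po <- planted_outcome(c(10, 8, 5, 5), n_per = 5L)
  fit <- fit_monotone(po$y, build_design(po$groups, ach))
  expect_equal(fit$beta1, 10)
  expect_equal(fit$beta_diffs, c(-2, -3, 0))
  expect_lt(fit$sse, 1e-20)
  un <- fit_unconstrained(po$y, build_design(po$groups, ach))
  expect_equal(un$beta, c(10, -2, -3, 0))
})

test_that("violating means are pooled like PAVA", {
  po <- planted_outcome(c(5, 6, 4, 3), n_per = 5L)
  fit <- fit_monotone(po$y, build_design(po$groups, ach))
  expect_equal(fit$fitted_means, c(5.5, 5.5, 4, 3))
  # general PAVA equivalence: equal weights, random means
  set.seed(10)
  for (i in 1:20) {
    mu <- rnorm(4)
    po <- planted_outcome(mu, n_per = 4L, sd = 0.5)
    fit <- fit_monotone(po$y, build_design(po$groups, ach))
    gm <- tapply(po$y, match(po$groups, ach$states), mean)
    iso <- -stats::isoreg(1:4, -as.numeric(gm))$yf   # antitonic PAVA
    expect_equal(fit$fitted_means, unname(iso), tolerance = 1e-10)
  }
})

test_that("the active-set solution equals independent oracles", {
  set.seed(11)
  for (i in 1:40) {
    n_per <- sample(3:8, 4L, replace = TRUE)
    groups <- rep(ach$states, times = n_per)
    n <- length(groups)
    Zdf <- data.frame(matrix(rnorm(n * 5L), n, 5L))
    y <- rnorm(n, rep(rnorm(4, 0, 2), times = n_per), 1)
    des <- build_design(groups, ach, Zdf)
    fit <- fit_monotone(y, des)
    # oracle 1: exhaustive pattern enumeration via lm.fit
    sse_oracle <- oracle_monotone_sse(y, des$X, des$Z)
    expect_equal(fit$sse, sse_oracle, tolerance = 1e-8)
    # invariants
    expect_true(all(fit$beta_diffs <= 1e-10))
    expect_true(all(diff(fit$fitted_means) <= 1e-10))
    un <- fit_unconstrained(y, des)
    expect_gte(fit$sse + 1e-10, un$sse)
  }
  # oracle 2: quadratic-programming route on a handful of instances
  if (requireNamespace("pracma", quietly = TRUE)) {
    set.seed(12)
    for (i in 1:5) {
      groups <- rep(ach$states, each = 5L)
      y <- rnorm(20, rep(rnorm(4), each = 5L))
      Zdf <- data.frame(z1 = rnorm(20), z2 = rnorm(20))
      des <- build_design(groups, ach, Zdf)
      fit <- fit_monotone(y, des)
      X <- cbind(des$X, des$Z)
      A <- matrix(0, 3L, ncol(X)); A[cbind(1:3, 2:4)] <- 1
      beta_qp <- pracma::lsqlincon(X, y, A = A, b = rep(0, 3L))
      expect_equal(fit$sse, sum((y - X %*% beta_qp)^2), tolerance = 1e-6)
    }
  }
})

test_that("unconstrained standard errors match the closed form", {
  set.seed(13)
  groups <- rep(ach$states, each = 3L)
  y <- rnorm(12L, rep(c(5, 4, 3, 2), each = 3L))
  des <- build_design(groups, ach)
  un <- fit_unconstrained(y, des)
  X <- des$X
  sigma2 <- un$sse / (12L - 4L)
  se_hand <- sqrt(sigma2 * diag(solve(t(X) %*% X)))
  expect_equal(un$se, unname(se_hand), tolerance = 1e-10)
})

test_that("BIC follows n log(SSE/n) + k log(n) and ranks by SSE", {
  fake <- list(sse = 2.0, n = 8L, k = 5L, active = c(FALSE, FALSE, FALSE))
  expect_equal(bic(fake), 8 * log(0.25) + 5 * log(8))
  expect_equal(bic(fake), -0.693147, tolerance = 1e-5)
  expect_equal(bic(list(sse = 3, n = 20L, k = 5L)),
               bic(list(sse = 3, n = 20L, k = 5L)))
  expect_lt(bic(list(sse = 1.5, n = 8L, k = 5L)), bic(fake))
  expect_warning(b0 <- bic(list(sse = 0, n = 8L, k = 5L)), "zero")
  expect_identical(b0, -Inf)
  expect_error(bic(list(sse = 1, n = 4L, k = 5L)), "n <= k")
  # effective-dimension mode drops active constraints from k
  fake$active <- c(TRUE, FALSE, TRUE)
  expect_equal(bic(fake, "effective"), 8 * log(0.25) + 3 * log(8))
})

test_that("sequence comparison prefers the generating order", {
  ps <- permutation_sequences()
  po <- planted_outcome(c(10, 9, 7, 4), n_per = 5L)
  # single-sequence set
  one <- sequence_set(list(ps[["ACH"]]), reference = "ACH")
  cmp1 <- suppressWarnings(compare_sequences(po$y, po$groups,
                                             sequences = one))
  expect_identical(cmp1$winner, "ACH")
  expect_equal(cmp1$reference_rank, 1L)
  # noiseless strictly decreasing along ACH: its SSE is 0, BIC minimal
  cmp <- suppressWarnings(compare_sequences(po$y, po$groups,
                                            sequences = ps))
  expect_identical(cmp$winner, "ACH")
  expect_equal(cmp$reference_rank, 1L)
  expect_equal(cmp$table$sse[cmp$table$sequence == "ACH"], 0,
               tolerance = 1e-20)
  # reversed data: the reversed permutation wins, ACH does not
  po_rev <- planted_outcome(c(4, 7, 9, 10), n_per = 5L)
  cmp_rev <- suppressWarnings(compare_sequences(po_rev$y, po_rev$groups,
                                                sequences = ps))
  expect_identical(ps[[cmp_rev$winner]]$states, rev(ach$states))
  expect_gt(cmp_rev$reference_rank, 1L)
})

test_that("comparison commutes with relabeling the groups", {
  ps <- permutation_sequences()
  set.seed(14)
  po <- planted_outcome(c(8, 6, 5, 1), n_per = 6L, sd = 1)
  cmp <- compare_sequences(po$y, po$groups, sequences = ps)
  # relabel by a permutation pi of the four states
  pi <- c(3L, 1L, 4L, 2L)
  states <- ach$states
  relabeled <- states[pi[match(po$groups, states)]]
  cmp2 <- compare_sequences(po$y, relabeled, sequences = ps)
  w1 <- states[pi[match(ps[[cmp$winner]]$states, states)]]
  expect_identical(ps[[cmp2$winner]]$states, w1)
  # BIC ranking equals SSE ranking at fixed k, n
  expect_identical(order(cmp$table$bic), order(cmp$table$sse))
})

test_that("sequences failing the group-count precondition are dropped", {
  # TAN's four states are well populated; ACH's second state (A+T-N-)
  # has only 2 subjects, below the default minimum of 3
  tan <- conversion_paths()[["TAN"]]
  groups <- c(rep(tan$states, each = 4L), rep("A+T-N-", 2L))
  y <- c(rep(c(5, 4, 3, 2), each = 4L), 4.5, 4.4)
  cp <- conversion_paths()
  w <- capture_warnings(cmp <- compare_sequences(y, groups,
                                                 sequences = cp))
  expect_true(any(grepl("dropping sequence ACH", w)))
  expect_false("ACH" %in% cmp$table$sequence)
  expect_true("TAN" %in% cmp$table$sequence)
  expect_error(suppressWarnings(
    compare_sequences(y, rep("A-T+N+", length(y)), sequences = cp)),
    "no sequence")
})

test_that("the trend test is one-sided for decline", {
  set.seed(15)
  # planted increase: one-sided p above one half
  po_up <- planted_outcome(c(1, 2, 3, 4), n_per = 10L, sd = 1)
  tt_up <- trend_test(po_up$y, po_up$groups, sequence = ach)
  expect_gt(tt_up$p, 0.5)
  # strong decline: 2 residual SD per step at 40 per group
  po_dn <- planted_outcome(c(8, 6, 4, 2), n_per = 40L, sd = 1)
  tt_dn <- trend_test(po_dn$y, po_dn$groups, sequence = ach)
  expect_lt(tt_dn$p, 1e-6)
  expect_lt(tt_dn$t, 0)
})

test_that("model SSEs nest: unconstrained <= constrained <= covariate-only", {
  set.seed(16)
  n <- 40L
  groups <- rep(ach$states, each = 10L)
  Zdf <- data.frame(age = rnorm(n, 70, 5), wmh = rlnorm(n, 1, 0.5))
  y <- rnorm(n, rep(c(5, 6, 3, 2), each = 10L))
  des <- build_design(groups, ach, Zdf)
  con <- fit_monotone(y, des)
  un <- fit_unconstrained(y, des)
  Znull <- cbind(1, des$Z)
  sse_null <- sum(stats::lm.fit(Znull, y)$residuals^2)
  expect_lte(un$sse, con$sse + 1e-10)
  expect_lte(con$sse, sse_null + 1e-10)
})
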