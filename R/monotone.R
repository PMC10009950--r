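#' Build the design for a monotone-decline fit along a sequence
#'
#' The mean structure codes the first coefficient as the mean of the first
#' sequence position and each further coefficient as the successive
#' difference between adjacent positions, i.e. column g is the indicator
#' of position >= g. Covariates are mean-centered over the included
#' subjects and shared (unconstrained) across sequence models.
#'
#' @param groups Character vector of per-subject ATN group labels (`NA`
#'   allowed; such subjects are excluded).
#' @param sequence A [group_sequence()].
#' @param covariates Optional numeric matrix / data frame of per-subject
#'   covariate values (rows aligned with `groups`).
#' @param min_group_n Minimum subjects required at each sequence position.
#' @return A `design_spec`: mean-structure matrix `X` (n x 4), centered
#'   covariate matrix `Z` (or `NULL`), `position`, `included` (row indices
#'   into the input), `counts`, `n_excluded`, and the sequence.
#' @export
build_design <- function(groups, sequence, covariates = NULL,
                         min_group_n = 3L) {
  stopifnot(inherits(sequence, "group_sequence"))
  pos_all <- match(groups, sequence$states)
  included <- which(!is.na(pos_all))
  if (!is.null(covariates)) {
    Z_all <- as.matrix(as.data.frame(covariates))
    storage.mode(Z_all) <- "double"
    if (nrow(Z_all) != length(groups)) {
      stop("covariate rows (", nrow(Z_all),
           ") disagree with groups length (", length(groups), ")",
           call. = FALSE)
    }
    included <- included[stats::complete.cases(Z_all[included, ,
                                                     drop = FALSE])]
  }
  pos <- pos_all[included]
  counts <- tabulate(pos, nbins = 4L)
  low <- which(counts < min_group_n)
  if (length(low)) {
    stop("insufficient subjects at sequence position(s) ",
         paste0(low, " (", sequence$states[low], ", n=", counts[low],
                collapse = "; "),
         "); need >= ", min_group_n, call. = FALSE)
  }
  X <- vapply(1:4, function(g) as.numeric(pos >= g), numeric(length(pos)))
  Z <- NULL
  if (!is.null(covariates)) {
    Z <- Z_all[included, , drop = FALSE]
    Z <- sweep(Z, 2L, colMeans(Z))
    if (qr(Z)$rank < ncol(Z)) {
      stop("covariate matrix is rank deficient over included subjects",
           call. = FALSE)
    }
  }
  structure(list(X = X, Z = Z, position = pos, included = included,
                 counts = counts,
                 n_excluded = length(groups) - length(included),
                 sequence = sequence),
            class = "design_spec")
}

# OLS of y (vector or matrix, columns = outcomes) on X; returns
# coefficients, SSE per outcome and the qr object.
ols_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix rank deficient", call. = FALSE)
  coef <- qr.coef(qx, y)
  res <- y - X %*% coef
  sse <- if (is.matrix(y)) colSums(res^2) else sum(res^2)
  list(coef = coef, sse = sse, qr = qx, residuals = res)
}

#' Constrained least-squares fit of monotone decline along a sequence
#'
#' Minimizes the residual sum of squares subject to the three successive
#' group-difference coefficients being non-positive (covariate
#' coefficients unconstrained), which encodes a monotone decline of the
#' adjusted position means. Solved exactly by enumerating all 2^3 patterns
#' of active constraints (a coefficient pinned to zero), keeping the
#' feasible pattern with minimal SSE; deterministic.
#'
#' @param y Numeric outcome, aligned with the full `groups` vector the
#'   design was built from (it is subset to the design's included rows) or
#'   already of included length.
#' @param design A [build_design()] result.
#' @return A `constrained_fit`: `beta1`, `beta_diffs` (3, all <= 0),
#'   `covariate_coef`, `fitted_means` (4, non-increasing), `sse`, `n`, `k`,
#'   `active` (constraint flags), `df_residual`.
#' @export
fit_monotone <- function(y, design) {
  y <- design_outcome(y, design)
  X <- design$X
  Z <- design$Z
  q <- if (is.null(Z)) 0L else ncol(Z)
  best <- NULL
  # patterns ordered by number of active constraints: unconstrained first
  patterns <- list(integer(0), 2L, 3L, 4L, c(2L, 3L), c(2L, 4L),
                   c(3L, 4L), c(2L, 3L, 4L))
  for (active in patterns) {
    free <- setdiff(1:4, active)
    Xp <- cbind(X[, free, drop = FALSE], Z)
    fit <- tryCatch(ols_fit(Xp, y), error = function(e) NULL)
    if (is.null(fit)) next
    beta <- numeric(4L)
    beta[free] <- fit$coef[seq_along(free)]
    if (any(beta[2:4] > 1e-10)) next
    if (is.null(best) || fit$sse < best$sse - 1e-12 * max(1, best$sse)) {
      best <- list(sse = fit$sse, beta = beta, active = active,
                   zcoef = if (q) fit$coef[length(free) + seq_len(q)]
                           else numeric(0))
    }
  }
  # the all-active pattern is always feasible, so best is never NULL
  n <- length(y)
  structure(list(
    beta1 = best$beta[1L],
    beta_diffs = best$beta[2:4],
    covariate_coef = best$zcoef,
    fitted_means = cumsum(best$beta),
    sse = best$sse,
    n = n,
    k = 4L + q + 1L,
    active = 2:4 %in% best$active,
    df_residual = n - (4L - sum(2:4 %in% best$active)) - q,
    sequence = design$sequence$name
  ), class = "constrained_fit")
}

#' @export
print.constrained_fit <- function(x, ...) {
  cat("monotone fit along ", x$sequence, ": fitted means ",
      paste(signif(x$fitted_means, 5), collapse = " >= "),
      ", SSE = ", signif(x$sse, 6), "\n", sep = "")
  invisible(x)
}

#' Ordinary least-squares fit on the same design (unconstrained)
#'
#' @param y Outcome vector (full-cohort or included length).
#' @param design A [build_design()] result.
#' @return List with `beta` (4 mean-structure coefficients),
#'   `covariate_coef`, `fitted_means`, `sse`, `se` (coefficient standard
#'   errors, textbook closed form), `n`, `k`, `df_residual`.
#' @export
fit_unconstrained <- function(y, design) {
  y <- design_outcome(y, design)
  Xfull <- cbind(design$X, design$Z)
  fit <- ols_fit(Xfull, y)
  q <- if (is.null(design$Z)) 0L else ncol(design$Z)
  n <- length(y)
  dfres <- n - ncol(Xfull)
  sigma2 <- fit$sse / dfres
  XtXinv <- chol2inv(qr.R(fit$qr)[, order(fit$qr$pivot), drop = FALSE])
  list(beta = fit$coef[1:4],
       covariate_coef = if (q) fit$coef[4L + seq_len(q)] else numeric(0),
       fitted_means = cumsum(fit$coef[1:4]),
       sse = fit$sse,
       se = sqrt(sigma2 * diag(XtXinv)),
       n = n, k = 4L + q + 1L, df_residual = dfres)
}

#' BIC of a Gaussian residual model from its SSE
#'
#' BIC = n log(SSE / n) + k log(n), with k counting all 4 mean-structure
#' coefficients, the covariate coefficients, and the residual variance.
#' Because k and n are identical across candidate sequences fitted on the
#' same subjects, ranking sequences by this BIC is equivalent to ranking
#' by SSE. `k_mode = "effective"` instead counts only mean-structure
#' coefficients whose monotonicity constraint is inactive (sensitivity
#' analysis).
#'
#' @param fit A [fit_monotone()] result (or any list with `sse`, `n`, `k`,
#'   `active`).
#' @param k_mode "full" (default) or "effective".
#' @return The BIC value; `-Inf` with a warning when SSE is zero.
#' @export
bic <- function(fit, k_mode = c("full", "effective")) {
  k_mode <- match.arg(k_mode)
  k <- fit$k
  if (k_mode == "effective" && !is.null(fit$active)) {
    k <- k - sum(fit$active)
  }
  if (fit$n <= k) stop("BIC undefined: n <= k", call. = FALSE)
  if (fit$sse <= 0) {
    warning("SSE is zero; returning -Inf BIC", call. = FALSE)
    return(-Inf)
  }
  fit$n * log(fit$sse / fit$n) + k * log(fit$n)
}

#' Compare candidate progression sequences by BIC
#'
#' Fits the constrained monotone model for every sequence in the set and
#' ranks them by BIC (minimal BIC wins). Ties (delta BIC below 1e-9) are
#' broken by canonical sequence order and flagged. Sequences whose design
#' preconditions fail on this cohort are dropped with a warning.
#'
#' @param y Outcome per subject (e.g. an ROI volume), aligned with
#'   `groups`.
#' @param groups Per-subject ATN group labels.
#' @param covariates Optional covariate matrix / data frame.
#' @param sequences A [sequence_set()] or a set name ("permutations24",
#'   "paths6").
#' @param min_group_n Minimum subjects per sequence position.
#' @param k_mode Passed to [bic()].
#' @return A `model_comparison`: `table` (data frame with sequence, sse,
#'   bic, n, k, n_active), `winner`, `delta_runner_up`, `reference`,
#'   `reference_rank`, `tie`, and the per-sequence `fits`.
#' @export
compare_sequences <- function(y, groups, covariates = NULL,
                              sequences = permutation_sequences(),
                              min_group_n = 3L, k_mode = "full") {
  sequences <- resolve_sequences(sequences)
  reference <- attr(sequences, "reference")
  fits <- list()
  rows <- list()
  for (s in sequences) {
    des <- tryCatch(build_design(groups, s, covariates, min_group_n),
                    error = function(e) e)
    if (inherits(des, "error")) {
      warning("dropping sequence ", s$name, ": ", conditionMessage(des),
              call. = FALSE)
      next
    }
    fit <- fit_monotone(y, des)
    fits[[s$name]] <- fit
    rows[[s$name]] <- data.frame(
      sequence = s$name, sse = fit$sse,
      bic = suppressWarnings(bic(fit, k_mode)),
      n = fit$n, k = fit$k, n_active = sum(fit$active),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no sequence satisfied the design preconditions", call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # canonical (set) order breaks ties: which.min keeps the first minimum
  win_idx <- which.min(tab$bic)
  others <- tab$bic[-win_idx]
  delta <- if (length(others)) min(others) - tab$bic[win_idx] else Inf
  if (is.nan(delta)) delta <- 0   # several exact (zero-SSE) fits tie
  ref_rank <- if (reference %in% tab$sequence) {
    order_idx <- order(tab$bic, seq_len(nrow(tab)))
    match(match(reference, tab$sequence), order_idx)
  } else NA_integer_
  structure(list(table = tab,
                 winner = tab$sequence[win_idx],
                 delta_runner_up = delta,
                 reference = reference,
                 reference_rank = ref_rank,
                 tie = is.finite(delta) && delta < 1e-9,
                 fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison over", nrow(x$table), "sequences: winner",
      x$winner, if (x$tie) "(tie)" else "",
      "| reference", x$reference, "rank", x$reference_rank, "\n")
  tab <- x$table[order(x$table$bic), ]
  print(utils::head(tab, 6L), row.names = FALSE)
  invisible(x)
}

#' One-sided trend test for volume decline along a sequence
#'
#' Ordinary least squares with the sequence position (1..4, centered)
#' entered as a linear regressor plus covariates; the t statistic is the
#' position slope over its standard error and the one-sided p-value tests
#' for decline (negative slope).
#'
#' @inheritParams compare_sequences
#' @param sequence A [group_sequence()].
#' @return List with `t`, `p` (one-sided, decline), `slope`, `se`, `df`,
#'   `n`.
#' @export
trend_test <- function(y, groups, covariates = NULL, sequence,
                       min_group_n = 3L) {
  des <- build_design(groups, sequence, covariates, min_group_n)
  y <- design_outcome(y, des)
  pos <- des$position - mean(des$position)
  X <- cbind(1, pos, des$Z)
  fit <- ols_fit(X, y)
  dfres <- length(y) - ncol(X)
  sigma2 <- fit$sse / dfres
  XtXinv <- chol2inv(qr.R(fit$qr)[, order(fit$qr$pivot), drop = FALSE])
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tval <- fit$coef[2L] / se
  list(t = unname(tval), p = unname(stats::pt(tval, dfres)),
       slope = unname(fit$coef[2L]), se = unname(se), df = dfres,
       n = length(y))
}

# subset a full-length outcome to a design's included rows (accepts an
# already-subset vector too)
design_outcome <- function(y, design) {
  y <- as.numeric(y)
  n_inc <- length(design$included)
  if (length(y) == n_inc) {
    # ambiguous only if the design excluded nobody; then both agree
  } else if (length(y) >= max(design$included)) {
    y <- y[design$included]
  } else {
    stop("outcome length (", length(y),
         ") matches neither the cohort nor the design", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("outcome contains non-finite values",
                               call. = FALSE)
  y
}
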