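#' Covariate-adjust hippocampal volume
#'
#' Residualizes raw hippocampal volume (ul) on the covariates via ordinary
#' least squares and re-centers at the grand mean of the raw volumes among
#' the fitted subjects, so the adjusted scale stays interpretable in ul.
#' Subjects with a missing volume or covariate get `NA`.
#'
#' @param cohort A [cohort_table()].
#' @param covariates Covariate column names (default age, sex, education,
#'   TICV, WMH).
#' @param subset Optional logical vector restricting the subjects the model
#'   is *fitted* on (e.g. biomarker-negative subjects); adjusted values are
#'   still produced for every subject with complete data.
#' @return List with `adjusted` (numeric per subject, ul) and `model`
#'   (an `adjustment_model`: coefficients, grand mean, R^2, residual SD).
#' @export
adjust_volume <- function(cohort,
                          covariates = c("age", "sex", "education",
                                         "ticv", "wmh"),
                          subset = NULL) {
  df <- as.data.frame(cohort)
  bad <- setdiff(covariates, names(df))
  if (length(bad)) {
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  y <- df$hippocampal_volume
  X <- as.matrix(df[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  complete <- stats::complete.cases(X) & !is.na(y)
  fit_on <- if (is.null(subset)) complete else complete & subset
  if (sum(fit_on) < length(covariates) + 2L) {
    stop("need at least ", length(covariates) + 2L,
         " subjects with complete data to fit the adjustment model",
         call. = FALSE)
  }
  Xf <- cbind(`(Intercept)` = 1, X[fit_on, , drop = FALSE])
  qx <- qr(Xf)
  if (qx$rank < ncol(Xf)) {
    drop_cols <- colnames(Xf)[qx$pivot[(qx$rank + 1L):ncol(Xf)]]
    stop("covariate matrix is rank deficient (collinear: ",
         paste(drop_cols, collapse = ", "), ")", call. = FALSE)
  }
  beta <- qr.coef(qx, y[fit_on])
  grand_mean <- mean(y[fit_on])
  resid_fit <- y[fit_on] - drop(Xf %*% beta)
  model <- structure(list(
    coefficients = beta,
    covariates = covariates,
    grand_mean = grand_mean,
    r_squared = 1 - sum(resid_fit^2) /
      sum((y[fit_on] - grand_mean)^2),
    residual_sd = sqrt(sum(resid_fit^2) /
                         (sum(fit_on) - ncol(Xf)))
  ), class = "adjustment_model")
  adjusted <- rep(NA_real_, nrow(df))
  pred <- drop(cbind(1, X[complete, , drop = FALSE]) %*% beta)
  adjusted[complete] <- y[complete] - pred + grand_mean
  names(adjusted) <- df$subject_id
  list(adjusted = adjusted, model = model)
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("hippocampal-volume adjustment model (", length(x$covariates),
      " covariates)\n  R^2 = ", signif(x$r_squared, 3),
      ", residual SD = ", signif(x$residual_sd, 4), " ul\n", sep = "")
  invisible(x)
}

#' Apply a fitted adjustment model to new subjects
#'
#' @param model An `adjustment_model` from [adjust_volume()].
#' @param cohort A [cohort_table()] with the model's covariates.
#' @return Adjusted volumes (ul), `NA` where data are incomplete.
#' @export
apply_adjustment <- function(model, cohort) {
  df <- as.data.frame(cohort)
  X <- as.matrix(df[, model$covariates, drop = FALSE])
  storage.mode(X) <- "double"
  y <- df$hippocampal_volume
  complete <- stats::complete.cases(X) & !is.na(y)
  out <- rep(NA_real_, nrow(df))
  pred <- drop(cbind(1, X[complete, , drop = FALSE]) %*% model$coefficients)
  out[complete] <- y[complete] - pred + model$grand_mean
  names(out) <- df$subject_id
  out
}

#' Estimate a biomarker cutoff by two-component Gaussian mixture
#'
#' Fits a univariate 2-component Gaussian mixture and returns the point
#' strictly between the two component means where the posterior membership
#' probabilities are equal. Degenerate fits are rejected (the caller may
#' fall back to a fixed cutoff): component means closer than half the
#' pooled component SD, or a fitted mixture whose density has no dip
#' between the means (as happens when EM splits a unimodal sample into
#' two heavily overlapping components).
#'
#' @param values Numeric marker values (at least 20 finite).
#' @param seed Integer seed (the fit is deterministic given the data; the
#'   seed is set for reproducibility of any randomized initialization).
#' @return The cutoff (marker units), with the mixture parameters attached
#'   as attributes `means`, `sds`, `weights` and `provenance = "gmm"`.
#' @importFrom mclust Mclust mclustBIC
#' @export
estimate_gmm_cutoff <- function(values, seed = 1L) {
  v <- values[is.finite(values)]
  if (length(v) < 20L) {
    stop("need at least 20 finite values for mixture estimation",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  fit <- Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) fit <- Mclust(v, G = 2, modelNames = "E",
                                  verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1L) sig <- rep(sig, 2L)
  w <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  mu <- mu[o]; sig <- sig[o]; w <- w[o]
  pooled_sd <- sqrt(mean(sig^2))
  if (diff(mu) < 0.5 * pooled_sd) {
    stop("degenerate mixture: component means separated by ",
         signif(diff(mu), 3), " < 0.5 pooled SD (", signif(pooled_sd, 3),
         ")", call. = FALSE)
  }
  if (!mixture_is_bimodal(mu, sig, w)) {
    stop("degenerate mixture: no density dip between the component means ",
         "(sample looks unimodal)", call. = FALSE)
  }
  cut <- equal_posterior_point(mu, sig, w)
  structure(cut, means = mu, sds = sig, weights = w, provenance = "gmm")
}

# TRUE iff the mixture density has a local minimum strictly between the
# component means (a dip separating two modes)
mixture_is_bimodal <- function(mu, sig, w) {
  xs <- seq(mu[1L], mu[2L], length.out = 512L)
  dens <- w[1L] * stats::dnorm(xs, mu[1L], sig[1L]) +
    w[2L] * stats::dnorm(xs, mu[2L], sig[2L])
  i_min <- which.min(dens)
  i_min > 1L && i_min < length(xs) &&
    dens[i_min] < (1 - 1e-6) * min(dens[1L], dens[length(xs)])
}

# Equal-posterior boundary of a 2-component Gaussian mixture, searched
# strictly between the means (log-density difference root).
equal_posterior_point <- function(mu, sig, w) {
  f <- function(x) {
    log(w[1L]) + stats::dnorm(x, mu[1L], sig[1L], log = TRUE) -
      log(w[2L]) - stats::dnorm(x, mu[2L], sig[2L], log = TRUE)
  }
  eps <- 1e-9 * max(1, diff(mu))
  lo <- mu[1L] + eps
  hi <- mu[2L] - eps
  if (f(lo) <= 0) return(lo)   # boundary degenerate, dominated everywhere
  if (f(hi) >= 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Estimate a diagnostic cutoff by Youden's index
#'
#' Scans all candidate thresholds (midpoints between adjacent sorted
#' distinct values) and returns the one maximizing
#' J = sensitivity + specificity - 1 for the given abnormality direction;
#' ties are broken toward the candidate with higher specificity.
#'
#' @param values Numeric marker values.
#' @param labels Binary reference standard (1/TRUE = abnormal).
#' @param direction "abnormal_above" (test positive above the cutoff) or
#'   "abnormal_below".
#' @return Cutoff with attributes `youden_j`, `sensitivity`, `specificity`,
#'   `provenance = "youden"`.
#' @export
estimate_youden_cutoff <- function(values, labels,
                                   direction = c("abnormal_above",
                                                 "abnormal_below")) {
  direction <- match.arg(direction)
  keep <- is.finite(values) & !is.na(labels)
  v <- values[keep]
  lab <- as.integer(as.logical(labels[keep]))
  if (length(unique(lab)) < 2L) {
    stop("both label classes must be present", call. = FALSE)
  }
  sv <- sort(unique(v))
  if (length(sv) < 2L) {
    stop("no candidate thresholds: all values identical", call. = FALSE)
  }
  cand <- (sv[-1L] + sv[-length(sv)]) / 2
  n_pos <- sum(lab == 1L)
  n_neg <- sum(lab == 0L)
  sens <- spec <- numeric(length(cand))
  for (i in seq_along(cand)) {
    test_pos <- if (direction == "abnormal_above") v > cand[i] else v < cand[i]
    sens[i] <- sum(test_pos & lab == 1L) / n_pos
    spec[i] <- sum(!test_pos & lab == 0L) / n_neg
  }
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(spec[best], decreasing = TRUE)][1L]
  structure(cand[best], youden_j = j[best], sensitivity = sens[best],
            specificity = spec[best], provenance = "youden")
}

#' Assemble a cutoff set
#'
#' Directions are fixed by biology: amyloid abnormal below the ratio
#' cutoff, phospho-tau abnormal above, hippocampal volume abnormal below,
#' total tau abnormal above.
#'
#' @param abeta_cutoff,ptau_cutoff,n_cutoff Positive cutoff values; the N
#'   cutoff is in ul (aHV mode) or pg/ml (ttau mode).
#' @param n_marker "ahv" or "ttau".
#' @param provenance Character tag(s), e.g. "fixed", "gmm", "youden".
#' @return A `cutoff_set` object.
#' @export
cutoff_set <- function(abeta_cutoff, ptau_cutoff, n_cutoff,
                       n_marker = c("ahv", "ttau"), provenance = "fixed") {
  n_marker <- match.arg(n_marker)
  vals <- c(abeta = abeta_cutoff, ptau = ptau_cutoff, n = n_cutoff)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all cutoffs must be finite and positive", call. = FALSE)
  }
  structure(list(
    abeta_cutoff = abeta_cutoff,
    ptau_cutoff = ptau_cutoff,
    n_cutoff = n_cutoff,
    n_marker = n_marker,
    direction = c(abeta = "abnormal_below", ptau = "abnormal_above",
                  n = if (n_marker == "ahv") "abnormal_below"
                      else "abnormal_above"),
    provenance = provenance
  ), class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("ATN cutoffs [", paste(x$provenance, collapse = ","), "]: A < ",
      x$abeta_cutoff, ", T > ", x$ptau_cutoff, ", N ",
      if (x$n_marker == "ahv") paste0("< ", x$n_cutoff, " ul (aHV)")
      else paste0("> ", x$n_cutoff, " pg/ml (ttau)"), "\n", sep = "")
  invisible(x)
}

#' Classify one subject's ATN status
#'
#' A+ iff abeta_ratio < cutoff; T+ iff ptau > cutoff; N+ iff adjusted
#' hippocampal volume < cutoff (aHV mode) or total tau > cutoff (ttau
#' mode). A value exactly at a cutoff is classified normal (-) in every
#' category.
#'
#' @param record One-row data frame (or list) with the marker fields.
#' @param cutoffs A [cutoff_set()].
#' @param adjusted_volume Covariate-adjusted hippocampal volume (ul);
#'   required in aHV mode.
#' @return An `atn_status`: flags `a_positive`, `t_positive`, `n_positive`
#'   and the `group_label`.
#' @export
classify_subject <- function(record, cutoffs, adjusted_volume = NULL) {
  need <- function(val, what) {
    if (is.null(val) || length(val) != 1L || is.na(val)) {
      stop("missing marker: ", what, call. = FALSE)
    }
    as.numeric(val)
  }
  ab <- need(record[["abeta_ratio"]], "abeta_ratio")
  pt <- need(record[["ptau"]], "ptau")
  a_pos <- ab < cutoffs$abeta_cutoff
  t_pos <- pt > cutoffs$ptau_cutoff
  n_pos <- if (cutoffs$n_marker == "ahv") {
    need(adjusted_volume, "adjusted hippocampal volume") < cutoffs$n_cutoff
  } else {
    need(record[["ttau"]], "ttau") > cutoffs$n_cutoff
  }
  structure(list(a_positive = a_pos, t_positive = t_pos, n_positive = n_pos,
                 group_label = atn_label(a_pos, t_pos, n_pos)),
            class = "atn_status")
}

#' @export
print.atn_status <- function(x, ...) {
  cat(pretty_label(x$group_label), "\n")
  invisible(x)
}

#' Classify a whole cohort into the 8 ATN groups
#'
#' Runs the full classification pipeline under a configuration: resolves
#' cutoff directives ("gmm" estimates the cutoff from the data by Gaussian
#' mixture; "youden" uses the clinical diagnosis, impaired MCI/DAT versus
#' unimpaired NC/SCD, as the reference standard), covariate-adjusts
#' hippocampal volume when it operationalizes N, classifies each subject,
#' and tabulates group sizes over all 8 groups. Subjects missing a required
#' marker are excluded (never imputed) and listed.
#'
#' @param cohort A [cohort_table()].
#' @param config An `analysis_config` (see [validate_config()]); a plain
#'   list is validated first.
#' @return An `atn_groups` object: `groups` (per-subject label, `NA` when
#'   excluded), `table` (named counts over the 8 groups), `excluded`
#'   (subject ids), `cutoffs` (the resolved [cutoff_set()]), `adjusted`
#'   (aHV per subject or `NULL`), `adjustment_model`.
#' @export
assign_groups <- function(cohort, config = validate_config()) {
  if (!inherits(config, "analysis_config")) config <- validate_config(config)
  df <- as.data.frame(cohort)
  n_marker <- config$n_marker

  adjusted <- NULL
  adj_model <- NULL
  if (n_marker == "ahv") {
    subset <- NULL
    adj <- adjust_volume(cohort, config$covariates)
    if (config$adjust_on == "atn_negative") {
      prelim <- resolve_marker_cutoff(config, "abeta", df, NULL)
      neg <- !is.na(df$abeta_ratio) & df$abeta_ratio >= prelim &
        !is.na(df$ptau) & df$ptau <= resolve_marker_cutoff(config, "ptau",
                                                           df, NULL)
      adj <- adjust_volume(cohort, config$covariates, subset = neg)
    }
    adjusted <- adj$adjusted
    adj_model <- adj$model
  }

  abeta_cut <- resolve_marker_cutoff(config, "abeta", df, adjusted)
  ptau_cut <- resolve_marker_cutoff(config, "ptau", df, adjusted)
  n_cut <- resolve_marker_cutoff(config,
                                 if (n_marker == "ahv") "ahv" else "ttau",
                                 df, adjusted)
  cuts <- cutoff_set(abeta_cut, ptau_cut, n_cut, n_marker,
                     provenance = attr(abeta_cut, "provenance") %||% "fixed")

  ok <- complete_markers(cohort, n_marker)
  if (n_marker == "ahv") ok <- ok & !is.na(adjusted)
  groups <- rep(NA_character_, nrow(df))
  for (i in which(ok)) {
    groups[i] <- classify_subject(df[i, ], cuts,
                                  adjusted_volume = adjusted[i])$group_label
  }
  tab <- table(factor(groups, levels = atn_labels()))
  structure(list(groups = groups,
                 table = tab,
                 excluded = df$subject_id[!ok],
                 cutoffs = cuts,
                 adjusted = adjusted,
                 adjustment_model = adj_model),
            class = "atn_groups")
}

#' @export
print.atn_groups <- function(x, ...) {
  cat("ATN classification of", length(x$groups), "subjects (",
      length(x$excluded), "excluded for missing markers)\n")
  print(stats::setNames(as.integer(x$table), pretty_label(names(x$table))))
  invisible(x)
}

# resolve a single marker's cutoff value or directive
resolve_marker_cutoff <- function(config, marker, df, adjusted) {
  v <- config$cutoffs[[marker]]
  if (is.numeric(v)) return(v)
  values <- switch(marker,
    abeta = df$abeta_ratio,
    ptau = df$ptau,
    ttau = df$ttau,
    ahv = adjusted %||% df$hippocampal_volume
  )
  if (identical(v, "gmm")) {
    return(estimate_gmm_cutoff(values, seed = config$seed))
  }
  if (identical(v, "youden")) {
    if (!"diagnosis" %in% names(df) || all(is.na(df$diagnosis))) {
      stop("youden cutoff for '", marker,
           "' needs a clinical diagnosis column as reference standard",
           call. = FALSE)
    }
    impaired <- df$diagnosis %in% c("MCI", "DAT")
    dir <- if (marker %in% c("abeta", "ahv")) "abnormal_below"
           else "abnormal_above"
    return(estimate_youden_cutoff(values, impaired, dir))
  }
  stop("unsupported cutoff directive '", v, "' for ", marker, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
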