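#' Gray-matter inclusion mask by absolute threshold
#'
#' A voxel enters the analysis mask iff its mean value across subjects is
#' at least the absolute threshold (default 0.05, the conventional
#' modulated-GM cut).
#'
#' @param dataset A [voxel_dataset()].
#' @param threshold Absolute threshold on the subject-mean GM value.
#' @return An [roi_mask()] named "GM".
#' @export
gm_mask <- function(dataset, threshold = 0.05) {
  mean_img <- apply(dataset$values, 1:3, mean)
  m <- mean_img >= threshold
  if (!any(m)) {
    stop("GM mask empty at threshold ", threshold, call. = FALSE)
  }
  roi_mask("GM", m)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up rejection at level `q` plus the standard monotone q-value
#' transform.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `rejected` (logical) and `qvalues`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  qvalues <- stats::p.adjust(pvals, method = "BH")
  # step-up rule: reject all p(i) with p(i) <= i/m * q for the largest
  # such i -- equivalent to qvalue <= q
  list(rejected = qvalues <= q, qvalues = qvalues)
}

# Precompute, for one sequence design, the 8 active-constraint pattern
# fits applied to a matrix of outcomes (rows = included subjects,
# columns = voxels). Returns constrained SSE per voxel (exact active-set
# enumeration, identical rule to fit_monotone).
constrained_sse_matrix <- function(design, Y) {
  patterns <- list(integer(0), 2L, 3L, 4L, c(2L, 3L), c(2L, 4L),
                   c(3L, 4L), c(2L, 3L, 4L))
  best <- rep(Inf, ncol(Y))
  for (active in patterns) {
    free <- setdiff(1:4, active)
    Xp <- cbind(design$X[, free, drop = FALSE], design$Z)
    qx <- qr(Xp)
    if (qx$rank < ncol(Xp)) next
    coef <- qr.coef(qx, Y)
    res <- Y - Xp %*% coef
    sse <- colSums(res^2)
    diff_rows <- which(free %in% 2:4)
    feasible <- if (length(diff_rows)) {
      colSums(coef[diff_rows, , drop = FALSE] > 1e-10) == 0L
    } else rep(TRUE, ncol(Y))
    thr <- best - 1e-12 * pmax(1, best)
    thr[!is.finite(best)] <- Inf
    improve <- feasible & (sse < thr)
    best[improve] <- sse[improve]
  }
  best
}

#' Voxel-wise sequence comparison (winner map)
#'
#' Applies the BIC comparison of [compare_sequences()] independently at
#' every in-mask voxel, using an exact vectorized active-set solver (the
#' candidate designs depend only on the group labels, so their
#' factorizations are shared across voxels; results are identical to the
#' per-voxel path).
#'
#' @param dataset A [voxel_dataset()] aligned with the cohort.
#' @param cohort A [cohort_table()].
#' @param sequences A [sequence_set()] or set name.
#' @param config An `analysis_config`; supplies the GM threshold,
#'   covariates and minimum group size.
#' @param groups Optional per-subject group labels (or an `atn_groups`
#'   object); classified from the cohort via [assign_groups()] when absent.
#' @param mask Optional [roi_mask()] overriding the GM threshold mask.
#' @return An `evidence_result`: 3-D arrays `winner` (index into
#'   `sequence_names`, `NA` outside the mask), `delta_bic` (margin to the
#'   runner-up), `tie`; plus `sequence_names`, `reference`, `mask`,
#'   `voxel_size`, and the per-sequence `n`/`k` table.
#' @export
voxelwise_compare <- function(dataset, cohort,
                              sequences = permutation_sequences(),
                              config = validate_config(),
                              groups = NULL, mask = NULL) {
  if (!inherits(config, "analysis_config")) config <- validate_config(config)
  check_alignment(dataset, cohort)
  sequences <- resolve_sequences(sequences)
  if (is.null(groups)) groups <- assign_groups(cohort, config)
  if (inherits(groups, "atn_groups")) groups <- groups$groups
  if (is.null(mask)) mask <- gm_mask(dataset, config$gm_threshold)
  check_mask_grid(mask, dataset)
  covs <- as.data.frame(cohort)[, config$covariates, drop = FALSE]

  Yfull <- dataset_matrix(dataset, mask$mask)   # subjects x voxels
  nvox <- ncol(Yfull)
  seq_names <- unname(vapply(sequences, `[[`, character(1L), "name"))
  bics <- matrix(Inf, nrow = nvox, ncol = length(sequences),
                 dimnames = list(NULL, seq_names))
  meta <- list()
  kept <- logical(length(sequences))
  for (j in seq_along(sequences)) {
    s <- sequences[[j]]
    des <- tryCatch(build_design(groups, s, covs, config$min_group_n),
                    error = function(e) e)
    if (inherits(des, "error")) {
      warning("dropping sequence ", s$name, ": ", conditionMessage(des),
              call. = FALSE)
      next
    }
    kept[j] <- TRUE
    Y <- Yfull[des$included, , drop = FALSE]
    sse <- constrained_sse_matrix(des, Y)
    n <- length(des$included)
    k <- 4L + ncol(des$Z %||% matrix(0, 1, 0)) + 1L
    b <- n * log(sse / n) + k * log(n)
    b[sse <= 0] <- -Inf
    bics[, j] <- b
    meta[[s$name]] <- data.frame(sequence = s$name, n = n, k = k)
  }
  if (!any(kept)) stop("no sequence satisfied the design preconditions",
                       call. = FALSE)
  bics <- bics[, kept, drop = FALSE]
  seq_names <- seq_names[kept]
  winner_idx <- max.col(-bics, ties.method = "first")
  if (ncol(bics) > 1L) {
    sorted2 <- apply(bics, 1L, function(b) sort(b, partial = 1:2)[1:2])
    delta <- sorted2[2L, ] - sorted2[1L, ]
    exact_tie <- rowSums(bics == -Inf) >= 2L   # several zero-SSE fits
    delta[is.nan(delta)] <- ifelse(exact_tie[is.nan(delta)], 0, Inf)
  } else {
    delta <- rep(Inf, nvox)
  }

  shape <- grid_shape(dataset)
  to_grid <- function(v, fill = NA) {
    a <- array(fill, dim = shape)
    a[mask$mask] <- v
    a
  }
  structure(list(
    winner = to_grid(winner_idx),
    delta_bic = to_grid(delta),
    tie = to_grid(delta < 1e-9),
    sequence_names = seq_names,
    reference = attr(sequences, "reference"),
    table = do.call(rbind, meta),
    mask = mask,
    voxel_size = dataset$voxel_size
  ), class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat("voxel-wise evidence over", length(x$sequence_names), "sequences;",
      sum(x$mask$mask), "in-mask voxels\n")
  print(utils::head(sort(winner_percentages(x), decreasing = TRUE), 6L))
  invisible(x)
}

#' Percentage of in-mask voxels won by each sequence
#'
#' @param result An `evidence_result` from [voxelwise_compare()].
#' @param mask Optional [roi_mask()] restricting the count (e.g. an ROI);
#'   defaults to the result's analysis mask.
#' @return Named numeric vector of percentages summing to 100.
#' @export
winner_percentages <- function(result, mask = NULL) {
  m <- if (is.null(mask)) result$mask$mask else {
    if (inherits(mask, "roi_mask")) mask$mask else mask
  }
  w <- result$winner[m & result$mask$mask]
  w <- w[!is.na(w)]
  if (!length(w)) stop("no in-mask voxels under the given mask",
                       call. = FALSE)
  counts <- tabulate(w, nbins = length(result$sequence_names))
  stats::setNames(100 * counts / sum(counts), result$sequence_names)
}

#' Voxel-wise trend-test map with FDR correction
#'
#' Runs the one-sided decline [trend_test()] along one sequence at every
#' in-mask voxel (a single shared design, vectorized) and applies
#' Benjamini-Hochberg FDR across in-mask voxels.
#'
#' @inheritParams voxelwise_compare
#' @param sequence A [group_sequence()] (e.g. `conversion_paths()$ACH`).
#' @return A `stat_map`: 3-D arrays `t`, `p`, `qvalue`, `neg_log10_p`,
#'   `significant`; plus `sequence`, `mask`, `fdr_q`, `voxel_size`.
#' @export
logp_map <- function(dataset, cohort, sequence,
                     config = validate_config(), groups = NULL,
                     mask = NULL) {
  if (!inherits(config, "analysis_config")) config <- validate_config(config)
  check_alignment(dataset, cohort)
  stopifnot(inherits(sequence, "group_sequence"))
  if (is.null(groups)) groups <- assign_groups(cohort, config)
  if (inherits(groups, "atn_groups")) groups <- groups$groups
  if (is.null(mask)) mask <- gm_mask(dataset, config$gm_threshold)
  check_mask_grid(mask, dataset)
  covs <- as.data.frame(cohort)[, config$covariates, drop = FALSE]
  des <- build_design(groups, sequence, covs, config$min_group_n)
  Y <- dataset_matrix(dataset, mask$mask)[des$included, , drop = FALSE]

  pos <- des$position - mean(des$position)
  X <- cbind(1, pos, des$Z)
  qx <- qr(X)
  coef <- qr.coef(qx, Y)
  res <- Y - X %*% coef
  dfres <- nrow(Y) - ncol(X)
  sigma2 <- colSums(res^2) / dfres
  XtXinv <- chol2inv(qr.R(qx)[, order(qx$pivot), drop = FALSE])
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tvals <- coef[2L, ] / se
  pvals <- stats::pt(tvals, dfres)
  fdr <- fdr_bh(pvals, config$fdr_q)

  shape <- grid_shape(dataset)
  to_grid <- function(v, fill = NA) {
    a <- array(fill, dim = shape)
    a[mask$mask] <- v
    a
  }
  structure(list(
    t = to_grid(tvals),
    p = to_grid(pvals),
    qvalue = to_grid(fdr$qvalues),
    neg_log10_p = to_grid(-log10(pmax(pvals, .Machine$double.xmin))),
    significant = to_grid(fdr$rejected, fill = FALSE),
    sequence = sequence$name,
    mask = mask,
    fdr_q = config$fdr_q,
    df = dfres,
    voxel_size = dataset$voxel_size
  ), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  inm <- x$mask$mask
  cat("trend-test map along ", x$sequence, ": ",
      sum(x$significant[inm]), " of ", sum(inm),
      " in-mask voxels significant at FDR q = ", x$fdr_q, "\n", sep = "")
  invisible(x)
}

#' ROI-level sequence comparison and winner-percentage summary
#'
#' Compares the candidate sequences on the summed in-ROI volume per
#' subject (or a supplied per-subject scalar), reports the one-sided
#' decline trend along the best sequence, and — when a voxel-wise
#' `evidence_result` is supplied — the percentage of in-ROI voxels whose
#' winner is the reference sequence ("VX%").
#'
#' @inheritParams voxelwise_compare
#' @param roi An [roi_mask()]; ignored when `roi_volumes` is given.
#' @param roi_volumes Optional per-subject scalar outcome replacing the
#'   in-ROI sum (e.g. an atlas ROI volume).
#' @param evidence Optional `evidence_result` for the VX% column.
#' @return An `roi_summary` data-frame row: roi, best_sequence, t, p,
#'   reference_rank, ref_vx_pct; the full `model_comparison` is attached
#'   as attribute `comparison`.
#' @export
roi_summary <- function(dataset = NULL, cohort, roi = NULL,
                        sequences = permutation_sequences(),
                        config = validate_config(), groups = NULL,
                        roi_volumes = NULL, evidence = NULL) {
  if (!inherits(config, "analysis_config")) config <- validate_config(config)
  sequences <- resolve_sequences(sequences)
  if (is.null(groups)) groups <- assign_groups(cohort, config)
  if (inherits(groups, "atn_groups")) groups <- groups$groups
  covs <- as.data.frame(cohort)[, config$covariates, drop = FALSE]
  roi_name <- if (!is.null(roi)) roi$name else "roi"
  if (is.null(roi_volumes)) {
    if (is.null(dataset) || is.null(roi)) {
      stop("need either roi_volumes or a dataset plus an ROI mask",
           call. = FALSE)
    }
    check_alignment(dataset, cohort)
    check_mask_grid(roi, dataset)
    vvol <- prod(dataset$voxel_size)
    roi_volumes <- rowSums(dataset_matrix(dataset, roi$mask)) * vvol
  }
  cmp <- compare_sequences(roi_volumes, groups, covs, sequences,
                           config$min_group_n)
  best <- sequences[[cmp$winner]]
  tt <- trend_test(roi_volumes, groups, covs, best, config$min_group_n)
  vx <- NA_real_
  if (!is.null(evidence)) {
    pct <- winner_percentages(evidence, roi)
    vx <- unname(pct[evidence$reference])
  }
  out <- data.frame(roi = roi_name, best_sequence = cmp$winner,
                    t = tt$t, p = tt$p,
                    reference_rank = cmp$reference_rank,
                    ref_vx_pct = vx, stringsAsFactors = FALSE)
  attr(out, "comparison") <- cmp
  class(out) <- c("roi_summary", "data.frame")
  out
}

#' Aggregate per-subject ROI volumes into Braak-stage composites
#'
#' Braak staging orders the anatomical spread of neurofibrillary tau
#' pathology; the conventional composites are stage I/II (entorhinal
#' cortex and hippocampus), III/IV (limbic, insular and temporal regions)
#' and V/VI (remaining cortical regions). Each composite's volume is the
#' per-subject sum of its constituent ROI volumes.
#'
#' @param roi_volume_table Data frame or matrix, rows = subjects,
#'   columns = ROI volumes.
#' @param stage_map Named list mapping each stage label to its constituent
#'   ROI column names; constituents must be disjoint across stages and
#'   non-empty.
#' @return Named list of `braak_composite` objects (`stage`,
#'   `constituents`, `volume` per subject).
#' @export
#' @examples
#' vols <- data.frame(entorhinal = c(1, 2), hippocampus = c(3, 4),
#'                    insula = c(5, 6))
#' braak_composites(vols, list("I/II" = c("entorhinal", "hippocampus"),
#'                             "III/IV" = "insula"))
braak_composites <- function(roi_volume_table,
                             stage_map = default_braak_map()) {
  tab <- as.data.frame(roi_volume_table)
  all_rois <- unlist(stage_map, use.names = FALSE)
  if (anyDuplicated(all_rois)) {
    dup <- unique(all_rois[duplicated(all_rois)])
    stop("ROI(s) assigned to more than one stage: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  missing_roi <- setdiff(all_rois, names(tab))
  if (length(missing_roi)) {
    stop("ROI(s) absent from the volume table: ",
         paste(missing_roi, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (stage in names(stage_map)) {
    members <- stage_map[[stage]]
    if (!length(members)) {
      stop("stage '", stage, "' has no constituent ROIs", call. = FALSE)
    }
    out[[stage]] <- structure(list(
      stage = stage,
      constituents = members,
      volume = rowSums(tab[, members, drop = FALSE])
    ), class = "braak_composite")
  }
  out
}

#' Default Braak-stage ROI membership
#'
#' A coarse default mapping of ROI names to composite stages; real
#' analyses should supply the membership matching their atlas.
#'
#' @return Named list of ROI name vectors.
#' @export
default_braak_map <- function() {
  list(
    "I/II" = c("entorhinal", "hippocampus"),
    "III/IV" = c("amygdala", "insula", "temporal", "cingulate"),
    "V/VI" = c("precuneus", "frontal", "parietal", "occipital",
               "sensorimotor")
  )
}

#' Write the standard output maps of an evidence analysis
#'
#' Writes the integer-coded winner map (with a JSON legend), the
#' runner-up BIC margin map, and the analysis mask; out-of-mask voxels
#' are 0 in the images.
#'
#' @param result An `evidence_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_evidence_maps <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vs <- result$voxel_size
  zero <- function(a) {
    a[is.na(a)] <- 0
    a
  }
  paths <- c(
    winner = file.path(out_dir, "winner.nii.gz"),
    delta_bic = file.path(out_dir, "delta_bic.nii.gz"),
    mask = file.path(out_dir, "mask.nii.gz"),
    legend = file.path(out_dir, "winner_legend.json"),
    percentages = file.path(out_dir, "winner_percentages.tsv")
  )
  write_map(zero(result$winner), vs, paths["winner"])
  db <- result$delta_bic
  db[!is.finite(db)] <- 0
  write_map(zero(db), vs, paths["delta_bic"])
  write_map(result$mask$mask, vs, paths["mask"])
  jsonlite::write_json(
    as.list(stats::setNames(seq_along(result$sequence_names),
                            result$sequence_names)),
    paths["legend"], auto_unbox = TRUE)
  pct <- winner_percentages(result)
  utils::write.table(data.frame(sequence = names(pct), percent = pct),
                     paths["percentages"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
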