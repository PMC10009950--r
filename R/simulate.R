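#' Define a planted effect profile for a simulated region
#'
#' The profile gives the mean volume offset at each of the 4 positions of
#' a progression sequence. `monotone` profiles must be non-increasing;
#' `biphasic` profiles rise from position 1 to 2 and end at their minimum
#' (the transient-expansion-then-decline shape that favours alternative
#' orderings placing the all-negative group after amyloid conversion);
#' `null` profiles are all zero.
#'
#' @param kind "monotone", "biphasic" or "null".
#' @param sequence The [group_sequence()] the offsets follow (default the
#'   ACH ordering).
#' @param offsets Numeric length-4 mean offsets (volume units).
#' @return An `effect_profile`.
#' @export
effect_profile <- function(kind = c("monotone", "biphasic", "null"),
                           sequence = conversion_paths()[["ACH"]],
                           offsets = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(sequence, "group_sequence"))
  if (is.null(offsets)) {
    offsets <- switch(kind,
      monotone = c(0, -1, -2, -3),
      biphasic = c(0, 1, 0, -2),
      null = c(0, 0, 0, 0))
  }
  offsets <- as.numeric(offsets)
  stopifnot(length(offsets) == 4L, all(is.finite(offsets)))
  ok <- switch(kind,
    monotone = all(diff(offsets) <= 0),
    biphasic = offsets[2L] > offsets[1L] && offsets[4L] == min(offsets),
    null = all(offsets == 0))
  if (!ok) {
    stop("offsets ", paste(offsets, collapse = ", "),
         " are not a valid '", kind, "' profile", call. = FALSE)
  }
  structure(list(kind = kind, sequence = sequence, offsets = offsets),
            class = "effect_profile")
}

#' Define an axis-aligned box region on the simulation grid
#'
#' @param name Region name.
#' @param lo,hi Integer length-3 corner voxel indices (1-based, inclusive).
#' @param profile An [effect_profile()].
#' @return A `sim_region`.
#' @export
sim_region <- function(name, lo, hi, profile) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(lo >= 1L),
            all(hi >= lo), inherits(profile, "effect_profile"))
  structure(list(name = name, lo = lo, hi = hi, profile = profile),
            class = "sim_region")
}

#' Build a simulation specification
#'
#' Defaults emulate the published DELCODE sample structure
#' ([delcode_reference()]): its 8 ATN group sizes, bimodal per-marker
#' component distributions matching the printed group means/SDs, a 0.7
#' phospho-tau/total-tau correlation (which keeps discordant tau groups
#' rare), covariate distributions typical of an elderly memory-clinic
#' cohort, and covariate confounding of hippocampal volume (age, sex,
#' TICV, WMH) so that adjustment is non-trivially exercised. The voxel
#' grid defaults to 24x24x24 at 2 mm with one monotone ACH region, one
#' biphasic region and null background; smoothing is off by default (the
#' 6-mm kernel of real VBM pipelines is available via `fwhm`).
#'
#' @param group_sizes Named integer vector over the 8 ATN groups.
#' @param markers List of per-marker component parameters; each of
#'   `abeta`, `ptau`, `ttau`, `hv` has `normal_mean`, `normal_sd`,
#'   `abnormal_mean`, `abnormal_sd` (hv in ul).
#' @param tau_correlation Within-component correlation of ptau and ttau.
#' @param n_marker Which marker the N flag of the planted groups governs:
#'   "ahv" (hippocampal volume bimodal by N) or "ttau".
#' @param covariates List of covariate distribution parameters.
#' @param hv_coef Covariate-to-hippocampal-volume coefficients (ul per
#'   covariate unit; applied to centered covariates).
#' @param grid_dim,voxel_size Voxel grid shape and mm size.
#' @param baseline Baseline voxel GM value.
#' @param residual_sd Voxel noise SD.
#' @param vox_coef Covariate-to-voxel-value coefficients (applied to
#'   centered covariates, uniform across voxels).
#' @param regions List of [sim_region()]s; `NULL` gives the two default
#'   planted regions (offsets in units of `residual_sd`).
#' @param fwhm Gaussian smoothing FWHM in mm (0 = none).
#' @param seed Integer seed; every output is a pure function of the spec.
#' @return A `simulation_spec`.
#' @export
simulation_spec <- function(group_sizes = NULL,
                            markers = NULL,
                            tau_correlation = 0.7,
                            n_marker = c("ahv", "ttau"),
                            covariates = NULL,
                            hv_coef = NULL,
                            grid_dim = c(24L, 24L, 24L),
                            voxel_size = c(2, 2, 2),
                            baseline = 0.5,
                            residual_sd = 0.1,
                            vox_coef = NULL,
                            regions = NULL,
                            fwhm = 0,
                            seed = 1L) {
  n_marker <- match.arg(n_marker)
  ref <- delcode_reference()
  if (is.null(group_sizes)) {
    group_sizes <- stats::setNames(ref$n, ref$group)
  }
  stopifnot(all(names(group_sizes) %in% atn_labels()),
            all(group_sizes >= 0))
  if (is.null(markers)) {
    markers <- list(
      abeta = list(normal_mean = 0.110, normal_sd = 0.012,
                   abnormal_mean = 0.060, abnormal_sd = 0.013),
      ptau = list(normal_mean = 41, normal_sd = 10,
                  abnormal_mean = 85, abnormal_sd = 30),
      ttau = list(normal_mean = 300, normal_sd = 100,
                  abnormal_mean = 650, abnormal_sd = 250),
      hv = list(normal_mean = 3140, normal_sd = 210,
                abnormal_mean = 2600, abnormal_sd = 180)
    )
  }
  for (m in markers) stopifnot(m$normal_sd > 0, m$abnormal_sd > 0)
  if (is.null(covariates)) {
    covariates <- list(age_mean = 69.5, age_sd = 5.5,
                       age_stage_slope = 1.2,  # years per positive marker
                       sex_p_female = 0.48,
                       education_mean = 14.3, education_sd = 2.9,
                       ticv_mean = 1400, ticv_sd = 120,
                       wmh_meanlog = 0.8, wmh_sdlog = 1.0)
  }
  if (is.null(hv_coef)) {
    hv_coef <- c(age = -10, sex = -120, education = 0, ticv = 0.4,
                 wmh = -6)
  }
  if (is.null(vox_coef)) {
    vox_coef <- c(age = -0.003, sex = -0.01, education = 0,
                  ticv = 5e-5, wmh = -0.002)
  }
  stopifnot(all(grid_dim >= 1L), all(voxel_size > 0), fwhm >= 0,
            residual_sd > 0, abs(tau_correlation) < 1)
  if (is.null(regions)) {
    sd <- residual_sd
    # two boxes scaled to the grid: lower-corner monotone, upper biphasic
    lo1 <- pmax(1L, round(grid_dim * 0.10))
    hi1 <- pmax(lo1, round(grid_dim * 0.42))
    lo2 <- pmax(1L, round(grid_dim * 0.58))
    hi2 <- pmax(lo2, round(grid_dim * 0.88))
    regions <- list(
      sim_region("ach_monotone", lo1, hi1,
                 effect_profile("monotone",
                                offsets = c(0, -1, -2, -3) * sd)),
      sim_region("biphasic", lo2, hi2,
                 effect_profile("biphasic",
                                offsets = c(0, 1, 0, -2) * sd))
    )
  }
  for (r in regions) {
    if (any(r$hi > grid_dim)) {
      stop("region '", r$name, "' extends outside the grid", call. = FALSE)
    }
  }
  structure(list(group_sizes = group_sizes, markers = markers,
                 tau_correlation = tau_correlation, n_marker = n_marker,
                 covariates = covariates, hv_coef = hv_coef,
                 grid_dim = as.integer(grid_dim),
                 voxel_size = as.numeric(voxel_size),
                 baseline = baseline, residual_sd = residual_sd,
                 vox_coef = vox_coef, regions = regions,
                 fwhm = fwhm, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a cohort with known ATN ground truth
#'
#' Assigns exactly the specified number of subjects to each ATN group
#' (fixed-size sampling), then draws each subject's markers from the
#' normal or abnormal mixture component dictated by the group's flags:
#' abeta from the low component for A+, ptau from the high component for
#' T+, and the N-governed marker (hippocampal volume low / total tau high)
#' per the N flag. Phospho- and total tau are drawn with the configured
#' within-component correlation. Hippocampal volume additionally receives
#' the covariate confounds (centered), and age increases with the number
#' of abnormal markers. Deterministic given the spec (seeded).
#'
#' @param spec A [simulation_spec()].
#' @return List with `cohort` (a [cohort_table()]) and `truth` (data frame
#'   with the assigned group, ACH position, and the component means used;
#'   generative coefficients attached as attributes).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  gs <- spec$group_sizes[spec$group_sizes > 0]
  groups <- rep(names(gs), times = gs)
  n <- length(groups)
  a_pos <- substr(groups, 2L, 2L) == "+"
  t_pos <- substr(groups, 4L, 4L) == "+"
  n_pos <- substr(groups, 6L, 6L) == "+"
  n_abn <- a_pos + t_pos + n_pos

  cv <- spec$covariates
  age <- stats::rnorm(n, cv$age_mean + cv$age_stage_slope * n_abn,
                      cv$age_sd)
  age <- pmax(age, 50)
  sex <- stats::rbinom(n, 1L, cv$sex_p_female)
  education <- pmax(stats::rnorm(n, cv$education_mean, cv$education_sd), 6)
  ticv <- stats::rnorm(n, cv$ticv_mean, cv$ticv_sd)
  wmh <- stats::rlnorm(n, cv$wmh_meanlog, cv$wmh_sdlog)

  comp <- function(m, abnormal) {
    list(mean = ifelse(abnormal, m$abnormal_mean, m$normal_mean),
         sd = ifelse(abnormal, m$abnormal_sd, m$normal_sd))
  }
  ab <- comp(spec$markers$abeta, a_pos)
  abeta <- pmax(stats::rnorm(n, ab$mean, ab$sd), 1e-4)

  # correlated tau pair: T flag governs ptau; ttau follows N in ttau mode,
  # T otherwise
  rho <- spec$tau_correlation
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  pt <- comp(spec$markers$ptau, t_pos)
  tt_flag <- if (spec$n_marker == "ttau") n_pos else t_pos
  tt <- comp(spec$markers$ttau, tt_flag)
  ptau <- pmax(pt$mean + pt$sd * z1, 1)
  ttau <- pmax(tt$mean + tt$sd * z2, 1)

  hv_flag <- if (spec$n_marker == "ahv") n_pos else rep(FALSE, n)
  hv <- comp(spec$markers$hv, hv_flag)
  hv_base <- stats::rnorm(n, hv$mean, hv$sd)
  hc <- spec$hv_coef
  confound <- hc["age"] * (age - mean(age)) +
    hc["sex"] * (sex - mean(sex)) +
    hc["education"] * (education - mean(education)) +
    hc["ticv"] * (ticv - mean(ticv)) +
    hc["wmh"] * (wmh - mean(wmh))
  hippocampal_volume <- pmax(hv_base + confound, 500)

  ach_states <- ad_continuum_states()
  cohort <- cohort_table(data.frame(
    subject_id = sprintf("sim%04d", seq_len(n)),
    age = age, sex = sex, education = education, ticv = ticv, wmh = wmh,
    abeta_ratio = abeta, ptau = ptau, ttau = ttau,
    hippocampal_volume = hippocampal_volume,
    stringsAsFactors = FALSE
  ), source = "simulate_cohort")
  truth <- data.frame(
    subject_id = cohort$subject_id,
    group = groups,
    ach_position = match(groups, ach_states),
    hv_component_mean = hv$mean,
    stringsAsFactors = FALSE
  )
  attr(truth, "hv_coef") <- hc
  attr(truth, "spec_seed") <- spec$seed
  list(cohort = cohort, truth = truth)
}

#' Simulate a voxel dataset with planted regional effects
#'
#' Each voxel value is baseline + the region's profile offset at the
#' subject's position along the profile's sequence (0 outside all regions
#' or when the subject's group is not on that sequence) + uniform
#' covariate effects (centered) + Gaussian noise, optionally followed by
#' Gaussian smoothing at the spec FWHM. Seeded independently of the
#' cohort draw (spec seed + 1) so cohort and images are jointly
#' deterministic.
#'
#' @param sim A [simulate_cohort()] result (cohort + truth).
#' @param spec The same [simulation_spec()].
#' @return List with `dataset` (a [voxel_dataset()]) and `truth` (3-D
#'   `region_id` array, region table, and the per-region profiles).
#' @export
simulate_voxels <- function(sim, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  cohort <- sim$cohort
  n <- nrow(cohort)
  set.seed(spec$seed + 1L)
  dims <- spec$grid_dim
  nvox <- prod(dims)

  vc <- spec$vox_coef
  df <- as.data.frame(cohort)
  subj_shift <- vc["age"] * (df$age - mean(df$age)) +
    vc["sex"] * (df$sex - mean(df$sex)) +
    vc["education"] * (df$education - mean(df$education)) +
    vc["ticv"] * (df$ticv - mean(df$ticv)) +
    vc["wmh"] * (df$wmh - mean(df$wmh))

  region_id <- array(0L, dim = dims)
  offset_mat <- matrix(0, nrow = n, ncol = nvox)  # subjects x voxels
  groups <- sim$truth$group
  for (ri in seq_along(spec$regions)) {
    r <- spec$regions[[ri]]
    vox_in <- array(FALSE, dim = dims)
    vox_in[r$lo[1L]:r$hi[1L], r$lo[2L]:r$hi[2L], r$lo[3L]:r$hi[3L]] <- TRUE
    region_id[vox_in] <- ri
    pos <- match(groups, r$profile$sequence$states)
    subj_off <- ifelse(is.na(pos), 0, r$profile$offsets[pos])
    offset_mat[, vox_in] <- subj_off
  }

  noise <- matrix(stats::rnorm(n * nvox, 0, spec$residual_sd),
                  nrow = n, ncol = nvox)
  vals <- spec$baseline + offset_mat + subj_shift + noise
  arr <- array(t(vals), dim = c(dims, n))
  if (spec$fwhm > 0) {
    for (i in seq_len(n)) {
      arr[, , , i] <- smooth_volume(arr[, , , i], spec$fwhm,
                                    spec$voxel_size)
    }
  }
  dataset <- voxel_dataset(arr, spec$voxel_size, cohort$subject_id)
  truth <- list(
    region_id = region_id,
    regions = data.frame(
      id = seq_along(spec$regions),
      name = vapply(spec$regions, `[[`, character(1L), "name"),
      kind = vapply(spec$regions, function(r) r$profile$kind,
                    character(1L)),
      sequence = vapply(spec$regions, function(r) r$profile$sequence$name,
                        character(1L)),
      stringsAsFactors = FALSE
    ),
    profiles = lapply(spec$regions, `[[`, "profile")
  )
  list(dataset = dataset, truth = truth)
}

#' Gaussian-smooth a 3-D image
#'
#' Separable Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2)) per
#' axis (converted from mm to voxels); the truncated kernel is
#' renormalized so constant images pass through unchanged and total mass
#' is preserved to truncation accuracy.
#'
#' @param image 3-D numeric array.
#' @param fwhm_mm Full width at half maximum, mm (0 returns the input).
#' @param voxel_size Numeric length-3 voxel size, mm.
#' @return The smoothed array.
#' @export
smooth_volume <- function(image, fwhm_mm, voxel_size) {
  if (fwhm_mm < 0) stop("FWHM must be non-negative", call. = FALSE)
  if (fwhm_mm == 0) return(image)
  stopifnot(length(dim(image)) == 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- image
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / voxel_size[ax]
    if (sigma_vox <= 0) next
    n <- dim(out)[ax]
    r <- max(1L, ceiling(4 * sigma_vox))
    idx <- seq_len(n)
    W <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= r, exp(-d^2 / (2 * sigma_vox^2)), 0)
    })
    W <- W / rowSums(W)   # truncated-kernel renormalization
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(out, perm)
    d <- dim(a)
    a <- W %*% matrix(a, nrow = d[1L])
    out <- aperm(array(a, dim = d), order(perm))
  }
  out
}
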