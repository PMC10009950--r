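ach <- conversion_paths()[["ACH"]]

# small fully-planted dataset: every voxel declines along ACH
make_planted_dataset <- function(n_per = 5L, dims = c(5L, 5L, 5L),
                                 sd = 0, means = c(0.8, 0.7, 0.6, 0.5),
                                 seed = 1L) {
  set.seed(seed)
  groups <- rep(ach$states, each = n_per)
  n <- length(groups)
  mu <- means[match(groups, ach$states)]
  vals <- array(rep(mu, each = prod(dims)), dim = c(dims, n))
  if (sd > 0) vals <- vals + array(rnorm(length(vals), 0, sd), dim(vals))
  list(dataset = voxel_dataset(vals, c(2, 2, 2)), groups = groups,
       cohort = cohort_table(make_cohort_df(n)))
}

test_that("the GM mask applies the absolute threshold to mean GM", {
  vals <- array(0.01, dim = c(4, 4, 4, 3))
  vals[1:2, , , ] <- 0.2
  ds <- voxel_dataset(vals, c(2, 2, 2))
  m <- gm_mask(ds, 0.05)
  expect_equal(sum(m$mask), 2L * 16L)
  expect_true(all(m$mask[1:2, , ]))
  expect_false(any(m$mask[3:4, , ]))
  expect_equal(sum(gm_mask(ds, 0)$mask), 64L)
  expect_error(gm_mask(voxel_dataset(array(0.04, c(3, 3, 3, 2)),
                                     c(2, 2, 2))), "empty")
})

test_that("BH-FDR matches hand step-up examples and the reference oracle", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$rejected))
  expect_false(any(fdr_bh(rep(0.5, 10), 0.05)$rejected))
  expect_true(fdr_bh(0.04, 0.05)$rejected)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(20)
  for (i in 1:200) {
    p <- runif(sample(5:80, 1L))^sample(1:3, 1L)
    q <- runif(1L, 0.01, 0.2)
    got <- fdr_bh(p, q)
    ref <- ref_bh(p, q)
    expect_identical(got$rejected, ref$rejected)
    expect_equal(got$qvalues, ref$qvalues, tolerance = 1e-12)
  }
})

test_that("a uniformly ACH-monotone dataset gives ACH 100% of voxels", {
  pl <- make_planted_dataset()
  ev <- voxelwise_compare(pl$dataset, pl$cohort, permutation_sequences(),
                          validate_config(list()), groups = pl$groups)
  pct <- winner_percentages(ev)
  expect_equal(unname(pct["ACH"]), 100)
  expect_equal(sum(pct), 100)
})

test_that("winner percentages recover a planted 60/40 split and sum to 100", {
  set.seed(21)
  n_per <- 20L
  groups <- rep(ach$states, each = n_per)
  n <- length(groups)
  dims <- c(5L, 5L, 4L)   # 100 voxels: 60 ACH-monotone, 40 reversed
  nvox <- prod(dims)
  mu_ach <- c(0.9, 0.8, 0.7, 0.6)[match(groups, ach$states)]
  mu_rev <- c(0.6, 0.7, 0.8, 0.9)[match(groups, ach$states)]
  vals <- array(0, dim = c(dims, n))
  flat <- matrix(0, nvox, n)
  flat[1:60, ] <- matrix(rep(mu_ach, each = 60L), 60L, n) +
    rnorm(60L * n, 0, 0.02)
  flat[61:100, ] <- matrix(rep(mu_rev, each = 40L), 40L, n) +
    rnorm(40L * n, 0, 0.02)
  vals <- array(flat, dim = c(dims, n))
  ds <- voxel_dataset(vals, c(2, 2, 2))
  ct <- cohort_table(make_cohort_df(n))
  ev <- voxelwise_compare(ds, ct, permutation_sequences(),
                          validate_config(list()), groups = groups)
  pct <- winner_percentages(ev)
  expect_equal(unname(pct["ACH"]), 60, tolerance = 2 / 60)
  rev_name <- ev$sequence_names[ev$winner[length(ev$winner)]]
  expect_equal(sum(pct), 100)
  # permuting subject order leaves the winner map unchanged
  perm <- sample(n)
  ds2 <- voxel_dataset(vals[, , , perm], c(2, 2, 2))
  ev2 <- voxelwise_compare(ds2, ct, permutation_sequences(),
                           validate_config(list()), groups = groups[perm])
  expect_identical(ev$winner, ev2$winner)
})

test_that("single-sequence comparison wins everywhere by construction", {
  pl <- make_planted_dataset()
  one <- sequence_set(list(ach), reference = "ACH")
  ev <- voxelwise_compare(pl$dataset, pl$cohort, one,
                          validate_config(list()), groups = pl$groups)
  expect_equal(unname(winner_percentages(ev)["ACH"]), 100)
})

test_that("roi_summary reports winner, trend and reference VX%", {
  pl <- make_planted_dataset(sd = 0.01, seed = 2L)
  dims <- grid_shape(pl$dataset)
  roi <- roi_mask("box", array(TRUE, dims))
  cfg <- validate_config(list())
  ev <- voxelwise_compare(pl$dataset, pl$cohort, permutation_sequences(),
                          cfg, groups = pl$groups)
  rs <- roi_summary(pl$dataset, pl$cohort, roi,
                    permutation_sequences(), cfg, groups = pl$groups,
                    evidence = ev)
  expect_identical(rs$best_sequence, "ACH")
  expect_equal(rs$reference_rank, 1L)
  expect_equal(rs$ref_vx_pct, 100)
  expect_lt(rs$p, 1e-6)
})

test_that("the ROI trend t equals a hand-computed OLS contrast", {
  set.seed(22)
  n_per <- 4L
  groups <- rep(ach$states, each = n_per)
  y <- rnorm(16L, rep(c(4, 3, 2.5, 1), each = n_per))
  cfg <- validate_config(list())
  ct <- cohort_table(make_cohort_df(16L))
  rs <- roi_summary(cohort = ct, roi_volumes = y,
                    sequences = sequence_set(list(ach), "ACH"),
                    config = cfg, groups = groups)
  # hand OLS: intercept + centered position + centered covariates
  covs <- as.data.frame(ct)[, cfg$covariates]
  Z <- scale(as.matrix(covs), scale = FALSE)
  Z <- Z[, apply(Z, 2L, function(x) any(x != 0)), drop = FALSE]
  pos <- rep(1:4, each = n_per)
  X <- cbind(1, pos - mean(pos), Z)
  b <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% b
  s2 <- sum(res^2) / (16L - ncol(X))
  se <- sqrt(s2 * solve(t(X) %*% X)[2L, 2L])
  t_hand <- b[2L] / se
  expect_equal(rs$t, as.numeric(t_hand), tolerance = 1e-8)
})

test_that("logp_map flags a planted decline and not its reverse", {
  pl <- make_planted_dataset(n_per = 15L, sd = 0.02,
                             means = c(0.8, 0.72, 0.64, 0.56), seed = 3L)
  cfg <- validate_config(list())
  lp <- logp_map(pl$dataset, pl$cohort, ach, cfg, groups = pl$groups)
  inm <- lp$mask$mask
  expect_true(all(lp$significant[inm]))
  expect_true(all(lp$neg_log10_p[inm] >= 0))
  # reversed decline: the one-sided test finds nothing
  rev_groups <- ach$states[5L - match(pl$groups, ach$states)]
  lp_rev <- logp_map(pl$dataset, pl$cohort, ach, cfg, groups = rev_groups)
  expect_false(any(lp_rev$significant[inm]))
})

test_that("Braak composites aggregate disjoint constituents", {
  vols <- data.frame(entorhinal = c(1, 2), hippocampus = c(3, 4),
                     amygdala = c(5, 6), insula = c(7, 8),
                     temporal = c(1, 1), cingulate = c(2, 2),
                     precuneus = c(3, 3), frontal = c(4, 4),
                     parietal = c(5, 5), occipital = c(6, 6),
                     sensorimotor = c(7, 7))
  comps <- braak_composites(vols)
  expect_equal(comps[["I/II"]]$volume, c(4, 6))
  total <- Reduce(`+`, lapply(comps, `[[`, "volume"))
  expect_equal(total, rowSums(vols))
  expect_error(
    braak_composites(vols, list(a = "entorhinal", b = "entorhinal")),
    "more than one stage")
  expect_error(
    braak_composites(vols, list(a = "entorhinal", b = character(0))),
    "no constituent")
})

test_that("evidence maps write and re-read consistently", {
  pl <- make_planted_dataset()
  # the cohort only holds AD-continuum groups, so the non-AD paths drop
  ev <- suppressWarnings(
    voxelwise_compare(pl$dataset, pl$cohort, conversion_paths(),
                      validate_config(list()), groups = pl$groups))
  dir <- withr::local_tempdir()
  paths <- write_evidence_maps(ev, dir)
  expect_true(all(file.exists(paths)))
  win_img <- RNifti::readNifti(paths[["winner"]])
  inm <- ev$mask$mask
  expect_equal(array(as.numeric(win_img), dim(inm))[inm],
               as.numeric(ev$winner[inm]))
  legend <- jsonlite::read_json(paths[["legend"]])
  expect_identical(names(legend), ev$sequence_names)
})
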