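# Explicit-loop oracles for the overlap statistics, independent of the
# vectorised implementations.
loop_overlap <- function(sf, prob, thr) {
  hits <- 0; total <- 0
  for (i in seq_along(sf$grid)) {
    if (sf$grid[i] > 0) {
      total <- total + 1
      if (prob$grid[i] > thr) hits <- hits + 1
    }
  }
  hits / total
}
loop_ratio <- function(tm, pm, mask) {
  num <- 0; st <- 0; sp <- 0; msize <- 0
  for (i in seq_along(tm$grid)) {
    if (mask[i]) {
      msize <- msize + 1
      num <- num + tm$grid[i] * pm$grid[i]
      st <- st + tm$grid[i]
      sp <- sp + pm$grid[i]
    }
  }
  num * msize / (st * sp)
}

random_maps <- function(seed, n = 6) {
  set.seed(seed)
  dims <- c(n, n, n)
  tm <- array(0, dims)
  surv <- array(runif(prod(dims)) < 0.3, dims)
  tm[surv] <- runif(sum(surv), 3, 8)
  pm <- array(runif(prod(dims)), dims)
  list(t = voxel_map(tm, semantics = "t_score"),
       p = voxel_map(pm, semantics = "probability"),
       bin = voxel_map((tm > 0) * 1, semantics = "binary"))
}

test_that("overlap statistics match explicit-loop oracles to 1e-12", {
  for (seed in 1:10) {
    m <- random_maps(seed)
    expect_equal(overlap_proportion(m$bin, m$p, 0.5),
                 loop_overlap(m$bin, m$p, 0.5), tolerance = 1e-12)
    expect_equal(normalized_activation_ratio(m$t, m$p),
                 loop_ratio(m$t, m$p, m$t$mask), tolerance = 1e-12)
  }
})

test_that("the activation ratio has its algebraic identities", {
  dims <- c(4, 1, 1)
  mask <- array(TRUE, dims)
  const_t <- voxel_map(array(3, dims), mask, semantics = "t_score")
  const_p <- voxel_map(array(0.4, dims), mask, semantics = "probability")
  expect_equal(normalized_activation_ratio(const_t, const_p), 1)

  # worked 4-voxel example: t = (2,0,0,0), p = (1,.1,.1,.1)
  tm <- voxel_map(array(c(2, 0, 0, 0), dims), mask, semantics = "t_score")
  pm <- voxel_map(array(c(1, 0.1, 0.1, 0.1), dims), mask,
                  semantics = "probability")
  expect_equal(normalized_activation_ratio(tm, pm), (2 * 1 * 4) / (2 * 1.3),
               tolerance = 1e-12)

  # t mass entirely where p = 0 -> ratio 0
  pm0 <- voxel_map(array(c(0, 0.5, 0.5, 0.5), dims), mask,
                   semantics = "probability")
  expect_equal(normalized_activation_ratio(tm, pm0), 0)

  # homogeneity of degree 0 in each map
  m <- random_maps(3)
  r <- normalized_activation_ratio(m$t, m$p)
  t10 <- m$t; t10$grid <- 10 * t10$grid
  expect_equal(normalized_activation_ratio(t10, m$p), r, tolerance = 1e-12)
  p3 <- m$p; p3$grid <- p3$grid / 3
  expect_equal(normalized_activation_ratio(m$t, p3), r, tolerance = 1e-12)

  # invariance to voxel relabeling (consistent permutation of both maps)
  perm <- sample(length(m$t$grid))
  tp <- voxel_map(array(m$t$grid[perm], dim(m$t$grid)), semantics = "t_score")
  pp <- voxel_map(array(m$p$grid[perm], dim(m$p$grid)),
                  semantics = "probability")
  expect_equal(normalized_activation_ratio(tp, pp), r, tolerance = 1e-12)

  # degenerate inputs error
  empty <- voxel_map(array(0, dims), mask, semantics = "t_score")
  expect_error(normalized_activation_ratio(empty, pm), "empty")
  zero_p <- voxel_map(array(0, dims), mask, semantics = "probability")
  expect_error(normalized_activation_ratio(tm, zero_p), "zero-probability")
})

test_that("overlap proportion covers its degenerate and hand-counted cases", {
  dims <- c(10, 1, 1)
  sf <- voxel_map(array(1, dims), semantics = "binary")
  everywhere <- voxel_map(array(0.9, dims), semantics = "probability")
  expect_equal(overlap_proportion(sf, everywhere), 1)
  nowhere <- voxel_map(array(0, dims), semantics = "probability")
  expect_equal(overlap_proportion(sf, nowhere), 0)
  seven <- voxel_map(array(c(rep(0.5, 7), rep(0, 3)), dims),
                     semantics = "probability")
  expect_equal(overlap_proportion(sf, seven), 0.7)
  empty <- voxel_map(array(0, dims), semantics = "binary")
  expect_error(overlap_proportion(empty, seven), "empty")
  small <- voxel_map(array(1, c(2, 1, 1)), semantics = "binary")
  expect_error(overlap_proportion(small, seven), "share a grid")
})

test_that("thresholding is monotone and respects sign and mask", {
  cfg <- small_config(n_per_group = 12, n_trials = 4, seed = 29)
  co <- simulate_cohort(cfg)
  tab <- co$ground_truth$subject_table
  glm <- fit_voxelwise_glm(lapply(co$subjects, `[[`, "volume"),
                           tab$mmn_amp_true, tab[, c("age", "tiv")])
  b_strict <- threshold_map(glm, 0.001)
  b_loose <- threshold_map(glm, 0.01)
  # smaller threshold -> subset of surviving voxels (brute-force check)
  expect_true(all(which(b_strict$grid == 1) %in% which(b_loose$grid == 1)))
  # degenerate threshold 1 keeps the whole positive-t portion of the mask
  b_all <- threshold_map(glm, 1)
  expect_equal(which(b_all$grid == 1),
               which(glm$mask & glm$t$grid > 0))
  # thresholded t map has t scores on exactly the surviving set
  tt <- threshold_t_map(glm, 0.01)
  expect_equal(tt$grid > 0, b_loose$grid > 0)
  expect_true(all(tt$grid[tt$grid > 0] == glm$t$grid[tt$grid > 0]))
})

test_that("the voxelwise GLM is calibrated under amplitude permutation", {
  cfg <- small_config(n_per_group = 12, n_trials = 4, seed = 37,
                      attenuation = c(controls = 0, patients = 0))
  co <- simulate_cohort(cfg)
  tab <- co$ground_truth$subject_table
  vols <- lapply(co$subjects, `[[`, "volume")
  set.seed(41)
  n_hits <- 0; n_tests <- 0
  for (perm in 1:25) {
    amp <- sample(tab$mmn_amp_true)
    glm <- fit_voxelwise_glm(vols, amp, tab[, c("age", "tiv")])
    n_hits <- n_hits + sum(glm$p$grid[glm$mask] < 0.001)
    n_tests <- n_tests + sum(glm$mask)
  }
  frac <- n_hits / n_tests
  expect_lt(frac, 0.001 + 3 * sqrt(0.001 / n_tests))
})

test_that("a true structural link concentrates t mass in the MD map", {
  hits <- 0
  for (seed in 1:8) {
    cfg <- small_config(n_per_group = 12, n_trials = 4, seed = 100 + seed,
                        subject_amp_sd = 0.3, beta_struct = 0.12)
    co <- simulate_cohort(cfg)
    tab <- co$ground_truth$subject_table
    glm <- fit_voxelwise_glm(lapply(co$subjects, `[[`, "volume"),
                             tab$mmn_amp_true, tab[, c("age", "tiv")])
    md <- co$ground_truth$md_map$grid > 0.5
    surv <- threshold_map(glm, 0.001)$grid == 1
    # enrichment odds ratio of surviving voxels inside the generative map
    a <- sum(surv & md); b <- sum(surv & !md)
    c_ <- sum(!surv & md & glm$mask); d <- sum(!surv & !md & glm$mask)
    or <- (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5))
    if (or > 3) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("activation ratio dissociates function from structure", {
  # atrophy foci sit outside MD; the volume-amplitude link sits inside MD
  wins <- 0
  for (seed in 1:8) {
    cfg <- small_config(n_per_group = 12, n_trials = 4, seed = 200 + seed,
                        subject_amp_sd = 0.3, beta_struct = 0.12)
    co <- simulate_cohort(cfg)
    tab <- co$ground_truth$subject_table
    vols <- lapply(co$subjects, `[[`, "volume")
    glm <- fit_voxelwise_glm(vols, tab$mmn_amp_true, tab[, c("age", "tiv")])
    ratio_md <- normalized_activation_ratio(threshold_t_map(glm, 0.001),
                                            co$ground_truth$md_map)
    atro <- fit_atrophy_glm(vols, tab$group, tab[, c("age", "tiv")])
    atro_t <- threshold_t_map(atro, 0.001)
    ratio_struct <- structural_control_ratio(atro_t, co$ground_truth$md_map)
    if (ratio_md > 2 * ratio_struct) wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("uniform atrophy gives a structural ratio of about 1", {
  dims <- c(6, 6, 6)
  mask <- array(TRUE, dims)
  uni <- voxel_map(array(4, dims), mask, semantics = "t_score")
  prob <- voxel_map(array(runif(prod(dims)), dims), mask,
                    semantics = "probability")
  expect_equal(structural_control_ratio(uni, prob), 1, tolerance = 1e-12)
})

test_that("GLM design errors are raised by name", {
  cfg <- small_config(n_per_group = 7, n_trials = 4, seed = 43)
  co <- simulate_cohort(cfg)
  tab <- co$ground_truth$subject_table
  vols <- lapply(co$subjects, `[[`, "volume")
  expect_error(fit_voxelwise_glm(vols, rep(1, 14), tab[, c("age", "tiv")]),
               "collinear.*mmn")
  expect_error(fit_voxelwise_glm(vols, tab$mmn_amp_true,
                                 tab[, c("age", "tiv")],
                                 design_variant = "group_adjusted_2"),
               "groups required")
  # grouped designs carry the group columns
  glm5 <- fit_voxelwise_glm(vols, tab$mmn_amp_true, tab[, c("age", "tiv")],
                            design_variant = "group_adjusted_5",
                            groups = tab$group)
  expect_true("patients" %in% glm5$design$columns)
  glm_p <- fit_voxelwise_glm(vols, tab$mmn_amp_true, tab[, c("age", "tiv")],
                             design_variant = "patients_only",
                             groups = tab$group)
  expect_equal(glm_p$design$n_subjects, 7)
})

test_that("voxel maps validate and round-trip through NIfTI", {
  expect_error(voxel_map(array(2, c(2, 2, 2)), semantics = "probability"),
               "\\[0, 1\\]")
  expect_error(voxel_map(array(0.5, c(2, 2, 2)), semantics = "binary"),
               "binary")
  m <- voxel_map(array(rnorm(27), c(3, 3, 3)), voxel_mm = 4,
                 semantics = "volume")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_voxel_map(m, path)
  m2 <- read_voxel_map(path, semantics = "volume")
  expect_equal(m2$grid, m$grid, tolerance = 1e-6)
  expect_equal(m2$voxel_mm, 4)

  # nearest-neighbour regrid: identity on the same grid
  rg <- regrid_nearest(m, dim(m$grid))
  expect_equal(rg$grid, m$grid)
  # downsample by 2 picks source voxels
  half <- regrid_nearest(m, c(2, 2, 2), target_voxel_mm = 8)
  expect_true(all(half$grid %in% m$grid))
})
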