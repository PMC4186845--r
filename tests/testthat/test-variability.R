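# Voxelwise variability maps and their across-subject correlation with
# behavioural scores.

test_that("voxel SD matches hand-computed values and conventions", {
  d <- c(2, 1, 1)
  mk <- array(TRUE, d)
  arr <- array(0, c(d, 3))
  arr[1, 1, 1, ] <- c(0, 10, -10)
  pc <- pc_series(arr, mk, 2)
  expect_equal(voxel_sd(pc)$sd[1, 1, 1], sqrt(200 / 3))        # 8.1650
  expect_equal(round(voxel_sd(pc)$sd[1, 1, 1], 4), 8.1650)
  expect_equal(voxel_sd(pc, ddof = 1)$sd[1, 1, 1], 10)
  expect_equal(voxel_sd(pc)$sd[2, 1, 1], 0)                    # constant

  alt <- array(rep(c(3, -3), 10), c(1, 1, 1, 20))
  pca <- pc_series(alt, array(TRUE, c(1, 1, 1)), 2)
  expect_equal(voxel_sd(pca)$sd[1, 1, 1], 3)
})

test_that("score correlation agrees with the least-squares slope test", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- correlate_with_scores(x, y)
    fit <- summary(lm(x ~ y))$coefficients
    expect_equal(abs(got$t), abs(fit["y", "t value"]), tolerance = 1e-10)
    expect_equal(got$p, fit["y", "Pr(>|t|)"], tolerance = 1e-10)
    expect_equal(got$r, cor(x, y), tolerance = 1e-12)
  }
  v <- rnorm(10)
  expect_equal(correlate_with_scores(v, v)$r, 1)
  pair <- exact_corr_pair(10, 0.63, seed = 5)
  expect_equal(correlate_with_scores(pair$x, pair$y)$r, 0.63)
  expect_lt(abs(correlate_with_scores(pair$x, pair$y)$p - 0.05), 0.005)
  expect_error(correlate_with_scores(rep(1, 10), rnorm(10)), "variance")
  expect_error(correlate_with_scores(rnorm(5), rnorm(4)), "lengths")
})

test_that("cohort variability map recovers an injected ROI effect", {
  medians <- vapply(1:5, function(s) {
    coh <- tiny_cohort(seed = 600 + s, n_subjects = 10, grid = c(20, 20, 16),
                       n_t = 60, effect_rois = list(list(label = 1,
                                                         target_r = 0.9)))
    maps <- lapply(coh$subjects, function(su) {
      voxel_sd(raw_pc(su), subject_id = su$subject_id)
    })
    sm <- cohort_variability_map(maps,
                                 vapply(coh$subjects, `[[`, 0, "score"))
    expect_true(all(abs(sm$r[sm$mask]) <= 1))
    median(sm$r[coh$parcellation == 1 & sm$mask])
  }, 0)
  expect_gte(sum(medians > 0.6), 4)
  expect_true(all(medians > 0.7 - 0.3))  # no catastrophic miss
  expect_true(median(medians) >= 0.7 && median(medians) <= 0.97)
})

test_that("null cohorts give a calibrated voxelwise false-positive rate", {
  fr <- vapply(1:6, function(s) {
    coh <- tiny_cohort(seed = 700 + s, n_subjects = 10, grid = c(20, 20, 16),
                       n_t = 60)
    maps <- lapply(coh$subjects, function(su) {
      voxel_sd(raw_pc(su), subject_id = su$subject_id)
    })
    sm <- cohort_variability_map(maps,
                                 vapply(coh$subjects, `[[`, 0, "score"))
    expect_gt(sum(sm$mask), 1000)
    mean(sm$p[sm$mask] < 0.05)
  }, 0)
  expect_lt(abs(mean(fr) - 0.05), 0.02)
})

test_that("variability is scale-equivariant and across-subject r invariant", {
  coh <- tiny_cohort(seed = 31, n_subjects = 6, n_t = 40)
  pcs <- lapply(coh$subjects, raw_pc)
  scores <- vapply(coh$subjects, `[[`, 0, "score")
  maps <- lapply(pcs, voxel_sd)
  scaled <- lapply(pcs, function(p) pc_series(3 * p$data, p$mask, p$tr))
  maps3 <- lapply(scaled, voxel_sd)
  expect_equal(maps3[[1]]$sd, 3 * maps[[1]]$sd)
  r1 <- cohort_variability_map(maps, scores)$r
  r3 <- cohort_variability_map(maps3, scores)$r
  expect_equal(r1, r3, tolerance = 1e-12)
})

test_that("cluster-average SD behaves like the variance of a mean", {
  d <- c(3, 1, 1)
  n_t <- 4000
  set.seed(55)
  base <- rnorm(n_t)
  arr <- array(0, c(d, n_t))
  arr[1, 1, 1, ] <- base
  arr[2, 1, 1, ] <- base
  arr[3, 1, 1, ] <- rnorm(n_t)
  pc <- pc_series(arr, array(TRUE, d), 2)

  two_same <- array(FALSE, d); two_same[1:2, 1, 1] <- TRUE
  expect_equal(cluster_average_sd(pc, two_same), voxel_sd(pc)$sd[1, 1, 1])

  indep <- array(FALSE, d); indep[c(1, 3), 1, 1] <- TRUE
  ratio <- cluster_average_sd(pc, indep) /
    mean(voxel_sd(pc)$sd[c(1, 3)])
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.05)

  const <- array(0, c(d, 10))
  pcc <- pc_series(const, array(TRUE, d), 2)
  expect_equal(cluster_average_sd(pcc, two_same), 0)
  expect_error(cluster_average_sd(pc, array(FALSE, d)), "empty")
})
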