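# Preprocessing chain: frame discard, morphology, smoothing, the nuisance
# design, OLS with mean restoration, percent change, concatenation and
# framewise displacement.

test_that("initial-volume discard trims the time axis only", {
  a <- array(rnorm(4 * 4 * 2 * 240), c(4, 4, 2, 240))
  out <- discard_initial(a, 5)
  expect_identical(dim(out), c(4L, 4L, 2L, 235L))
  expect_identical(out[, , , 1], a[, , , 6])
  expect_identical(discard_initial(a, 0), a)
  expect_error(discard_initial(a, 240), "n_discard")
})

test_that("per-slice erosion matches the brute-force structuring-element oracle", {
  slab <- array(TRUE, c(10, 10, 1))
  out <- erode_mask_2d(slab, 2)
  expect_equal(sum(out), 36)
  expect_true(all(which(out, arr.ind = TRUE)[, 1:2] %in% 3:8))

  empty <- array(FALSE, c(6, 6, 3))
  expect_identical(erode_mask_2d(empty, 2), empty)

  set.seed(71)
  rnd <- array(runif(12 * 12 * 4) > 0.3, c(12, 12, 4))
  expect_identical(erode_mask_2d(rnd, 0), rnd)
  expect_identical(erode_mask_2d(rnd, 1), oracle_erode(rnd, se_offsets_2d))
  expect_identical(erode_mask_2d(rnd, 2),
                   oracle_erode(oracle_erode(rnd, se_offsets_2d),
                                se_offsets_2d))
  expect_identical(erode_mask_3d(rnd, 1), oracle_erode(rnd, se_offsets_3d))
})

test_that("gaussian smoothing has the closed-form width and preserves mass", {
  expect_equal(fwhm_to_sigma(3, 2), 3 / (2 * 2 * sqrt(2 * log(2))))
  expect_equal(fwhm_to_sigma(3, 2), 0.63699, tolerance = 1e-4)

  const <- array(7, c(10, 10, 8))
  expect_equal(smooth_gaussian(const, 3, 2), const, tolerance = 1e-10)

  imp <- array(0, c(15, 15, 15))
  imp[8, 8, 8] <- 1
  sm <- smooth_gaussian(imp, 3, 2)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_identical(smooth_gaussian(imp, 0, 2), imp)
})

test_that("tissue regions come from thresholding then 3D erosion", {
  pv <- array(0, c(12, 12, 12))
  pv[3:10, 3:10, 3:10] <- 1
  reg <- tissue_region(pv, 0.99, 2)
  expect_equal(sum(reg), 4^3)
  expect_true(all(which(reg, arr.ind = TRUE) %in% 5:8))

  expect_warning(empty <- tissue_region(array(0.5, c(6, 6, 6)), 0.99, 0),
                 "empty")
  expect_true(attr(empty, "empty"))
  expect_identical(unname(tissue_region(pv, 0.99, 0)), pv >= 0.99,
                   ignore_attr = TRUE)
})

test_that("the nuisance design has exactly 19 labelled columns", {
  n_t <- 60
  set.seed(2)
  motion <- matrix(rnorm(n_t * 6), n_t, 6)
  des <- build_nuisance_design(motion, rnorm(n_t), rnorm(n_t))
  expect_equal(ncol(des$matrix), 19)
  expect_length(des$column_labels, 19)
  expect_true(all(des$matrix[, "mean"] == 1))
  # derivative columns are backward differences with leading zero
  expect_equal(des$matrix[, "dmotion_1"], c(0, diff(motion[, 1])))

  des2 <- build_nuisance_design(matrix(1.5, n_t, 6), rnorm(n_t), rnorm(n_t))
  expect_true(all(des2$matrix[, paste0("dmotion_", 1:6)] == 0))

  wm <- rnorm(n_t)
  expect_warning(des3 <- build_nuisance_design(motion, wm, wm), "collinear")
  expect_gt(des3$condition_number, 1e8)
  expect_error(build_nuisance_design(motion[1:10, ], rnorm(10), rnorm(10)),
               "20 frames")
})

test_that("nuisance regression removes the design and restores the mean", {
  n_t <- 50
  ts <- rnorm(n_t, mean = 30)
  intercept_only <- list(matrix = matrix(1, n_t, 1))
  expect_equal(regress_and_restore_mean(ts, intercept_only), ts)

  lin <- seq_len(n_t) - 1
  des <- list(matrix = cbind(1, lin))
  trendy <- 2 * lin + 5
  expect_equal(regress_and_restore_mean(trendy, des),
               rep(mean(trendy), n_t))

  set.seed(8)
  motion <- matrix(rnorm(n_t * 6), n_t, 6)
  full <- build_nuisance_design(motion, rnorm(n_t), rnorm(n_t))
  y <- rnorm(n_t, 100)
  cleaned <- regress_and_restore_mean(y, full)
  resid <- cleaned - mean(y)
  for (j in seq_len(19)) {
    x <- full$matrix[, j]
    expect_lt(abs(sum(resid * x)) / (sqrt(sum(resid^2)) * sqrt(sum(x^2))),
              1e-8)
  }
})

test_that("percent change normalises to a zero-mean percent series", {
  expect_equal(percent_change(c(100, 110, 90)), c(0, 10, -10))
  expect_equal(percent_change(rep(42, 10)), rep(0, 10))
  expect_error(percent_change(c(-1, 1)), "near zero")
  set.seed(4)
  x <- rnorm(100, 500, 20)
  expect_lt(abs(mean(percent_change(x))), 1e-9)
})

test_that("runs are concatenated after per-run normalisation", {
  d <- c(5, 5, 4)
  mk <- array(TRUE, d)
  mkrun <- function(n_t, seed) {
    set.seed(seed)
    raw <- array(rnorm(prod(d) * n_t, 100, 5), c(d, n_t))
    Y <- matrix(raw, prod(d), n_t)
    pcm <- 100 * (Y / rowMeans(Y) - 1)
    pc_series(array(pcm, c(d, n_t)), mk, tr = 2)
  }
  r1 <- mkrun(235, 1); r2 <- mkrun(235, 2)
  cat2 <- concatenate_runs(list(r1, r2))
  expect_equal(dim(cat2$data)[4], 470)
  expect_identical(cat2$data[, , , 1:235], r1$data)
  expect_identical(concatenate_runs(list(r1)), r1)

  d2 <- c(6, 5, 4)
  r3 <- pc_series(array(0, c(d2, 10)), array(TRUE, d2), 2)
  expect_error(concatenate_runs(list(r1, r3)), "grid")
})

test_that("framewise displacement follows the Power formula", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m)$fd, rep(0, 10))

  m1 <- m; m1[6:10, 1] <- 0.1
  fd1 <- framewise_displacement(m1)
  expect_equal(fd1$fd[6], 0.1)
  expect_equal(sum(fd1$fd), 0.1)

  m2 <- m; m2[4:10, 5] <- 0.01
  fd2 <- framewise_displacement(m2, head_radius = 50,
                                rotation_unit = "radians")
  expect_equal(fd2$fd[4], 0.5)

  m3 <- m; m3[4:10, 5] <- 1  # one degree step
  fd3 <- framewise_displacement(m3, rotation_unit = "degrees")
  expect_equal(fd3$fd[4], 50 * pi / 180)

  # invariance to constant offsets on any parameter
  set.seed(12)
  mm <- matrix(rnorm(60), 10, 6)
  shifted <- sweep(mm, 2, runif(6, -5, 5), "+")
  expect_equal(framewise_displacement(mm)$fd,
               framewise_displacement(shifted)$fd)
  expect_error(framewise_displacement(mm, rotation_unit = "turns"), "unit")
})

test_that("the full subject chain yields zero-mean percent series and FD", {
  coh <- tiny_cohort(seed = 21, n_subjects = 3, n_t = 40)
  pp <- preprocess_subject(coh$subjects[[1]], n_discard = 5)
  d <- dim(pp$pc$data)
  expect_equal(d[4], 35)
  Y <- matrix(pp$pc$data, prod(d[1:3]), d[4])
  mu <- rowMeans(Y[as.vector(pp$pc$mask), , drop = FALSE])
  expect_lt(max(abs(mu)), 1e-9)
  expect_gt(pp$mean_fd, 0)
  expect_equal(pp$log$n_discard, 5)
})

test_that("the optional low-pass filter reduces per-voxel variability", {
  coh <- tiny_cohort(seed = 22, n_subjects = 3, n_t = 60)
  plain <- preprocess_subject(coh$subjects[[1]])
  filt <- preprocess_subject(coh$subjects[[1]], lowpass = TRUE)
  sd0 <- voxel_sd(plain$pc)$sd
  sd1 <- voxel_sd(filt$pc)$sd
  mask <- plain$pc$mask & filt$pc$mask
  expect_true(all(sd1[mask] < sd0[mask]))
})
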