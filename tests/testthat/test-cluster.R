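# Cluster-extent inference: component labelling, the Monte-Carlo null, the
# minimum corrected extent, extraction and reporting.

test_that("compiled component labelling matches the BFS oracle", {
  set.seed(91)
  for (i in 1:20) {
    mask <- array(runif(12^3) < 0.25, c(12, 12, 12))
    for (conn in c(6L, 18L, 26L)) {
      expect_identical(component_sizes(label_components(mask, conn)),
                       component_sizes(oracle_components(mask, conn)))
    }
  }
  # labelled partition covers exactly the mask
  mask <- array(runif(10^3) < 0.3, c(10, 10, 10))
  lab <- label_components(mask, 6L)
  expect_identical(lab > 0, mask)
})

test_that("the null distribution behaves at threshold extremes and is seeded", {
  mask <- array(TRUE, c(12, 12, 12))
  nd1 <- simulate_null_distribution(mask, fwhm = 0, voxel_size = 2,
                                    voxel_p = 0.9999, n_iter = 100, seed = 4)
  expect_true(all(nd1$max_cluster_sizes >= 0.98 * sum(mask)))

  # unsmoothed noise: suprathreshold voxel fraction matches the binomial rate
  set.seed(10)
  fr <- replicate(60, {
    z <- gaussian_null_field(mask, 0, 2)
    mean(abs(z) > qnorm(0.975))
  })
  expect_lt(abs(mean(fr) - 0.05), 0.01)

  nd2 <- simulate_null_distribution(mask, 3, 2, 0.05, n_iter = 100, seed = 7)
  nd3 <- simulate_null_distribution(mask, 3, 2, 0.05, n_iter = 100, seed = 7)
  expect_identical(nd2$max_cluster_sizes, nd3$max_cluster_sizes)
  expect_error(simulate_null_distribution(array(FALSE, c(4, 4, 4)), 3, 2),
               "empty")
})

test_that("the minimum corrected extent follows the quantile definition", {
  mk <- function(sizes) {
    structure(list(max_cluster_sizes = sizes, n_iter = length(sizes),
                   voxel_p = 0.05, fwhm = 3, voxel_size = 2,
                   connectivity = 6L, mask_size = 1000, seed = 1L),
              class = "null_cluster_dist")
  }
  expect_equal(min_cluster_size(mk(rep(10L, 200)), 0.05), 11L)
  # exactly 5% of iterations reach size 1, so k = 1 already satisfies the rule
  expect_equal(min_cluster_size(mk(c(rep(0L, 190), rep(5L, 10))), 0.05), 1L)
  expect_equal(min_cluster_size(mk(c(rep(0L, 180), rep(5L, 20))), 0.05), 6L)
  # near-unit alpha: any rarely-reached size passes immediately
  expect_equal(min_cluster_size(mk(c(rep(0L, 199), 3L)), 0.995), 1L)
  expect_warning(min_cluster_size(mk(rep(2L, 100)), 0.005), "resolution")
})

test_that("the corrected extent grows with smoothness and with alpha strictness", {
  mask <- array(TRUE, c(16, 16, 16))
  nd_smooth <- function(fw) {
    simulate_null_distribution(mask, fw, 2, 0.05, n_iter = 200, seed = 13)
  }
  k3 <- min_cluster_size(nd_smooth(3), 0.05)
  k6 <- min_cluster_size(nd_smooth(6), 0.05)
  expect_gte(k6, k3)

  nd <- nd_smooth(3)
  expect_gte(min_cluster_size(nd, 0.01), min_cluster_size(nd, 0.05))

  # stricter forming threshold cannot enlarge the corrected extent
  k_strict <- min_cluster_size(
    simulate_null_distribution(mask, 3, 2, 0.01, n_iter = 200, seed = 13),
    0.05)
  expect_lte(k_strict, k3)
})

test_that("extraction keeps only sufficiently large sign-homogeneous components", {
  d <- c(20, 20, 10)
  mask <- array(TRUE, d)
  p <- array(0.5, d)
  r <- array(0.1, d)
  blob1 <- expand.grid(i = 2:11, j = 2:7, k = 2:6)       # 300 voxels
  blob2 <- expand.grid(i = 14:18, j = 10:14, k = 7:10)   # 100 voxels
  for (b in list(blob1, blob2)) {
    idx <- as.matrix(b)
    p[idx] <- 0.001
    r[idx] <- 0.8
  }
  stat <- make_stat_map(r, p, mask)
  kept <- extract_clusters(stat, voxel_p = 0.05, k_min = 258)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$n_voxels, 300)

  both <- extract_clusters(stat, voxel_p = 0.05, k_min = 1)
  expect_equal(sort(both$n_voxels), c(100, 300))

  none <- extract_clusters(make_stat_map(r, array(0.5, d), mask),
                           voxel_p = 0.05, k_min = 1)
  expect_equal(nrow(none), 0)

  # adjacent opposite-sign voxels split into separate clusters
  r2 <- array(0, d); p2 <- array(0.5, d)
  r2[5:6, 5, 5] <- c(0.9, -0.9); p2[5:6, 5, 5] <- 0.001
  split <- extract_clusters(make_stat_map(r2, p2, mask), 0.05, 1)
  expect_equal(nrow(split), 2)
  merged <- extract_clusters(make_stat_map(r2, p2, mask), 0.05, 1,
                             split_sign = FALSE)
  expect_equal(nrow(merged), 1)
})

test_that("reports carry peaks, labels, sides and oriented coordinates", {
  d <- c(11, 11, 11)
  mask <- array(TRUE, d)
  parc <- array(0L, d)
  parc[2:4, 5:7, 5:7] <- 1L   # low-x parcel: RAS left, LPS x > 0
  parc[8:10, 5:7, 5:7] <- 2L
  labels <- tibble::tibble(label = 1:2, name = c("caudate", "caudate"),
                           side = c("L", "R"))
  r <- array(0, d); p <- array(0.5, d)
  r[3, 6, 6] <- 0.87; p[3, 6, 6] <- 2 * pt(-0.87 * sqrt(8 / (1 - 0.87^2)), 8)
  stat <- make_stat_map(r, p, mask, n_subjects = 10, voxel_size = 2)
  cl <- extract_clusters(stat, voxel_p = 0.05, k_min = 1)
  rep_lps <- report_clusters(cl, stat, parc, labels, orientation = "LPS")
  expect_equal(rep_lps$region, "caudate")
  expect_equal(rep_lps$side, "L")
  # voxel (3,6,6) of an 11-grid at 2 mm, origin-centred: RAS x = -6 -> LPS +6
  expect_equal(rep_lps$peak_x, 6)
  expect_equal(rep_lps$peak_y, 0)
  expect_equal(rep_lps$peak_r, 0.87)
  expect_equal(signif(rep_lps$peak_p, 1), 0.001)

  rep_ras <- report_clusters(cl, stat, parc, labels, orientation = "RAS")
  expect_equal(rep_ras$peak_x, -6)
  expect_equal(rep_ras$side, "L")

  # deterministic tie-break at equal |r|: smallest linear index wins
  r2 <- array(0, d); p2 <- array(0.5, d)
  r2[5, 5, 5] <- 0.9; r2[6, 5, 5] <- 0.9
  p2[5:6, 5, 5] <- 0.001
  st2 <- make_stat_map(r2, p2, mask, voxel_size = 2)
  cl2 <- extract_clusters(st2, 0.05, 1)
  rp2 <- report_clusters(cl2, st2, parc, labels)
  # voxel (5,5,5) wins over (6,5,5); RAS x = (5-6)*2 = -2 -> LPS +2
  expect_equal(rp2$peak_x, 2)
  comp <- rp2$composition[[1]]
  expect_true(all(c("label", "region", "n_voxels") %in% names(comp)))
})

test_that("formatted reports round the way results tables print", {
  d <- c(8, 8, 8)
  mask <- array(TRUE, d)
  r <- array(0, d); p <- array(0.5, d)
  r[4, 4, 4] <- 0.8765; p[4, 4, 4] <- 0.000423
  stat <- make_stat_map(r, p, mask)
  cl <- extract_clusters(stat, 0.05, 1)
  fr <- format_cluster_report(report_clusters(cl, stat, array(0L, d),
                                              tibble::tibble(label = integer(),
                                                             name = character())))
  expect_equal(fr$peak_r, 0.88)
  expect_equal(fr$peak_p, 0.0004)
  expect_false("composition" %in% names(fr))
})
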