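# Voxelwise BOLD signal variability and its across-subject correlation with
# a behavioural score.

#' Voxelwise standard deviation of a percent-change series
#'
#' BOLD signal variability: the per-voxel temporal standard deviation of the
#' percent-change time series, in percent units. The population formula
#' (divide by T) is the default; with several hundred frames the sample
#' formula differs negligibly, and the convention used travels with the map.
#'
#' @param pc A [pc_series()].
#' @param ddof Delta degrees of freedom: 0 (population, default) or 1
#'   (sample).
#' @param subject_id Identifier carried along for cohort bookkeeping.
#' @return A `variability_map`: list with `sd` (3D, percent), `mask`,
#'   `subject_id`, `ddof`.
#' @export
voxel_sd <- function(pc, ddof = 0L, subject_id = NA_character_) {
  stopifnot(inherits(pc, "pc_series"), ddof %in% c(0L, 1L))
  d <- dim(pc$data)
  if (d[4] < 2) abort("need at least two frames")
  Y <- matrix(pc$data, prod(d[1:3]), d[4])
  mu <- rowMeans(Y)
  ss <- rowMeans(Y^2) - mu^2
  ss[ss < 0] <- 0
  sdv <- sqrt(ss * if (ddof == 1L) d[4] / (d[4] - 1) else 1)
  sdv[!as.vector(pc$mask)] <- 0
  structure(list(sd = array(sdv, d[1:3]), mask = pc$mask,
                 subject_id = subject_id, ddof = ddof),
            class = "variability_map")
}

#' Correlate a per-subject metric with behavioural scores
#'
#' Pearson correlation across subjects with the two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom —
#' equivalent to the slope test of a simple linear regression of the metric
#' on the score.
#'
#' @param values Per-subject scalars (e.g. mean FD, ROI variability).
#' @param scores Per-subject behavioural scores (percent).
#' @return One-row tibble: `r`, `p`, `t`, `df`, `n`.
#' @examples
#' correlate_with_scores(example_cohort_summary()$mean_fd_mm,
#'                       example_cohort_summary()$score_pct)
#' @export
correlate_with_scores <- function(values, scores) {
  n <- length(values)
  if (n != length(scores)) abort("lengths differ")
  if (n < 3) abort("need at least three subjects")
  if (anyNA(values) || anyNA(scores)) abort("missing values are not allowed")
  if (sd(values) == 0 || sd(scores) == 0)
    abort("zero variance: correlation undefined")
  r <- cor(values, scores)
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, p = 2 * pt(-abs(t), df), t = t, df = df, n = n)
}

# Vectorised across-subject correlation: M is subjects x voxels, scores is
# length-n. Zero-variance voxels give NA.
.corr_columns <- function(M, scores) {
  n <- nrow(M)
  sc <- scores - mean(scores)
  Mc <- sweep(M, 2, colMeans(M), "-")
  num <- as.vector(crossprod(Mc, sc))
  den <- sqrt(colSums(Mc^2) * sum(sc^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(t), df)
  p[!is.na(r) & abs(r) >= 1] <- 0
  list(r = r, p = p)
}

.new_stat_map <- function(r_v, p_v, mask, n_subjects, metric_name,
                          affine, voxel_size) {
  d <- dim(mask)
  r <- array(NA_real_, d); p <- array(NA_real_, d)
  r[as.vector(mask)] <- r_v[as.vector(mask)]
  p[as.vector(mask)] <- p_v[as.vector(mask)]
  structure(list(r = r, p = p, mask = mask, n_subjects = n_subjects,
                 metric_name = metric_name, affine = affine,
                 voxel_size = voxel_size),
            class = "cohort_stat_map")
}

#' @export
print.cohort_stat_map <- function(x, ...) {
  cat(sprintf(
    "<cohort_stat_map> metric \"%s\", %d subjects, %d mask voxels, max |r| = %.3f\n",
    x$metric_name, x$n_subjects, sum(x$mask),
    max(abs(x$r[x$mask]), na.rm = TRUE)))
  invisible(x)
}

#' Across-subject correlation map of BOLD signal variability with scores
#'
#' Applies [correlate_with_scores()] voxelwise (vectorised) within the
#' intersection of the subjects' analysis masks.
#'
#' @param maps List of [voxel_sd()] maps, one per subject, on one grid.
#' @param scores Per-subject behavioural scores, same order.
#' @param affine 4x4 RAS affine carried to the result (for reporting).
#' @param voxel_size Voxel edge, mm.
#' @return A `cohort_stat_map`: 3D `r` and `p` arrays (NA outside the
#'   intersection mask), `n_subjects`, `metric_name = "variability"`.
#' @export
cohort_variability_map <- function(maps, scores, affine = NULL,
                                   voxel_size = 1) {
  n <- length(maps)
  if (n != length(scores)) abort("one score per map is required")
  ids <- vapply(maps, function(m) m$subject_id, "")
  if (anyDuplicated(stats::na.omit(ids))) abort("duplicate subject ids")
  d0 <- dim(maps[[1]]$sd)
  for (m in maps) {
    if (!identical(dim(m$sd), d0)) abort("maps are not on one grid")
  }
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  M <- do.call(rbind, lapply(maps, function(m) as.vector(m$sd)))
  cc <- .corr_columns(M, scores)
  if (is.null(affine)) affine <- .default_affine(d0, voxel_size)
  .new_stat_map(cc$r, cc$p, mask, n, "variability", affine, voxel_size)
}

#' Variability of the cluster-average time course
#'
#' Averages the percent-change time courses over a cluster, then takes the
#' SD of that average series. Because averaging cancels independent noise,
#' this is at most the mean of the voxelwise SDs.
#'
#' @param pc A [pc_series()].
#' @param cluster_mask Logical 3D array (or vector of linear voxel indices).
#' @param ddof 0 (population) or 1 (sample).
#' @return Scalar SD in percent units.
#' @export
cluster_average_sd <- function(pc, cluster_mask, ddof = 0L) {
  stopifnot(inherits(pc, "pc_series"))
  d <- dim(pc$data)
  sel <- if (is.logical(cluster_mask)) {
    which(as.vector(cluster_mask) & as.vector(pc$mask))
  } else {
    intersect(as.integer(cluster_mask), which(as.vector(pc$mask)))
  }
  if (length(sel) == 0) abort("cluster is empty within the analysis mask")
  Y <- matrix(pc$data, prod(d[1:3]), d[4])
  avg <- colMeans(Y[sel, , drop = FALSE])
  v <- mean(avg^2) - mean(avg)^2
  v <- max(v, 0)
  sqrt(v * if (ddof == 1L) d[4] / (d[4] - 1) else 1)
}

#' Scores and mean framewise displacement of the ten-subject example cohort
#'
#' Per-subject behavioural performance scores (percent correct) and mean
#' framewise displacement (mm) for the ten-subject example cohort used in
#' the documentation: the worked motion-confound example checks that head
#' motion is unrelated to performance (r = 0.09, p = 0.80).
#'
#' @return Tibble with `subject`, `score_pct`, `mean_fd_mm`.
#' @export
example_cohort_summary <- function() {
  tibble::tibble(
    subject = 1:10,
    score_pct = c(95.9, 85.64, 78.75, 76.6, 90.06,
                  83.59, 80.13, 88.46, 92.27, 90.48),
    mean_fd_mm = c(0.081, 0.058, 0.062, 0.102, 0.105,
                   0.085, 0.100, 0.108, 0.088, 0.097)
  )
}
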