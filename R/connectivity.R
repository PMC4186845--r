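# Seed-based functional connectivity: parcel-mean time courses, whole-brain
# seed correlation maps, the Fisher z-transformation, and the across-subject
# correlation of z with behavioural scores.

#' Fisher z-transformation
#'
#' `z = atanh(r)`, with `|r|` clipped to `1 - 1e-7` first so saturated
#' correlations map to a large finite value rather than infinity.
#'
#' @param r Correlations in `[-1, 1]`.
#' @param clip Clipping bound on `|r|`.
#' @return Fisher-transformed values.
#' @examples
#' fisher_z(0.5)
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Seed definitions from a parcellation label table
#'
#' @param labels Tibble with `label`, `name`, `side` (as in a `bold_cohort`).
#' @param parcellation Integer 3D array.
#' @return Tibble of seed definitions: `label`, `name`, `side`, `n_voxels`.
#' @export
seed_definitions <- function(labels, parcellation) {
  counts <- table(factor(parcellation[parcellation > 0],
                         levels = labels$label))
  out <- dplyr::mutate(labels, n_voxels = as.integer(counts[as.character(
    .data$label)]))
  missing <- out$label[out$n_voxels == 0 | is.na(out$n_voxels)]
  if (length(missing) > 0)
    abort(paste0("labels absent from parcellation: ",
                 paste(missing, collapse = ", ")))
  out
}

#' Mean time course of a region of interest
#'
#' Unweighted mean over the ROI voxels (intersected with the analysis mask)
#' at each timepoint.
#'
#' @param pc A [pc_series()].
#' @param roi_mask Logical 3D array, or an integer parcellation plus `label`.
#' @param label Parcel label to select when `roi_mask` is an integer array.
#' @return Length-T numeric series.
#' @export
roi_mean_timeseries <- function(pc, roi_mask, label = NULL) {
  stopifnot(inherits(pc, "pc_series"))
  if (!is.null(label)) roi_mask <- roi_mask == label
  sel <- which(as.vector(roi_mask) & as.vector(pc$mask))
  if (length(sel) == 0) abort("ROI does not intersect the analysis mask")
  d <- dim(pc$data)
  colMeans(matrix(pc$data, prod(d[1:3]), d[4])[sel, , drop = FALSE])
}

#' Whole-brain seed correlation map with Fisher z
#'
#' Pearson correlation of every in-mask voxel's time course with the seed
#' time course, and its Fisher z-transform. Seed-interior voxels are
#' retained in the map (they correlate highly by construction); cluster
#' reporting can exclude them downstream.
#'
#' @param pc A [pc_series()].
#' @param seed_ts Length-T seed time course (nonconstant).
#' @param seed Optional seed definition (one row of [seed_definitions()]),
#'   carried in the result.
#' @param subject_id Carried in the result.
#' @return A `connectivity_map`: list with 3D `r` and `z` (NA outside the
#'   mask), `mask`, `seed`, `subject_id`.
#' @export
seed_correlation_map <- function(pc, seed_ts, seed = NULL,
                                 subject_id = NA_character_) {
  stopifnot(inherits(pc, "pc_series"))
  d <- dim(pc$data)
  if (length(seed_ts) != d[4]) abort("seed series length does not match")
  if (sd(seed_ts) == 0) abort("seed time course is constant")
  Y <- matrix(pc$data, prod(d[1:3]), d[4])
  sel <- which(as.vector(pc$mask))
  sc <- seed_ts - mean(seed_ts)
  Yc <- Y[sel, , drop = FALSE] -
    rowMeans(Y[sel, , drop = FALSE])
  num <- as.vector(Yc %*% sc)
  den <- sqrt(rowSums(Yc^2) * sum(sc^2))
  rv <- ifelse(den > 0, num / den, NA_real_)
  rv <- pmin(pmax(rv, -1), 1)
  r <- array(NA_real_, d[1:3]); r[sel] <- rv
  z <- array(NA_real_, d[1:3]); z[sel] <- fisher_z(rv)
  structure(list(r = r, z = z, mask = pc$mask, seed = seed,
                 subject_id = subject_id),
            class = "connectivity_map")
}

#' Across-subject correlation map of seed connectivity with scores
#'
#' Voxelwise Pearson correlation (and two-tailed p) of the Fisher-z
#' connectivity values with the behavioural scores, within the intersection
#' of subject masks. All maps must share one seed.
#'
#' @param maps List of [seed_correlation_map()] results, one per subject.
#' @param scores Per-subject scores, same order.
#' @param affine,voxel_size Spatial metadata carried to the result.
#' @return A `cohort_stat_map` with `metric_name = "connectivity:<seed>"`.
#'   Voxels where z is constant across subjects get `NA` (flagged
#'   undefined).
#' @export
cohort_connectivity_map <- function(maps, scores, affine = NULL,
                                    voxel_size = 1) {
  n <- length(maps)
  if (n != length(scores)) abort("one score per map is required")
  seeds <- unique(vapply(maps, function(m) {
    if (is.null(m$seed)) "" else paste(m$seed$label, m$seed$name, m$seed$side)
  }, ""))
  if (length(seeds) != 1) abort("all subjects must use the same seed")
  d0 <- dim(maps[[1]]$z)
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  M <- do.call(rbind, lapply(maps, function(m) {
    if (!identical(dim(m$z), d0)) abort("maps are not on one grid")
    as.vector(m$z)
  }))
  M[is.na(M)] <- 0
  cc <- .corr_columns(M, scores)
  if (is.null(affine)) affine <- .default_affine(d0, voxel_size)
  seed_name <- if (nzchar(seeds)) seeds else "seed"
  .new_stat_map(cc$r, cc$p, mask, n,
                paste0("connectivity:", seed_name), affine, voxel_size)
}
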