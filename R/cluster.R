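# Monte-Carlo cluster-extent familywise-error correction and cluster
# reporting: smooth-Gaussian null fields, the null distribution of the
# largest suprathreshold cluster, the minimum corrected cluster extent, and
# anatomically labelled cluster tables.

#' Label connected components of a binary volume
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces + edges +
#'   corners).
#' @return Integer 3D array; 0 is background, components are numbered from 1
#'   in order of first encounter (column-major).
#' @export
label_components <- function(mask, connectivity = 6L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  .label_components_cpp(mask, dim(mask), as.integer(connectivity))
}

.connectivity_code <- function(rule) {
  if (is.numeric(rule)) return(as.integer(rule))
  switch(rule, faces = 6L, edges = 18L, corners = 26L,
         abort("connectivity rule must be faces, edges or corners"))
}

#' One smooth standardised Gaussian null field
#'
#' White Gaussian noise over the full grid, smoothed at the given FWHM, then
#' restandardised to zero mean and unit variance within the mask — the null
#' field model underlying the Monte-Carlo cluster correction.
#'
#' @param mask Logical 3D array.
#' @param fwhm Smoothness, mm.
#' @param voxel_size Voxel edge, mm.
#' @return 3D array of z-values (defined everywhere; standardised within the
#'   mask).
#' @export
gaussian_null_field <- function(mask, fwhm, voxel_size) {
  d <- dim(mask)
  z <- smooth_gaussian(array(rnorm(prod(d)), d), fwhm, voxel_size)
  mu <- mean(z[mask])
  sg <- sd(z[mask])
  (z - mu) / sg
}

#' Monte-Carlo null distribution of the largest suprathreshold cluster
#'
#' Per iteration: fill the grid with white Gaussian noise, smooth at `fwhm`,
#' restandardise within the mask, apply the two-sided voxelwise threshold at
#' `voxel_p`, and record the size of the largest connected component of the
#' suprathreshold set (0 if none).
#'
#' @param mask Logical 3D analysis mask.
#' @param fwhm Assumed smoothness of the statistic map, mm (the applied
#'   smoothing FWHM by default in the pipeline).
#' @param voxel_size Voxel edge, mm.
#' @param voxel_p Two-sided cluster-forming voxelwise p threshold.
#' @param n_iter Number of Monte-Carlo iterations (>= 100).
#' @param connectivity_rule `"faces"`, `"edges"`, `"corners"` (or 6/18/26).
#' @param seed Integer seed.
#' @return A `null_cluster_dist`: list with `max_cluster_sizes`, `n_iter`,
#'   `voxel_p`, `fwhm`, `voxel_size`, `connectivity`, `mask_size`, `seed`.
#' @export
simulate_null_distribution <- function(mask, fwhm, voxel_size,
                                       voxel_p = 0.05, n_iter = 1000L,
                                       connectivity_rule = "faces",
                                       seed = 1L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) abort("mask is empty")
  if (voxel_p <= 0 || voxel_p >= 1) abort("voxel_p must lie in (0, 1)")
  if (n_iter < 100) abort("use at least 100 iterations")
  conn <- .connectivity_code(connectivity_rule)
  thr <- qnorm(1 - voxel_p / 2)
  set.seed(seed)
  maxes <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    z <- gaussian_null_field(mask, fwhm, voxel_size)
    supra <- mask & abs(z) > thr
    maxes[i] <- if (any(supra)) {
      max(tabulate(label_components(supra, conn)))
    } else 0L
  }
  structure(list(max_cluster_sizes = maxes, n_iter = as.integer(n_iter),
                 voxel_p = voxel_p, fwhm = fwhm, voxel_size = voxel_size,
                 connectivity = conn, mask_size = sum(mask),
                 seed = as.integer(seed)),
            class = "null_cluster_dist")
}

#' @export
print.null_cluster_dist <- function(x, ...) {
  cat(sprintf(
    "<null_cluster_dist> %d iterations, voxel p %.3g, FWHM %g mm, %d mask voxels\n",
    x$n_iter, x$voxel_p, x$fwhm, x$mask_size))
  cat(sprintf("  max cluster sizes: median %d, 95%% %d; k_min(0.05) = %d\n",
              stats::median(x$max_cluster_sizes),
              as.integer(stats::quantile(x$max_cluster_sizes, 0.95)),
              min_cluster_size(x, 0.05)))
  invisible(x)
}

#' Minimum corrected cluster extent
#'
#' The smallest cluster size `k` such that the fraction of null iterations
#' whose largest cluster reaches `k` is at most `alpha` — the minimum
#' cluster extent controlling familywise error at `alpha`.
#'
#' @param dist A [simulate_null_distribution()] result.
#' @param alpha Familywise error level in `(0, 1)`.
#' @return Integer voxel count.
#' @export
min_cluster_size <- function(dist, alpha = 0.05) {
  stopifnot(inherits(dist, "null_cluster_dist"))
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (alpha < 1 / dist$n_iter)
    warn("alpha is below the Monte-Carlo resolution (1/n_iter)")
  sizes <- dist$max_cluster_sizes
  for (k in seq_len(max(sizes) + 1L)) {
    if (mean(sizes >= k) <= alpha) return(as.integer(k))
  }
  as.integer(max(sizes) + 1L)
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Thresholds the voxelwise p-map at `voxel_p`, finds connected components
#' (by default separately for positive and negative `r`, since reported
#' effects are signed), and keeps components of at least `k_min` voxels.
#'
#' @param stat A `cohort_stat_map`.
#' @param voxel_p Cluster-forming voxelwise p threshold.
#' @param k_min Minimum cluster extent (from [min_cluster_size()]).
#' @param connectivity_rule `"faces"`, `"edges"`, `"corners"` (or 6/18/26).
#' @param split_sign Treat positive and negative correlations as separate
#'   clusters (default TRUE).
#' @return Tibble with one row per surviving cluster: `cluster_id`, `sign`,
#'   `n_voxels`, and `voxels` (list column of linear voxel indices).
#' @export
extract_clusters <- function(stat, voxel_p = 0.05, k_min = 1L,
                             connectivity_rule = "faces",
                             split_sign = TRUE) {
  stopifnot(inherits(stat, "cohort_stat_map"))
  conn <- .connectivity_code(connectivity_rule)
  supra <- stat$mask & !is.na(stat$p) & stat$p < voxel_p
  signs <- if (split_sign) c(1, -1) else 0
  rows <- list()
  for (s in signs) {
    sel <- if (s == 1) supra & stat$r > 0
           else if (s == -1) supra & stat$r < 0
           else supra
    sel[is.na(sel)] <- FALSE
    if (!any(sel)) next
    lab <- label_components(sel, conn)
    sizes <- tabulate(lab)
    for (k in which(sizes >= k_min)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sign = if (s == 0) sign(stat$r[which(lab == k)[1]]) else s,
        n_voxels = sizes[k],
        voxels = list(which(lab == k)))
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(cluster_id = integer(), sign = numeric(),
                          n_voxels = integer(), voxels = list()))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$n_voxels))
  dplyr::mutate(out, cluster_id = dplyr::row_number(),
                .before = 1)
}

#' Report clusters in an anatomically labelled table
#'
#' One row per cluster: the peak voxel (maximum `|r|`, ties broken by the
#' smallest linear index), the parcellation label and hemisphere at the
#' peak, the peak world coordinates in the requested orientation, and the
#' peak `r` and `p`. A `composition` list column gives per-parcel voxel
#' counts within each cluster. The hemisphere is read from the sign of the
#' left-right world coordinate at the peak (in LPS, positive x is left).
#'
#' @param clusters An [extract_clusters()] tibble.
#' @param stat The `cohort_stat_map` the clusters came from.
#' @param parcellation Integer 3D label array on the same grid.
#' @param labels Label table (`label`, `name`, optionally `side`).
#' @param affine 4x4 RAS voxel-to-world affine; defaults to the one carried
#'   by `stat`.
#' @param orientation `"LPS"` (left-posterior-superior, the reporting
#'   default) or `"RAS"`.
#' @return A `cluster_report` tibble: `region`, `side`, `n_voxels`,
#'   `peak_x`, `peak_y`, `peak_z` (mm), `peak_r`, `peak_p`, `sign`,
#'   `composition`.
#' @export
report_clusters <- function(clusters, stat, parcellation, labels,
                            affine = NULL, orientation = c("LPS", "RAS")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(stat, "cohort_stat_map"))
  if (!identical(dim(parcellation), dim(stat$r)))
    abort("parcellation is not on the statistic map's grid")
  if (is.null(affine)) affine <- stat$affine
  d <- dim(stat$r)
  name_of <- setNames(labels$name, labels$label)

  rows <- purrr::pmap(clusters, function(cluster_id, sign, n_voxels,
                                         voxels, ...) {
    rv <- abs(stat$r[voxels])
    peak <- voxels[which(rv == max(rv))]
    peak <- min(peak)  # deterministic tie-break: smallest linear index
    ijk <- arrayInd(peak, d)
    xyz <- .voxel_to_world(ijk, affine, orientation)
    lr <- if (orientation == "LPS") xyz[1, "x"] else -xyz[1, "x"]
    lab <- parcellation[peak]
    comp <- table(factor(parcellation[voxels]))
    comp <- tibble::tibble(
      label = as.integer(names(comp)),
      region = ifelse(names(comp) == "0", "unlabelled",
                      unname(name_of[names(comp)])),
      n_voxels = as.integer(comp))
    tibble::tibble(
      cluster_id = cluster_id,
      region = if (lab > 0) unname(name_of[as.character(lab)]) else "unlabelled",
      side = if (lr > 0) "L" else "R",
      n_voxels = n_voxels,
      peak_x = unname(xyz[1, "x"]), peak_y = unname(xyz[1, "y"]),
      peak_z = unname(xyz[1, "z"]),
      peak_r = stat$r[peak], peak_p = stat$p[peak],
      sign = sign, composition = list(comp))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(cluster_id = integer(), region = character(),
                          side = character(), n_voxels = integer(),
                          peak_x = numeric(), peak_y = numeric(),
                          peak_z = numeric(), peak_r = numeric(),
                          peak_p = numeric(), sign = numeric(),
                          composition = list())
  }
  attr(out, "orientation") <- orientation
  attr(out, "metric") <- stat$metric_name
  class(out) <- c("cluster_report", class(out))
  out
}

#' Format a cluster report the way results tables print it
#'
#' Rounds coordinates to mm, `peak_r` to 2 decimals and `peak_p` to one
#' significant figure, dropping the list column.
#'
#' @param report A [report_clusters()] tibble.
#' @return A plain tibble ready for printing or TSV export.
#' @export
format_cluster_report <- function(report) {
  dplyr::mutate(
    dplyr::select(tibble::as_tibble(report), -dplyr::any_of("composition")),
    dplyr::across(dplyr::starts_with("peak_"),
                  ~ if (dplyr::cur_column() == "peak_p") signif(.x, 1)
                    else round(.x, 2)))
}
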