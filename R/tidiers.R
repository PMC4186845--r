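# Broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @exportS3Method generics::tidy
tidy.cohort_stat_map <- function(x, ...) {
  sel <- which(as.vector(x$mask))
  ijk <- arrayInd(sel, dim(x$r))
  tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                 r = x$r[sel], p = x$p[sel])
}

#' @exportS3Method generics::glance
glance.cohort_stat_map <- function(x, ...) {
  rv <- x$r[x$mask]
  tibble::tibble(metric = x$metric_name, n_subjects = x$n_subjects,
                 n_voxels = sum(x$mask),
                 max_abs_r = max(abs(rv), na.rm = TRUE),
                 prop_p_lt_05 = mean(x$p[x$mask] < 0.05, na.rm = TRUE))
}

#' @exportS3Method generics::tidy
tidy.null_cluster_dist <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$n_iter),
                 max_cluster_size = x$max_cluster_sizes)
}

#' @exportS3Method generics::glance
glance.null_cluster_dist <- function(x, ...) {
  tibble::tibble(n_iter = x$n_iter, voxel_p = x$voxel_p, fwhm = x$fwhm,
                 mask_size = x$mask_size,
                 k_min_05 = min_cluster_size(x, 0.05))
}

#' @exportS3Method generics::tidy
tidy.fd_trace <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$fd), fd = x$fd)
}

#' @exportS3Method generics::glance
glance.fd_trace <- function(x, ...) {
  tibble::tibble(n_frames = length(x$fd), mean_fd = x$mean_fd,
                 max_fd = max(x$fd), head_radius = x$head_radius,
                 rotation_unit = x$rotation_unit)
}

#' @exportS3Method generics::tidy
tidy.variability_map <- function(x, ...) {
  sel <- which(as.vector(x$mask))
  ijk <- arrayInd(sel, dim(x$sd))
  tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3], sd = x$sd[sel])
}

#' Plot axial slices of an across-subject correlation map
#'
#' @param object A `cohort_stat_map`.
#' @param slices Z indices to display; defaults to four evenly spaced
#'   in-mask slices.
#' @param ... Unused.
#' @return A ggplot object (facetted axial montage of `r`).
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_stat_map <- function(object, slices = NULL, ...) {
  d <- dim(object$r)
  if (is.null(slices)) {
    zz <- which(apply(object$mask, 3, any))
    slices <- unique(round(stats::quantile(zz, c(0.2, 0.4, 0.6, 0.8))))
  }
  df <- tidy(object)
  df <- dplyr::filter(df, .data$k %in% slices)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Across-subject correlation: ",
                                 object$metric_name),
                  x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Histogram of the Monte-Carlo null of maximum cluster size
#'
#' @param object A `null_cluster_dist`.
#' @param alpha Familywise level whose minimum cluster extent is marked.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.null_cluster_dist <- function(object, alpha = 0.05, ...) {
  k <- min_cluster_size(object, alpha)
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$max_cluster_size)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = k, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "largest null cluster (voxels)", y = "iterations",
                  title = sprintf("Cluster-extent null (k_min = %d at alpha = %.2f)",
                                  k, alpha)) +
    ggplot2::theme_minimal()
}

#' Framewise-displacement trace plot
#'
#' @param object An `fd_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fd_trace <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$frame,
                                             y = .data$fd)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_fd, linetype = "dashed") +
    ggplot2::labs(x = "frame", y = "FD (mm)",
                  title = sprintf("Framewise displacement (mean %.3f mm)",
                                  object$mean_fd)) +
    ggplot2::theme_minimal()
}

#' Cluster-average variability versus behavioural score
#'
#' For each reported cluster, the SD of the cluster-averaged percent-change
#' time course per subject, against the subjects' scores — the qualitative
#' per-cluster view of the variability-performance relation.
#'
#' @param report A [report_clusters()] result with its source clusters.
#' @param clusters The [extract_clusters()] tibble the report came from.
#' @param pcs List of per-subject [pc_series()].
#' @param scores Per-subject scores.
#' @return Tibble: `cluster_id`, `region`, `subject`, `score`,
#'   `cluster_sd`.
#' @export
cluster_score_table <- function(report, clusters, pcs, scores) {
  purrr::pmap_dfr(
    dplyr::select(tibble::as_tibble(report), "cluster_id", "region"),
    function(cluster_id, region) {
      vox <- clusters$voxels[[match(cluster_id, clusters$cluster_id)]]
      tibble::tibble(
        cluster_id = cluster_id, region = region,
        subject = seq_along(pcs), score = scores,
        cluster_sd = vapply(pcs, cluster_average_sd, 0,
                            cluster_mask = vox))
    })
}

#' Scatter plot of cluster-average variability against score
#'
#' @param tbl A [cluster_score_table()] tibble.
#' @return A ggplot object, one facet per cluster.
#' @export
plot_cluster_scores <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$score,
                                    y = .data$cluster_sd)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::facet_wrap(~ cluster_id + region, scales = "free_y") +
    ggplot2::labs(x = "performance score (%)",
                  y = "cluster-average BOLD variability (% change SD)") +
    ggplot2::theme_minimal()
}
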