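# Per-subject preprocessing: initial-volume discard, mask erosion, tissue
# nuisance regions, the 19-column nuisance design, OLS regression with mean
# restoration, percent-signal-change conversion, run concatenation, optional
# low-pass filtering, and framewise displacement.

#' Discard initial frames of a 4D series
#'
#' Drops the first `n_discard` volumes (magnetisation steady-state settling).
#' Motion traces must be trimmed identically by the caller.
#'
#' @param series 4D (X, Y, Z, T) array.
#' @param n_discard Number of leading frames to drop; must leave >= 1 frame.
#' @return 4D array with `T - n_discard` frames; `tr`/`voxel_size`
#'   attributes are carried over.
#' @export
discard_initial <- function(series, n_discard = 5L) {
  d <- dim(series)
  stopifnot(length(d) == 4L)
  if (n_discard < 0 || n_discard >= d[4])
    abort("`n_discard` must satisfy 0 <= n_discard < T")
  if (n_discard == 0) return(series)
  out <- series[, , , (n_discard + 1):d[4], drop = FALSE]
  attr(out, "tr") <- attr(series, "tr")
  attr(out, "voxel_size") <- attr(series, "voxel_size")
  out
}

#' Threshold and erode a partial-volume map into a tissue nuisance region
#'
#' Voxels at or above the partial-volume threshold, then 3D box erosion
#' applied `erode` times to minimise partial voluming with neighbouring
#' tissue.
#'
#' @param pv_map 3D array of tissue fractions in `[0, 1]`.
#' @param threshold Partial-volume threshold in `(0, 1]`.
#' @param erode Number of 3D erosion passes.
#' @return Logical 3D mask with attribute `empty` flagging an empty result
#'   (the caller decides how to proceed).
#' @export
tissue_region <- function(pv_map, threshold = 0.99, erode = 2L) {
  stopifnot(threshold > 0, threshold <= 1, erode >= 0)
  out <- erode_mask_3d(pv_map >= threshold, erode)
  if (!any(out)) {
    warn("tissue region is empty after thresholding and erosion")
    attr(out, "empty") <- TRUE
  } else {
    attr(out, "empty") <- FALSE
  }
  out
}

# Backward difference with leading zero; keeps series length.
.backward_diff <- function(x) c(0, diff(x))

#' Build the 19-column nuisance design
#'
#' Columns: mean, linear and quadratic trends (3); six rigid-body motion
#' parameters and their first derivatives (12); mean WM and CSF signals and
#' their first derivatives (4). Derivatives are backward differences with
#' first element 0; trends are centred polynomials over `0:(T-1)`.
#'
#' @param motion T x 6 motion-parameter matrix (post-discard frames).
#' @param wm_ts,csf_ts Length-T mean tissue time courses.
#' @return A `nuisance_design`: list with `matrix` (T x 19),
#'   `column_labels`, `trend_convention`, and `condition_number` (a large
#'   value flags near-collinearity).
#' @export
build_nuisance_design <- function(motion, wm_ts, csf_ts) {
  motion <- as.matrix(motion)
  n_t <- nrow(motion)
  if (ncol(motion) != 6) abort("`motion` must have 6 columns")
  if (length(wm_ts) != n_t || length(csf_ts) != n_t)
    abort("tissue time courses must match the motion trace length")
  if (n_t < 20) abort("fewer than 20 frames: design would be rank-deficient")
  t0 <- seq_len(n_t) - 1
  lin <- t0 - mean(t0)
  quad <- lin^2 - mean(lin^2)
  dmotion <- apply(motion, 2, .backward_diff)
  X <- cbind(1, lin, quad, motion, dmotion,
             wm_ts, csf_ts, .backward_diff(wm_ts), .backward_diff(csf_ts))
  labels <- c("mean", "linear", "quadratic",
              paste0("motion_", 1:6), paste0("dmotion_", 1:6),
              "wm", "csf", "dwm", "dcsf")
  colnames(X) <- labels
  Xv <- X[, -1, drop = FALSE]
  Xv <- Xv[, apply(Xv, 2, sd) > 0, drop = FALSE]
  kappa_x <- if (ncol(Xv) >= 2) {
    kappa(scale(Xv, center = TRUE, scale = TRUE), exact = FALSE)
  } else 1
  if (!is.finite(kappa_x) || kappa_x > 1e8)
    warn(sprintf("nuisance design is near-collinear (condition number %.3g)",
                 kappa_x))
  structure(list(matrix = X, column_labels = labels,
                 trend_convention = "centred polynomials over 0:(T-1)",
                 condition_number = kappa_x),
            class = "nuisance_design")
}

# Shared QR machinery: residuals of Y (T x V) against the design, with the
# per-column temporal mean restored afterwards.
.regress_restore_matrix <- function(Y, design) {
  X <- design$matrix
  if (nrow(Y) != nrow(X)) abort("time dimension does not match the design")
  qrd <- qr(X)
  if (qrd$rank < ncol(X))
    warn("design not of full column rank; least-squares fit uses the pivoted QR")
  res <- qr.resid(qrd, Y)
  sweep(res, 2, colMeans(Y), "+")
}

#' Regress nuisance terms from a time series and restore its mean
#'
#' Ordinary least-squares residual against the nuisance design, plus the
#' original temporal mean (so subsequent percent-change conversion divides
#' by the true baseline).
#'
#' @param ts Length-T numeric series.
#' @param design A [build_nuisance_design()] result (or any list with a
#'   `matrix` element).
#' @return Length-T cleaned series with the original mean.
#' @export
regress_and_restore_mean <- function(ts, design) {
  drop(.regress_restore_matrix(matrix(ts, ncol = 1), design))
}

#' Convert a time series to percent signal change
#'
#' `100 * (ts - mean(ts)) / mean(ts)`; by construction the result has zero
#' temporal mean.
#'
#' @param ts Length-T numeric series with `|mean(ts)|` above `eps`.
#' @param eps Guard against division by a near-zero baseline.
#' @return Length-T series in percent units.
#' @examples
#' percent_change(c(100, 110, 90))
#' @export
percent_change <- function(ts, eps = 1e-6) {
  m <- mean(ts)
  if (abs(m) <= eps) abort("series mean is near zero; voxel should be excluded")
  100 * (ts - m) / m
}

# Percent change for a (T x V) matrix; voxels with near-zero baseline are
# dropped from the mask rather than producing infinities.
.percent_change_matrix <- function(Y, mask_v, eps = 1e-6) {
  mu <- colMeans(Y)
  bad <- abs(mu) <= eps & mask_v
  keep <- mask_v & !bad
  out <- matrix(0, nrow(Y), length(mask_v))
  sel <- which(keep)
  out[, sel] <- 100 * sweep(Y[, sel, drop = FALSE], 2, mu[sel], "-") /
    rep(mu[sel], each = nrow(Y))
  list(pc = out, mask_v = keep, n_dropped = sum(bad))
}

#' Construct a percent-change series object
#'
#' @param data 4D (X, Y, Z, T) array in percent units (zero temporal mean
#'   inside the mask).
#' @param mask Logical 3D analysis mask.
#' @param tr Repetition time, seconds.
#' @return A `pc_series` list.
#' @export
pc_series <- function(data, mask, tr) {
  stopifnot(length(dim(data)) == 4L, identical(dim(data)[1:3], dim(mask)))
  structure(list(data = data, mask = mask, tr = tr), class = "pc_series")
}

#' @export
print.pc_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pc_series> %dx%dx%d, %d frames, TR %g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Concatenate percent-change runs in time
#'
#' Percent change is computed per run before concatenation, so each run is
#' normalised to its own baseline.
#'
#' @param runs List of [pc_series()] objects on identical grids and masks.
#' @return A single `pc_series` whose time dimension is the sum.
#' @export
concatenate_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  if (length(runs) == 1) return(runs[[1]])
  d0 <- dim(runs[[1]]$data)[1:3]
  for (r in runs[-1]) {
    if (!identical(dim(r$data)[1:3], d0) ||
        !identical(r$mask, runs[[1]]$mask))
      abort("runs must share one grid and mask")
  }
  data <- array(
    do.call(cbind, lapply(runs, function(r) matrix(r$data, prod(d0)))),
    c(d0, sum(vapply(runs, function(r) dim(r$data)[4], 1L))))
  pc_series(data, runs[[1]]$mask, runs[[1]]$tr)
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations plus the three rotations converted
#' to arc length on a sphere of `head_radius` mm. `fd[1] = 0`; the mean is
#' taken over frames 2..T.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations.
#' @param head_radius Sphere radius in mm (default 50).
#' @param rotation_unit `"degrees"` or `"radians"`; taken from the matrix
#'   `rotation_unit` attribute when present.
#' @return An `fd_trace`: list with `fd` (length T, mm), `mean_fd`,
#'   `head_radius`, `rotation_unit`.
#' @examples
#' m <- matrix(0, 10, 6); m[6:10, 1] <- 0.1
#' framewise_displacement(m)$fd[6]
#' @export
framewise_displacement <- function(motion, head_radius = 50,
                                   rotation_unit = NULL) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) abort("need at least two frames")
  if (ncol(motion) != 6) abort("`motion` must have 6 columns")
  if (is.null(rotation_unit))
    rotation_unit <- attr(motion, "rotation_unit") %||% "degrees"
  if (!rotation_unit %in% c("degrees", "radians"))
    abort("`rotation_unit` must be \"degrees\" or \"radians\"")
  rot <- motion[, 4:6, drop = FALSE]
  if (rotation_unit == "degrees") rot <- rot * pi / 180
  dtrans <- abs(apply(motion[, 1:3, drop = FALSE], 2, diff))
  drot <- abs(apply(rot, 2, diff))
  fd <- c(0, rowSums(cbind(dtrans, head_radius * drot)))
  structure(list(fd = fd, mean_fd = mean(fd[-1]), head_radius = head_radius,
                 rotation_unit = rotation_unit),
            class = "fd_trace")
}

#' @export
print.fd_trace <- function(x, ...) {
  cat(sprintf("<fd_trace> %d frames, mean FD %.4f mm (radius %g mm, %s)\n",
              length(x$fd), x$mean_fd, x$head_radius, x$rotation_unit))
  invisible(x)
}

#' Zero-phase low-pass filter for BOLD time series
#'
#' Fourth-order Butterworth applied forward and backward
#' ([signal::filtfilt()]). Off by default in the pipeline; high-frequency
#' BOLD components carry signal of interest.
#'
#' @param ts Length-T series.
#' @param tr Repetition time, seconds.
#' @param cutoff_hz Cutoff frequency, Hz.
#' @return Filtered series of the same length.
#' @export
lowpass_filter <- function(ts, tr, cutoff_hz = 0.08) {
  ny <- 1 / (2 * tr)
  if (cutoff_hz <= 0 || cutoff_hz >= ny)
    abort("cutoff must lie strictly between 0 and the Nyquist frequency")
  bf <- signal::butter(4, cutoff_hz / ny, type = "low")
  m <- mean(ts)
  m + signal::filtfilt(bf, ts - m)
}

#' Preprocess one subject into a concatenated percent-change series
#'
#' Runs the full per-subject chain, in order: spatial smoothing, initial
#' volume discard (motion trimmed identically), per-slice brain-mask
#' erosion, WM/CSF nuisance-region construction from partial-volume maps,
#' 19-regressor nuisance regression with mean restoration, optional
#' low-pass filtering, percent-change conversion per run, and run
#' concatenation. Framewise displacement is computed from the trimmed
#' motion traces.
#'
#' If a tissue region is empty at the requested erosion (possible on small
#' grids), the erosion count is reduced until the region is nonempty; the
#' value used is recorded in the returned log.
#'
#' @param subject A `subject_record` (see [generate_cohort()]).
#' @param n_discard Leading frames dropped per run.
#' @param fwhm Spatial smoothing FWHM, mm.
#' @param mask_erosion Per-slice brain-mask erosion passes.
#' @param pv_threshold Partial-volume threshold for WM/CSF regions.
#' @param tissue_erosion 3D erosion passes for WM/CSF regions.
#' @param head_radius Sphere radius for framewise displacement, mm.
#' @param lowpass Apply the 0.08 Hz low-pass filter (default off).
#' @param lowpass_hz Low-pass cutoff, Hz.
#' @return List: `pc` (a [pc_series()]), `fd` (list of `fd_trace` per run),
#'   `mean_fd`, `mask` (analysis mask actually used), `log` (parameters and
#'   any fallbacks).
#' @export
preprocess_subject <- function(subject, n_discard = 5L, fwhm = 3,
                               mask_erosion = 2L, pv_threshold = 0.99,
                               tissue_erosion = 2L, head_radius = 50,
                               lowpass = FALSE, lowpass_hz = 0.08) {
  stopifnot(inherits(subject, "subject_record"))
  voxel_size <- attr(subject$runs[[1]], "voxel_size") %||% 1
  tr <- attr(subject$runs[[1]], "tr") %||% 1
  mask <- erode_mask_2d(subject$brain_mask, mask_erosion)
  if (!any(mask)) abort("brain mask is empty after erosion")

  regions <- list()
  used_erosion <- c(wm = NA_integer_, csf = NA_integer_)
  for (tt in c("wm", "csf")) {
    er <- tissue_erosion
    repeat {
      reg <- suppressWarnings(
        tissue_region(subject$pv_maps[[tt]], pv_threshold, er))
      if (any(reg) || er == 0) break
      er <- er - 1L
    }
    if (!any(reg)) abort(paste0(toupper(tt), " nuisance region is empty"))
    regions[[tt]] <- reg
    used_erosion[tt] <- er
  }

  pcs <- vector("list", length(subject$runs))
  fds <- vector("list", length(subject$runs))
  dropped <- 0L
  for (rr in seq_along(subject$runs)) {
    sm <- smooth_gaussian(subject$runs[[rr]], fwhm, voxel_size)
    sm <- discard_initial(sm, n_discard)
    mot <- subject$motion[[rr]]
    mot_trim <- mot[(n_discard + 1):nrow(mot), , drop = FALSE]
    attr(mot_trim, "rotation_unit") <- attr(mot, "rotation_unit")
    fds[[rr]] <- framewise_displacement(mot_trim, head_radius = head_radius)

    d <- dim(sm)
    Y <- matrix(sm, prod(d[1:3]), d[4])
    wm_ts <- colMeans(Y[as.vector(regions$wm), , drop = FALSE])
    csf_ts <- colMeans(Y[as.vector(regions$csf), , drop = FALSE])
    design <- build_nuisance_design(mot_trim, wm_ts, csf_ts)

    maskv <- as.vector(mask)
    cleaned <- matrix(0, d[4], length(maskv))
    cleaned[, maskv] <- .regress_restore_matrix(t(Y[maskv, , drop = FALSE]),
                                                design)
    if (lowpass) {
      sel <- which(maskv)
      cleaned[, sel] <- apply(cleaned[, sel, drop = FALSE], 2,
                              lowpass_filter, tr = tr, cutoff_hz = lowpass_hz)
    }
    pcr <- .percent_change_matrix(cleaned, maskv)
    dropped <- dropped + pcr$n_dropped
    mask <- array(pcr$mask_v, d[1:3])
    pcs[[rr]] <- pc_series(array(t(pcr$pc), c(d[1:3], d[4])), mask, tr)
  }
  # a voxel dropped in any run is dropped everywhere
  final_mask <- Reduce(`&`, lapply(pcs, `[[`, "mask"))
  pcs <- lapply(pcs, function(p) pc_series(p$data, final_mask, p$tr))
  pc <- concatenate_runs(pcs)

  list(
    pc = pc, fd = fds,
    mean_fd = mean(unlist(lapply(fds, function(f) f$fd[-1]))),
    mask = final_mask,
    log = list(n_discard = n_discard, fwhm = fwhm,
               mask_erosion = mask_erosion, pv_threshold = pv_threshold,
               tissue_erosion_requested = tissue_erosion,
               tissue_erosion_used = as.list(used_erosion),
               head_radius = head_radius, lowpass = lowpass,
               lowpass_hz = if (lowpass) lowpass_hz else NA_real_,
               n_voxels_dropped_zero_mean = dropped,
               sd_convention = "population (divide by T)")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
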