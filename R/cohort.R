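# Synthetic multi-subject resting-state cohort generator. Produces 4D BOLD
# runs with AR(1) temporal noise and Gaussian spatial smoothness, rigid-body
# motion traces with a prescribed mean framewise displacement, tissue
# partial-volume maps, an integer parcellation, and per-subject behavioural
# scores, with region-specific variability-score and connectivity-score
# effects injected at configurable strength.

#' Configuration for a synthetic resting-state cohort
#'
#' Defaults emulate a small single-site study: ten subjects, two 8-minute
#' runs of 240 frames at TR = 2 s on a 2 mm grid, behavioural scores drawn
#' uniformly over 76-96 percent, mean framewise displacement in 0.06-0.11 mm,
#' one parcel carrying a variability-score effect with across-subject target
#' correlation 0.9, and a left-caudate to right-fusiform connectivity
#' coupling whose amplitude grows linearly with the score.
#'
#' @param n_subjects Number of subjects.
#' @param grid_shape Integer length-3 volume dimensions (X, Y, Z).
#' @param voxel_size Isotropic voxel edge, mm.
#' @param n_runs Runs per subject.
#' @param n_timepoints_per_run Frames per run.
#' @param tr Repetition time, seconds.
#' @param ar1_coeff Lag-1 autoregressive coefficient of the temporal noise,
#'   in `[0, 1)`.
#' @param spatial_fwhm Gaussian smoothness imposed on the noise fields, mm.
#' @param effect_rois List of `list(label =, target_r =)` entries: parcels in
#'   which the per-subject signal SD is an affine function of the score,
#'   jittered so the across-subject SD-vs-score Pearson correlation targets
#'   `target_r`.
#' @param connectivity_effect `list(seed_label =, target_label =, slope =)` or
#'   `NULL`: a shared latent time course added to the seed parcel at fixed
#'   amplitude and to the target parcel with amplitude
#'   `slope * (score - min(score_range))` percent.
#' @param score_range Behavioural score range (percent), sampled uniformly.
#' @param mean_fd_range Range of per-subject mean framewise displacement, mm.
#' @param seed Integer root seed; all randomness derives from it.
#' @param baseline_sd Baseline percent-change SD of the noise, percent.
#' @param effect_depth Fractional modulation depth of the SD effect (0.3
#'   means the effect spans roughly +/-30 percent of baseline SD over the
#'   cohort).
#' @param seed_amplitude Amplitude of the latent connectivity time course in
#'   the seed parcel, percent.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 10L,
                          grid_shape = c(48L, 56L, 40L),
                          voxel_size = 2,
                          n_runs = 2L,
                          n_timepoints_per_run = 240L,
                          tr = 2,
                          ar1_coeff = 0.4,
                          spatial_fwhm = 3,
                          effect_rois = list(list(label = 1L, target_r = 0.9)),
                          connectivity_effect = list(seed_label = 1L,
                                                     target_label = 8L,
                                                     slope = 0.04),
                          score_range = c(76, 96),
                          mean_fd_range = c(0.06, 0.11),
                          seed = 1L,
                          baseline_sd = 1,
                          effect_depth = 0.3,
                          seed_amplitude = 0.8) {
  stopifnot(n_subjects >= 3, length(grid_shape) == 3, all(grid_shape >= 8),
            voxel_size > 0, n_runs >= 1, tr > 0)
  if (abs(ar1_coeff) >= 1) abort("`ar1_coeff` must lie in (-1, 1)")
  if (n_timepoints_per_run <= 5 + 19)
    abort("`n_timepoints_per_run` must exceed the discarded frames plus the 19 nuisance regressors")
  if (score_range[1] < 0 || score_range[2] > 100 || diff(score_range) <= 0)
    abort("`score_range` must be increasing and within [0, 100]")
  for (e in effect_rois) {
    if (abs(e$target_r) >= 1) abort("effect ROI target r must lie in (-1, 1)")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = as.integer(grid_shape),
    voxel_size = voxel_size, n_runs = as.integer(n_runs),
    n_timepoints_per_run = as.integer(n_timepoints_per_run), tr = tr,
    ar1_coeff = ar1_coeff, spatial_fwhm = spatial_fwhm,
    effect_rois = effect_rois, connectivity_effect = connectivity_effect,
    score_range = score_range, mean_fd_range = mean_fd_range,
    seed = as.integer(seed), baseline_sd = baseline_sd,
    effect_depth = effect_depth, seed_amplitude = seed_amplitude
  ), class = "cohort_config")
}

# Shared anatomy: ellipsoidal brain mask, concentric tissue compartments
# (CSF core, WM shell, GM rim) and four bilateral box parcels placed in the
# GM rim so that parcel signal is not absorbed into the WM/CSF nuisance
# regressors.
.build_anatomy <- function(grid_shape) {
  d <- grid_shape
  centre <- (d + 1) / 2
  semi <- 0.45 * d
  ix <- (seq_len(d[1]) - centre[1]) / semi[1]
  iy <- (seq_len(d[2]) - centre[2]) / semi[2]
  iz <- (seq_len(d[3]) - centre[3]) / semi[3]
  r2 <- outer(outer(ix^2, iy^2, "+"), iz^2, "+")
  r <- sqrt(r2)
  mask <- r <= 1
  zero <- array(0, d)
  pv_csf <- zero; pv_csf[mask & r < 0.2] <- 1
  pv_wm <- zero;  pv_wm[mask & r >= 0.2 & r < 0.55] <- 1
  pv_gm <- zero;  pv_gm[mask & r >= 0.55] <- 1

  # parcel centres as unit-sphere offsets (x sign encodes hemisphere; the
  # default affine is RAS, so negative world x = left)
  base <- list(
    caudate     = c(0.69, 0.00,  0.00),
    putamen     = c(0.55, 0.45,  0.00),
    hippocampus = c(0.50, -0.35, -0.35),
    fusiform    = c(0.45, -0.30,  0.40)
  )
  half <- max(1L, round(0.09 * min(d)))
  parc <- array(0L, d)
  rows <- list()
  lab <- 0L
  for (nm in names(base)) {
    for (side in c("L", "R")) {
      lab <- lab + 1L
      u <- base[[nm]]
      u[1] <- if (side == "L") -u[1] else u[1]
      ctr <- round(centre + semi * u)
      rng <- lapply(1:3, function(a) {
        pmax(1L, ctr[a] - half):pmin(d[a], ctr[a] + half)
      })
      box <- array(FALSE, d)
      box[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
      sel <- box & mask & parc == 0L
      parc[sel] <- lab
      rows[[lab]] <- tibble::tibble(label = lab, name = nm, side = side,
                                    n_voxels = sum(sel))
    }
  }
  labels <- dplyr::bind_rows(rows)
  list(mask = mask, pv_maps = list(wm = pv_wm, csf = pv_csf, gm = pv_gm),
       parcellation = parc, labels = labels)
}

# Unit-variance AR(1)-in-time, spatially smoothed noise as a (voxels x T)
# matrix restricted to grid order; frames are standardised within the mask.
.noise_field <- function(d3, n_t, phi, sigma_vox, mask, seed) {
  set.seed(seed)
  w <- array(rnorm(prod(d3) * n_t), c(d3, n_t))
  if (sigma_vox > 0) {
    for (axis in 1:3) {
      w <- .apply_axis(w, .gaussian_kernel_matrix(d3[axis], sigma_vox), axis)
    }
  }
  w <- matrix(w, prod(d3), n_t)
  mv <- as.vector(mask)
  mu <- colMeans(w[mv, , drop = FALSE])
  sg <- sqrt(colMeans(w[mv, , drop = FALSE]^2) - mu^2)
  w <- sweep(sweep(w, 2, mu, "-"), 2, sg, "/")
  if (phi != 0) {
    s <- sqrt(1 - phi^2)
    for (t in 2:n_t) w[, t] <- phi * w[, t - 1] + s * w[, t]
  }
  w
}

.ar1_series <- function(n_t, phi) {
  e <- rnorm(n_t)
  if (phi == 0) return(e)
  s <- sqrt(1 - phi^2)
  for (t in 2:n_t) e[t] <- phi * e[t - 1] + s * e[t]
  e
}

#' Generate a synthetic resting-state cohort
#'
#' Deterministic given `config$seed`. Scores are drawn uniformly over the
#' configured range; voxel noise is AR(1) in time and Gaussian-smooth in
#' space; within each effect parcel the per-subject signal SD is an affine
#' function of the (standardised) score plus Gaussian jitter sized so the
#' across-subject SD-vs-score correlation targets the configured value; the
#' connectivity effect adds one latent time course to seed and target parcels
#' with target amplitude increasing linearly in the score.
#'
#' @param config A [cohort_config()].
#' @return A `bold_cohort`: list with `subjects` (list of `subject_record`),
#'   `parcellation`, `labels`, `affine`, `voxel_size`, `config`.
#' @examples
#' cfg <- cohort_config(n_subjects = 4, grid_shape = c(12, 12, 10),
#'                      n_runs = 1, n_timepoints_per_run = 40, seed = 7)
#' coh <- generate_cohort(cfg)
#' length(coh$subjects)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  d3 <- config$grid_shape
  anat <- .build_anatomy(d3)
  for (e in config$effect_rois) {
    if (!e$label %in% anat$labels$label)
      abort(paste0("effect ROI label ", e$label, " absent from parcellation"))
  }
  ce <- config$connectivity_effect
  if (!is.null(ce) &&
      !all(c(ce$seed_label, ce$target_label) %in% anat$labels$label))
    abort("connectivity effect labels absent from parcellation")

  n <- config$n_subjects
  set.seed(.derive_seed(config$seed, "scores"))
  scores <- runif(n, config$score_range[1], config$score_range[2])
  z <- as.vector(scale(scores))
  set.seed(.derive_seed(config$seed, "jitter"))
  eta <- matrix(rnorm(n * max(1L, length(config$effect_rois))), nrow = n)
  set.seed(.derive_seed(config$seed, "fd"))
  target_fd <- runif(n, config$mean_fd_range[1], config$mean_fd_range[2])

  sigma_vox <- fwhm_to_sigma(config$spatial_fwhm, config$voxel_size)
  n_t <- config$n_timepoints_per_run
  maskv <- as.vector(anat$mask)
  baseline <- 1000

  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    # per-subject SD map (percent units)
    sd_map <- rep(config$baseline_sd, prod(d3))
    for (k in seq_along(config$effect_rois)) {
      e <- config$effect_rois[[k]]
      mult <- 1 + config$effect_depth *
        (e$target_r * z[s] + sqrt(1 - e$target_r^2) * eta[s, k])
      mult <- max(mult, 0.2)
      sd_map[as.vector(anat$parcellation == e$label)] <-
        config$baseline_sd * mult
    }

    runs <- vector("list", config$n_runs)
    motion <- vector("list", config$n_runs)
    for (rr in seq_len(config$n_runs)) {
      idx <- (s - 1L) * config$n_runs + rr
      x <- .noise_field(d3, n_t, config$ar1_coeff, sigma_vox, anat$mask,
                        .derive_seed(config$seed, "noise", idx))
      fluct <- x * sd_map
      if (!is.null(ce)) {
        set.seed(.derive_seed(config$seed, "latent", idx))
        u <- .ar1_series(n_t, config$ar1_coeff)
        amp_target <- ce$slope * (scores[s] - config$score_range[1])
        seed_sel <- as.vector(anat$parcellation == ce$seed_label)
        tgt_sel <- as.vector(anat$parcellation == ce$target_label)
        fluct[seed_sel, ] <- fluct[seed_sel, ] +
          rep(config$seed_amplitude * u, each = sum(seed_sel))
        fluct[tgt_sel, ] <- fluct[tgt_sel, ] +
          rep(amp_target * u, each = sum(tgt_sel))
      }
      vol <- baseline * (1 + fluct / 100)
      vol[!maskv, ] <- 0
      run <- array(vol, c(d3, n_t))
      attr(run, "tr") <- config$tr
      attr(run, "voxel_size") <- config$voxel_size
      runs[[rr]] <- run
      motion[[rr]] <- generate_motion(
        n_t, target_fd[s], seed = .derive_seed(config$seed, "motion", idx))
    }

    subjects[[s]] <- structure(list(
      subject_id = sprintf("sub-%02d", s),
      runs = runs, motion = motion,
      brain_mask = anat$mask, pv_maps = anat$pv_maps,
      score = scores[s], target_mean_fd = target_fd[s]
    ), class = "subject_record")
  }

  structure(list(
    subjects = subjects, parcellation = anat$parcellation,
    labels = anat$labels,
    affine = .default_affine(d3, config$voxel_size),
    voxel_size = config$voxel_size, config = config
  ), class = "bold_cohort")
}

#' @export
print.bold_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<bold_cohort> %d subjects, grid %s at %g mm, %d run(s) x %d frames (TR %g s)\n",
    cfg$n_subjects, paste(cfg$grid_shape, collapse = "x"), cfg$voxel_size,
    cfg$n_runs, cfg$n_timepoints_per_run, cfg$tr))
  cat(sprintf("  scores %.1f-%.1f, %d parcels\n",
              min(purrr::map_dbl(x$subjects, "score")),
              max(purrr::map_dbl(x$subjects, "score")), nrow(x$labels)))
  invisible(x)
}

#' Generate a rigid-body motion trace with an exact mean framewise displacement
#'
#' A six-parameter Gaussian random walk (3 translations in mm, 3 rotations in
#' degrees) rescaled so that the Power-formula mean framewise displacement
#' equals `target_mean_fd` exactly (FD is positively homogeneous in the
#' trace, so rescaling is exact).
#'
#' @param n_timepoints Number of frames (>= 2).
#' @param target_mean_fd Desired mean framewise displacement, mm (>= 0).
#' @param seed Integer seed.
#' @param head_radius Sphere radius used to convert rotations to mm.
#' @param rotation_unit Unit of the generated rotation columns.
#' @return A `n_timepoints` x 6 matrix with attribute `rotation_unit`.
#' @export
generate_motion <- function(n_timepoints, target_mean_fd, seed,
                            head_radius = 50,
                            rotation_unit = c("degrees", "radians")) {
  rotation_unit <- match.arg(rotation_unit)
  if (n_timepoints < 2) abort("`n_timepoints` must be at least 2")
  if (target_mean_fd < 0) abort("`target_mean_fd` must be non-negative")
  m <- matrix(0, n_timepoints, 6)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  if (target_mean_fd > 0) {
    set.seed(seed)
    steps <- matrix(rnorm(n_timepoints * 6, sd = 0.02), n_timepoints, 6)
    steps[1, ] <- 0
    m[] <- apply(steps, 2, cumsum)
    fd <- framewise_displacement(m, head_radius = head_radius,
                                 rotation_unit = rotation_unit)
    m <- m * (target_mean_fd / fd$mean_fd)
  }
  attr(m, "rotation_unit") <- rotation_unit
  m
}

#' Score a same/moved recall task
#'
#' The behavioural performance score: the percentage of judgments matching
#' the ground truth across all trials.
#'
#' @param truth Logical (or two-level) vector of true states.
#' @param judgments Vector of responses, same length and coding.
#' @return Percent correct in `[0, 100]`.
#' @examples
#' score_recall(rep(TRUE, 4), c(TRUE, TRUE, FALSE, TRUE))
#' @export
score_recall <- function(truth, judgments) {
  if (length(truth) == 0) abort("`truth` must be nonempty")
  if (length(truth) != length(judgments)) abort("lengths differ")
  100 * mean(truth == judgments)
}
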