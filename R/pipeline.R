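# End-to-end orchestration: cohort serialization (NIfTI + text), manifest
# I/O, and the two analysis drivers (variability and seed connectivity),
# each writing statistic maps, cluster tables, a motion-confound check and
# a provenance log.

.write_nifti_vol <- function(arr, affine, voxel_size, path) {
  im <- RNifti::asNifti(arr)
  RNifti::sform(im) <- structure(affine, code = 2L)
  RNifti::writeNifti(im, path)
  path
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Per subject: 4D runs as NIfTI-1, motion as whitespace-delimited 6-column
#' text, brain mask and WM/CSF/GM partial-volume maps as NIfTI. Shared:
#' parcellation NIfTI, label table TSV, scores TSV, a manifest TSV linking
#' everything, and the generating configuration as YAML.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bold_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aff <- cohort$affine; vs <- cohort$voxel_size
  .write_nifti_vol(cohort$parcellation, aff, vs,
                   file.path(dir, "parcellation.nii.gz"))
  write.table(cohort$labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rows <- purrr::map(cohort$subjects, function(s) {
    id <- s$subject_id
    run_paths <- character(length(s$runs))
    motion_paths <- character(length(s$runs))
    for (rr in seq_along(s$runs)) {
      run_paths[rr] <- file.path(dir, sprintf("%s_run-%d_bold.nii.gz", id, rr))
      .write_nifti_vol(s$runs[[rr]], aff, vs, run_paths[rr])
      motion_paths[rr] <- file.path(dir, sprintf("%s_run-%d_motion.txt", id, rr))
      write.table(format(s$motion[[rr]], digits = 10), motion_paths[rr],
                  sep = " ", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    mask_path <- file.path(dir, paste0(id, "_mask.nii.gz"))
    .write_nifti_vol(s$brain_mask * 1L, aff, vs, mask_path)
    pv_paths <- purrr::imap_chr(s$pv_maps, function(pv, tt) {
      p <- file.path(dir, sprintf("%s_pv-%s.nii.gz", id, tt))
      .write_nifti_vol(pv, aff, vs, p)
      p
    })
    tibble::tibble(
      subject_id = id, score = s$score,
      runs = paste(run_paths, collapse = ";"),
      motion = paste(motion_paths, collapse = ";"),
      mask = mask_path,
      pv_wm = pv_paths[["wm"]], pv_csf = pv_paths[["csf"]],
      pv_gm = pv_paths[["gm"]],
      tr = cohort$config$tr, voxel_size = vs,
      rotation_unit = attr(s$motion[[1]], "rotation_unit"))
  })
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(manifest[, c("subject_id", "score")],
              file.path(dir, "scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- cohort$config
  cfg$effect_rois <- purrr::map(cfg$effect_rois, as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(manifest_path)
}

#' Read a cohort manifest
#'
#' @param path Manifest TSV path (as written by [write_cohort()]): columns
#'   `subject_id`, `score`, semicolon-separated `runs` and `motion` paths,
#'   `mask`, `pv_wm`, `pv_csf`, `pv_gm`, `tr`, `voxel_size`,
#'   `rotation_unit`.
#' @return Tibble, one row per subject.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  m <- tibble::as_tibble(read.delim(path, sep = "\t",
                                    stringsAsFactors = FALSE))
  needed <- c("subject_id", "score", "runs", "motion", "mask",
              "pv_wm", "pv_csf", "pv_gm", "tr", "voxel_size")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0)
    abort(paste0("manifest lacks columns: ", paste(missing, collapse = ", ")))
  refs <- c(unlist(strsplit(m$runs, ";")), unlist(strsplit(m$motion, ";")),
            m$mask, m$pv_wm, m$pv_csf, m$pv_gm)
  absent <- refs[!file.exists(refs)]
  if (length(absent) > 0)
    abort(paste0("missing input file(s): ", paste(absent, collapse = ", ")))
  m
}

#' Load one subject record from a manifest row
#'
#' @param row One-row data frame from [read_manifest()].
#' @return A `subject_record` as produced by [generate_cohort()].
#' @export
load_subject_record <- function(row) {
  run_paths <- strsplit(row$runs, ";")[[1]]
  motion_paths <- strsplit(row$motion, ";")[[1]]
  runs <- purrr::map(run_paths, function(p) {
    a <- array(as.numeric(RNifti::readNifti(p)), dim(RNifti::readNifti(p)))
    attr(a, "tr") <- row$tr
    attr(a, "voxel_size") <- row$voxel_size
    a
  })
  motion <- purrr::map(motion_paths, function(p) {
    m <- as.matrix(read.table(p))
    dimnames(m) <- NULL
    attr(m, "rotation_unit") <- row$rotation_unit %||% "degrees"
    m
  })
  mask <- array(as.numeric(RNifti::readNifti(row$mask)) > 0.5,
                dim(RNifti::readNifti(row$mask)))
  pv <- purrr::map(list(wm = row$pv_wm, csf = row$pv_csf, gm = row$pv_gm),
                   function(p) {
                     array(as.numeric(RNifti::readNifti(p)),
                           dim(RNifti::readNifti(p)))
                   })
  structure(list(subject_id = row$subject_id, runs = runs, motion = motion,
                 brain_mask = mask, pv_maps = pv, score = row$score),
            class = "subject_record")
}

#' Analysis run configuration
#'
#' Defaults mirror the reference processing choices: 5 discarded frames,
#' 3 mm smoothing, 0.99 partial-volume threshold with 2 erosions, 50 mm
#' head radius, two-sided voxelwise p = 0.05 cluster-forming threshold,
#' familywise alpha = 0.05 from a 1000-iteration Monte-Carlo null, low-pass
#' filtering off.
#'
#' @param manifest Path to a cohort manifest TSV (may be `NULL` when an
#'   in-memory cohort is supplied to the drivers).
#' @param out_dir Output directory.
#' @param n_discard,fwhm,pv_threshold,erosions,head_radius,lowpass
#'   Preprocessing parameters (see [preprocess_subject()]).
#' @param voxel_p Cluster-forming voxelwise two-sided p threshold.
#' @param alpha Familywise error level.
#' @param n_iter Monte-Carlo iterations for the cluster null.
#' @param connectivity_rule Cluster connectivity (`"faces"`, `"edges"`,
#'   `"corners"`).
#' @param null_fwhm Smoothness assumed for the Monte-Carlo null; defaults
#'   to `fwhm` (the applied smoothing).
#' @param orientation Reporting orientation for peak coordinates.
#' @param seed Root seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest = NULL, out_dir = tempfile("boldvar_run_"),
                       n_discard = 5L, fwhm = 3, pv_threshold = 0.99,
                       erosions = 2L, head_radius = 50, lowpass = FALSE,
                       voxel_p = 0.05, alpha = 0.05, n_iter = 1000L,
                       connectivity_rule = "faces", null_fwhm = NULL,
                       orientation = "LPS", seed = 1L) {
  structure(list(
    manifest = manifest, out_dir = out_dir, n_discard = n_discard,
    fwhm = fwhm, pv_threshold = pv_threshold, erosions = erosions,
    head_radius = head_radius, lowpass = lowpass, voxel_p = voxel_p,
    alpha = alpha, n_iter = as.integer(n_iter),
    connectivity_rule = connectivity_rule,
    null_fwhm = null_fwhm %||% fwhm, orientation = orientation,
    seed = as.integer(seed)
  ), class = "run_config")
}

.load_cohort_from_manifest <- function(config) {
  m <- read_manifest(config$manifest)
  if (nrow(m) < 3) abort("manifest must list at least 3 subjects")
  subjects <- purrr::map(seq_len(nrow(m)),
                         function(i) load_subject_record(m[i, ]))
  vs <- m$voxel_size[1]
  aff <- RNifti::xform(RNifti::readNifti(m$mask[1]))
  aff <- matrix(as.numeric(aff), 4, 4)
  list(subjects = subjects, voxel_size = vs, affine = aff)
}

.preprocess_cohort <- function(subjects, config) {
  purrr::map(subjects, function(s) {
    preprocess_subject(
      s, n_discard = config$n_discard, fwhm = config$fwhm,
      mask_erosion = config$erosions, pv_threshold = config$pv_threshold,
      tissue_erosion = config$erosions, head_radius = config$head_radius,
      lowpass = config$lowpass)
  })
}

.motion_confound <- function(preps, scores) {
  correlate_with_scores(vapply(preps, `[[`, 0, "mean_fd"), scores)
}

.write_provenance <- function(config, path, extra = list()) {
  prov <- c(unclass(config), extra,
            list(package_version = as.character(utils::packageVersion("boldvar")),
                 timestamp = format(Sys.time(), tz = "UTC")))
  prov <- purrr::map(prov, function(x) if (is.null(x)) NA else x)
  yaml::write_yaml(prov, path)
}

#' Run the variability analysis end to end
#'
#' Preprocesses every subject, maps voxelwise BOLD signal variability,
#' correlates it with the behavioural scores across subjects, computes the
#' Monte-Carlo minimum cluster extent, extracts and labels surviving
#' clusters, and checks the motion confound (mean FD vs score). Outputs:
#' `variability_r.nii.gz`, `variability_p.nii.gz`, `clusters.tsv`,
#' `motion_confound.tsv`, `provenance.yaml` under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param cohort Optional in-memory [generate_cohort()] cohort; when `NULL`
#'   the manifest in `config` is read instead. Parcellation and labels for
#'   reporting are taken from the cohort or from `parcellation`/`labels`.
#' @param parcellation,labels Required when running from a manifest:
#'   integer label volume and label table for cluster reporting.
#' @return Invisibly, a list: `stat_map`, `report`, `clusters`, `k_min`,
#'   `null`, `motion_confound`, `mean_fd`, `out_dir`.
#' @export
run_variability_analysis <- function(config, cohort = NULL,
                                     parcellation = NULL, labels = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    loaded <- .load_cohort_from_manifest(config)
    subjects <- loaded$subjects
    if (is.null(parcellation) || is.null(labels))
      abort("supply `parcellation` and `labels` when running from a manifest")
    affine <- loaded$affine; vs <- loaded$voxel_size
  } else {
    subjects <- cohort$subjects
    parcellation <- parcellation %||% cohort$parcellation
    labels <- labels %||% cohort$labels
    affine <- cohort$affine; vs <- cohort$voxel_size
  }
  scores <- vapply(subjects, `[[`, 0, "score")

  preps <- .preprocess_cohort(subjects, config)
  sd_maps <- purrr::map2(preps, subjects, function(p, s) {
    voxel_sd(p$pc, subject_id = s$subject_id)
  })
  stat <- cohort_variability_map(sd_maps, scores, affine = affine,
                                 voxel_size = vs)
  null <- simulate_null_distribution(
    stat$mask, fwhm = config$null_fwhm, voxel_size = vs,
    voxel_p = config$voxel_p, n_iter = config$n_iter,
    connectivity_rule = config$connectivity_rule,
    seed = .derive_seed(config$seed, "cluster_null"))
  k_min <- min_cluster_size(null, config$alpha)
  clusters <- extract_clusters(stat, voxel_p = config$voxel_p,
                               k_min = k_min,
                               connectivity_rule = config$connectivity_rule)
  report <- report_clusters(clusters, stat, parcellation, labels,
                            orientation = config$orientation)
  confound <- .motion_confound(preps, scores)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_nifti_vol(ifelse(is.na(stat$r), 0, stat$r), affine, vs,
                   file.path(config$out_dir, "variability_r.nii.gz"))
  .write_nifti_vol(ifelse(is.na(stat$p), 1, stat$p), affine, vs,
                   file.path(config$out_dir, "variability_p.nii.gz"))
  write.table(format_cluster_report(report),
              file.path(config$out_dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(confound, file.path(config$out_dir, "motion_confound.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .write_provenance(config,
                    file.path(config$out_dir, "provenance.yaml"),
                    list(stage = "variability", k_min = k_min,
                         n_subjects = length(subjects)))

  invisible(list(stat_map = stat, report = report, clusters = clusters,
                 k_min = k_min, null = null, motion_confound = confound,
                 mean_fd = vapply(preps, `[[`, 0, "mean_fd"),
                 out_dir = config$out_dir))
}

#' Run the seed-connectivity analysis end to end
#'
#' For each seed parcel: computes per-subject whole-brain Fisher-z seed
#' correlation maps, correlates z with the behavioural scores across
#' subjects, applies the Monte-Carlo cluster correction, and writes one
#' statistic map and cluster table per seed plus a summary of which seeds
#' produced surviving clusters.
#'
#' @param config A [run_config()].
#' @param seeds Tibble of seed definitions ([seed_definitions()]); defaults
#'   to every parcel in the label table.
#' @inheritParams run_variability_analysis
#' @return Invisibly, a list: `per_seed` (named list with `stat_map`,
#'   `report`, `clusters`), `summary` tibble (`label`, `name`, `side`,
#'   `n_clusters`), `k_min`, `null`, `motion_confound`, `out_dir`.
#' @export
run_connectivity_analysis <- function(config, cohort = NULL, seeds = NULL,
                                      parcellation = NULL, labels = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    loaded <- .load_cohort_from_manifest(config)
    subjects <- loaded$subjects
    if (is.null(parcellation) || is.null(labels))
      abort("supply `parcellation` and `labels` when running from a manifest")
    affine <- loaded$affine; vs <- loaded$voxel_size
  } else {
    subjects <- cohort$subjects
    parcellation <- parcellation %||% cohort$parcellation
    labels <- labels %||% cohort$labels
    affine <- cohort$affine; vs <- cohort$voxel_size
  }
  if (is.null(seeds)) seeds <- seed_definitions(labels, parcellation)
  if (nrow(seeds) == 0) {
    warn("empty seed list: nothing to do")
    return(invisible(list(per_seed = list(), summary = tibble::tibble())))
  }
  missing <- setdiff(seeds$label, unique(as.vector(parcellation)))
  if (length(missing) > 0)
    abort(paste0("seed label(s) not in parcellation: ",
                 paste(missing, collapse = ", ")))
  scores <- vapply(subjects, `[[`, 0, "score")

  preps <- .preprocess_cohort(subjects, config)
  group_mask <- Reduce(`&`, purrr::map(preps, "mask"))
  null <- simulate_null_distribution(
    group_mask, fwhm = config$null_fwhm, voxel_size = vs,
    voxel_p = config$voxel_p, n_iter = config$n_iter,
    connectivity_rule = config$connectivity_rule,
    seed = .derive_seed(config$seed, "cluster_null"))
  k_min <- min_cluster_size(null, config$alpha)
  confound <- .motion_confound(preps, scores)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  per_seed <- list()
  summary_rows <- list()
  for (i in seq_len(nrow(seeds))) {
    sdef <- seeds[i, ]
    maps <- purrr::map2(preps, subjects, function(p, s) {
      ts <- roi_mean_timeseries(p$pc, parcellation, label = sdef$label)
      seed_correlation_map(p$pc, ts, seed = sdef, subject_id = s$subject_id)
    })
    stat <- cohort_connectivity_map(maps, scores, affine = affine,
                                    voxel_size = vs)
    clusters <- extract_clusters(stat, voxel_p = config$voxel_p,
                                 k_min = k_min,
                                 connectivity_rule = config$connectivity_rule)
    report <- report_clusters(clusters, stat, parcellation, labels,
                              orientation = config$orientation)
    tag <- sprintf("seed-%02d_%s_%s", sdef$label, sdef$name, sdef$side)
    .write_nifti_vol(ifelse(is.na(stat$r), 0, stat$r), affine, vs,
                     file.path(config$out_dir, paste0(tag, "_r.nii.gz")))
    write.table(format_cluster_report(report),
                file.path(config$out_dir, paste0(tag, "_clusters.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    per_seed[[tag]] <- list(stat_map = stat, report = report,
                            clusters = clusters)
    summary_rows[[i]] <- tibble::tibble(
      label = sdef$label, name = sdef$name, side = sdef$side,
      n_clusters = nrow(clusters))
  }
  summary <- dplyr::bind_rows(summary_rows)
  write.table(summary, file.path(config$out_dir, "seed_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .write_provenance(config,
                    file.path(config$out_dir, "provenance.yaml"),
                    list(stage = "connectivity", k_min = k_min,
                         n_subjects = length(subjects),
                         seeds = paste(seeds$label, collapse = ",")))

  invisible(list(per_seed = per_seed, summary = summary, k_min = k_min,
                 null = null, motion_confound = confound,
                 out_dir = config$out_dir))
}
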