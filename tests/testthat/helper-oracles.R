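# Independent brute-force oracles and small fixtures, built in code.

# Brute-force binary erosion: a voxel survives iff every structuring-element
# offset lands on a TRUE voxel (outside the array counts as FALSE).
oracle_erode <- function(mask, offsets) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (row in seq_len(nrow(idx))) {
    v <- idx[row, ]
    ok <- TRUE
    for (o in seq_len(nrow(offsets))) {
      w <- v + offsets[o, ]
      if (any(w < 1) || any(w > d) || !mask[w[1], w[2], w[3]]) {
        ok <- FALSE
        break
      }
    }
    out[v[1], v[2], v[3]] <- ok
  }
  out
}

se_offsets_2d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0))
se_offsets_3d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

# Breadth-first-search connected components, independent of the compiled
# labeller.
oracle_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  offs <- se_offsets_3d[rowSums(abs(se_offsets_3d)) > 0, , drop = FALSE]
  nn <- rowSums(abs(offs))
  offs <- offs[nn <= switch(as.character(connectivity),
                            "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  labels <- array(0L, d)
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (o in seq_len(nrow(offs))) {
        w <- ijk + offs[o, ]
        if (any(w < 1) || any(w > d)) next
        wl <- w[1] + d[1] * ((w[2] - 1) + d[2] * (w[3] - 1))
        if (mask[wl] && labels[wl] == 0L) {
          labels[wl] <- current
          queue <- c(queue, wl)
        }
      }
    }
  }
  labels
}

# Partition voxel counts of a labelling, invariant to label numbering.
component_sizes <- function(labels) sort(tabulate(labels[labels > 0]))

dice_coefficient <- function(a, b) {
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Small cohort for fast tests.
tiny_cohort <- function(seed = 1, n_subjects = 5, grid = c(16, 16, 12),
                        n_t = 40, effect_rois = list(),
                        connectivity_effect = NULL, ...) {
  generate_cohort(cohort_config(
    n_subjects = n_subjects, grid_shape = grid, n_runs = 1,
    n_timepoints_per_run = n_t, seed = seed, effect_rois = effect_rois,
    connectivity_effect = connectivity_effect, ...))
}

# Percent-fluctuation series straight from a raw synthetic run (baseline
# 1000), bypassing preprocessing — used where only the generator's output
# statistics are under test.
raw_pc <- function(subject, run = 1) {
  arr <- subject$runs[[run]]
  pc_series(100 * (arr / 1000 - 1), subject$brain_mask,
            attr(arr, "tr") %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Construct a cohort_stat_map directly from r/p arrays (for cluster tests).
make_stat_map <- function(r, p, mask, n_subjects = 10, voxel_size = 2) {
  boldvar:::.new_stat_map(as.vector(r), as.vector(p), mask, n_subjects,
                          "test", boldvar:::.default_affine(dim(mask),
                                                            voxel_size),
                          voxel_size)
}

# Vectors with an exact prescribed sample correlation.
exact_corr_pair <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  e <- rnorm(n)
  e <- scale(e - x * sum(e * x) / sum(x^2))[, 1]
  list(x = x, y = rho * x + sqrt(1 - rho^2) * e)
}
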