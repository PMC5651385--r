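#' Generate a synthetic two-group cohort feature table
#'
#' Emulates the feature structure the pipeline sees after masking a cohort
#' of co-registered scalar diffusion maps: a subjects-by-voxels matrix with
#' independent Gaussian voxel noise, in which a designated fraction of
#' voxels carries a group effect. Control values are
#' \eqn{N(\mu_0, \sigma^2)} i.i.d.; at the discriminative voxels patients are
#' shifted by \eqn{-d\,\sigma} (patients *lower*, so recovered linear-SVM
#' coefficients are negative there, matching the convention that negative
#' coefficients mean controls have the higher intensities); elsewhere
#' patients are distributed exactly as controls. Default cohort sizes follow
#' the study design (32 patients, 36 controls); `baseline = 1.0` and
#' `noise_sd = 0.1` give a plausible mean-kurtosis-like scale and are
#' otherwise arbitrary.
#'
#' @param n_patients,n_controls Group sizes (defaults 32 and 36).
#' @param n_voxels Number of voxel columns.
#' @param discriminative_fraction Fraction of voxels carrying the group
#'   effect; `round(discriminative_fraction * n_voxels)` voxels are chosen
#'   (at seeded random positions) and recorded as ground truth.
#' @param effect_size Standardized mean group difference `d >= 0` at the
#'   discriminative voxels.
#' @param noise_sd Voxel noise standard deviation.
#' @param baseline Control mean intensity.
#' @param patients_lower Simulate patients lower (default) or higher.
#' @param seed Integer seed; the table is fully determined by the arguments.
#' @param measure_tag Measure name recorded on the table.
#' @return A [cohort_features()] tibble (patients first, then controls) with
#'   the 0-based ground-truth voxel indices attached as attribute
#'   `"ground_truth"` (see [ground_truth_voxels()]).
#' @export
#' @examples
#' tab <- generate_cohort(n_voxels = 50, seed = 1)
#' length(ground_truth_voxels(tab))
generate_cohort <- function(n_patients = 32, n_controls = 36, n_voxels = 500,
                            discriminative_fraction = 0.1, effect_size = 2,
                            noise_sd = 0.1, baseline = 1.0,
                            patients_lower = TRUE, seed = 1,
                            measure_tag = "synthetic") {
  stopifnot(n_patients >= 2, n_controls >= 2, n_voxels >= 1,
            discriminative_fraction >= 0, discriminative_fraction <= 1,
            effect_size >= 0, noise_sd > 0)
  n <- n_patients + n_controls
  n_disc <- round(discriminative_fraction * n_voxels)
  withr::with_seed(seed, {
    truth <- sort(sample.int(n_voxels, n_disc))
    m <- matrix(stats::rnorm(n * n_voxels, mean = baseline, sd = noise_sd),
                n, n_voxels)
  })
  shift <- effect_size * noise_sd * (if (patients_lower) -1 else 1)
  if (n_disc > 0) {
    m[seq_len(n_patients), truth] <- m[seq_len(n_patients), truth] + shift
  }
  tab <- cohort_features(
    m,
    labels = rep(c(1L, 0L), c(n_patients, n_controls)),
    subject_ids = c(sprintf("pat%02d", seq_len(n_patients)),
                    sprintf("con%02d", seq_len(n_controls))),
    measure_tag = measure_tag
  )
  attr(tab, "ground_truth") <- truth - 1L # 0-based, matching voxel_index_map
  tab
}

#' Ground-truth discriminative voxel indices of a synthetic table
#'
#' @param table A table from [generate_cohort()] (or re-extracted from
#'   [generate_volume_fixtures()] output).
#' @return Integer vector of 0-based voxel indices (relative to the table's
#'   columns for [generate_cohort()] output).
#' @export
ground_truth_voxels <- function(table) attr(table, "ground_truth")

#' Generate NIfTI volume fixtures embedding a synthetic cohort
#'
#' Writes per-subject scalar maps, a white-matter probability map and an
#' atlas label volume to `dir`, planting the cohort's voxel columns at
#' seeded random grid locations. The planted locations get white-matter
#' probability 0.3 and an ROI atlas label, so they — and only they — pass
#' the default mask ([build_mask()] with threshold 0.2 and
#' `roi_labels = fixture$roi_labels`); decoy voxels passing exactly one of
#' the two criteria are planted as well, and the remaining background fails
#' both. Re-extracting with that mask recovers the feature table bit-exactly
#' (columns reordered to ascending linear index).
#'
#' @param dir Output directory (created if needed).
#' @param grid_dims 3-D grid dimensions; `prod(grid_dims)` must be at least
#'   `n_voxels` plus room for decoys.
#' @param seed Integer seed (drives both the cohort and the placement).
#' @inheritParams generate_cohort
#' @param ... Further arguments to [generate_cohort()].
#' @return List with `dir`, the per-subject map `paths`, `wm_path`,
#'   `atlas_path`, `roi_labels`, the planted 0-based `voxel_index_map`, the
#'   cohort `table` (columns already in grid order) and the grid's 0-based
#'   `ground_truth` indices.
#' @export
generate_volume_fixtures <- function(dir, grid_dims = c(12, 12, 8),
                                     n_voxels = 100, seed = 1, ...) {
  n_grid <- prod(grid_dims)
  n_decoy <- min(20, n_grid - n_voxels)
  if (n_grid < n_voxels + 2) {
    stop(sprintf("Grid of %d voxels is too small for %d analysis voxels.",
                 n_grid, n_voxels), call. = FALSE)
  }
  tab <- generate_cohort(n_voxels = n_voxels, seed = seed, ...)

  withr::with_seed(seed, {
    pick <- sample.int(n_grid, n_voxels + n_decoy)
  })
  planted <- sort(pick[seq_len(n_voxels)])
  decoys <- pick[-seq_len(n_voxels)]
  wm_only <- decoys[seq_len(floor(n_decoy / 2))]
  roi_only <- setdiff(decoys, wm_only)

  # reorder cohort columns to ascending planted linear index
  m <- feature_matrix(tab)
  tab_grid <- cohort_features(
    m, labels = feature_labels(tab), subject_ids = tab$subject_id,
    voxel_index_map = planted - 1L, measure_tag = measure_tag(tab)
  )
  truth_grid <- sort((planted - 1L)[ground_truth_voxels(tab) + 1L])
  attr(tab_grid, "ground_truth") <- truth_grid

  wm <- array(0.05, grid_dims)
  wm[planted] <- 0.3
  wm[wm_only] <- 0.9 # in white matter but outside the ROI
  atlas <- array(0L, grid_dims)
  atlas[planted] <- rep_len(c(1L, 2L), length(planted))
  atlas[roi_only] <- 1L # in the ROI but below the WM threshold

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(nrow(tab_grid)), function(s) {
    vol <- array(0, grid_dims)
    vol[planted] <- m[s, ]
    p <- file.path(dir, paste0("map_", tab_grid$subject_id[s], ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol), p)
    p
  }, character(1))
  names(paths) <- tab_grid$subject_id
  wm_path <- file.path(dir, "wm_probability.nii.gz")
  atlas_path <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(wm), wm_path)
  RNifti::writeNifti(RNifti::asNifti(atlas + 0), atlas_path)

  list(
    dir = dir, paths = paths, wm_path = wm_path, atlas_path = atlas_path,
    roi_labels = c(1L, 2L), voxel_index_map = planted - 1L,
    table = tab_grid, ground_truth = truth_grid
  )
}

#' Permute the group labels of a cohort table
#'
#' Uniformly permutes the label vector while leaving the features untouched,
#' preserving class counts — the permutation null used to check that the
#' pipeline's accuracy falls to chance when the labels carry no information.
#'
#' @param table A [cohort_features()] tibble.
#' @param seed Integer seed.
#' @return The table with permuted labels (same class, same attributes).
#' @export
permute_labels <- function(table, seed = 1) {
  stopifnot(inherits(table, "cohort_features"))
  perm <- withr::with_seed(seed, sample.int(nrow(table)))
  out <- table
  out$label <- table$label[perm]
  out
}
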