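#' Build the analysis mask from a white-matter probability map and an atlas
#'
#' A voxel enters the analysis when it has probability `threshold` or greater
#' of belonging to white matter (the comparison is inclusive) *and* its atlas
#' label is in `roi_labels` — typically the union of all regions of interest
#' for the left temporal lobe. Both volumes must already live on the common
#' analysis grid.
#'
#' @param wm White-matter probability volume: a 3-D numeric array or
#'   `RNifti::niftiImage` with values in \[0, 1\].
#' @param atlas Integer-valued label volume on the same grid.
#' @param roi_labels Integer vector of atlas labels whose union defines the
#'   region of interest.
#' @param threshold White-matter probability cutoff, inclusive; default 0.20.
#'
#' @return A `mask_set` object: a list with the logical `mask` array, the
#'   0-based `voxel_index_map` of mask-true voxels (column-major linear
#'   indices, ascending), `n_voxels`, the two criteria's individual counts and
#'   the inputs' parameters.
#' @export
#' @examples
#' wm <- array(c(0.1, 0.2, 0.5, 0.9), c(2, 2, 1))
#' atlas <- array(c(1L, 1L, 0L, 2L), c(2, 2, 1))
#' build_mask(wm, atlas, roi_labels = c(1, 2))
build_mask <- function(wm, atlas, roi_labels, threshold = 0.2) {
  wm <- as_volume_array(wm)
  atlas <- as_volume_array(atlas)
  if (!identical(dim(wm), dim(atlas))) {
    stop(sprintf(
      "Grid mismatch: white-matter map is %s but atlas is %s.",
      paste(dim(wm), collapse = "x"), paste(dim(atlas), collapse = "x")
    ), call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must be a probability in [0, 1].", call. = FALSE)
  }
  wm_ok <- wm >= threshold
  roi_ok <- array(atlas %in% as.integer(roi_labels), dim(atlas))
  mask <- wm_ok & roi_ok
  if (!any(mask)) {
    stop(sprintf(
      paste0("Analysis mask is empty: %d voxels pass the white-matter ",
             "threshold (>= %g) and %d are in the ROI label set, but their ",
             "intersection is empty."),
      sum(wm_ok), threshold, sum(roi_ok)
    ), call. = FALSE)
  }
  structure(
    list(
      mask = mask,
      voxel_index_map = which(as.logical(mask)) - 1L,
      n_voxels = sum(mask),
      n_wm = sum(wm_ok),
      n_roi = sum(roi_ok),
      threshold = threshold,
      roi_labels = as.integer(roi_labels),
      grid_dims = dim(mask)
    ),
    class = "mask_set"
  )
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf(
    "# Analysis mask: %d voxels on a %s grid (WM >= %g: %d; ROI labels {%s}: %d)\n",
    x$n_voxels, paste(x$grid_dims, collapse = "x"), x$threshold, x$n_wm,
    paste(x$roi_labels, collapse = ","), x$n_roi
  ))
  invisible(x)
}

#' Extract the subject-by-voxel feature matrix under a mask
#'
#' Reads every subject's scalar map at the mask-true voxels and assembles the
#' cohort feature table; columns are ordered by ascending linear voxel index.
#'
#' @param volumes Named list of per-subject volumes (3-D arrays,
#'   `RNifti::niftiImage`, or file paths readable by [RNifti::readNifti()]).
#'   Names are used as subject ids when present.
#' @param labels Group labels, one per volume (patient = 1, control = 0).
#' @param mask A `mask_set` from [build_mask()].
#' @param measure_tag Measure name recorded on the table.
#'
#' @return A [cohort_features()] tibble with `mask$n_voxels` voxel columns.
#' @export
extract_features <- function(volumes, labels, mask, measure_tag = "synthetic") {
  stopifnot(inherits(mask, "mask_set"))
  ids <- names(volumes)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(volumes))
  rows <- lapply(seq_along(volumes), function(s) {
    v <- as_volume_array(volumes[[s]])
    if (!identical(dim(v), mask$grid_dims)) {
      stop(sprintf(
        "Subject '%s': volume grid %s does not match mask grid %s.",
        ids[s], paste(dim(v), collapse = "x"),
        paste(mask$grid_dims, collapse = "x")
      ), call. = FALSE)
    }
    vals <- v[mask$voxel_index_map + 1L]
    if (!all(is.finite(vals))) {
      bad <- mask$voxel_index_map[which(!is.finite(vals))[1]]
      stop(sprintf(
        "Subject '%s' has a non-finite value at masked voxel index %d.",
        ids[s], bad
      ), call. = FALSE)
    }
    vals
  })
  cohort_features(
    do.call(rbind, rows),
    labels = labels,
    subject_ids = ids,
    voxel_index_map = mask$voxel_index_map,
    measure_tag = measure_tag
  )
}

#' Render a per-voxel coefficient vector back to image space
#'
#' Places `values[j]` at the table's `voxel_index_map[j]` and 0 everywhere
#' else, so that re-extracting with the same mask recovers the vector exactly.
#' Used to write aggregated SVM coefficient maps (and sign-count maps) as
#' NIfTI volumes for inspection alongside the input scalar maps.
#'
#' @param values Numeric vector, one value per voxel column of `table`.
#' @param table The [cohort_features()] tibble whose voxel index map defines
#'   the placement.
#' @param reference A reference volume (array, `niftiImage` or path) supplying
#'   grid dimensions and, when a NIfTI image, orientation metadata.
#' @param path Optional output path; when given, the volume is written with
#'   [RNifti::writeNifti()].
#' @return The coefficient volume as an array (invisibly when `path` is given).
#' @export
write_coefficient_map <- function(values, table, reference, path = NULL) {
  stopifnot(inherits(table, "cohort_features"))
  idx <- voxel_index_map(table)
  if (length(values) != length(idx)) {
    stop(sprintf(
      "Coefficient vector has length %d but the table has %d voxels.",
      length(values), length(idx)
    ), call. = FALSE)
  }
  ref <- if (is.character(reference)) RNifti::readNifti(reference) else reference
  out <- array(0, dim(ref)[1:3])
  out[idx + 1L] <- values
  if (!is.null(path)) {
    img <- if (inherits(ref, "niftiImage")) {
      RNifti::asNifti(out, reference = ref)
    } else {
      RNifti::asNifti(out)
    }
    RNifti::writeNifti(img, path)
    return(invisible(out))
  }
  out
}

# Coerce paths / niftiImage / arrays to a plain numeric 3-D array. Singleton
# trailing dimensions are restored/dropped as needed (NIfTI writers collapse
# them).
as_volume_array <- function(x) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  a <- unclass(as.array(x))
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  while (length(d) > 3 && d[length(d)] == 1) d <- d[-length(d)]
  if (length(d) > 3) stop("Volumes must be 3-D.", call. = FALSE)
  dim(a) <- c(d, rep(1L, 3 - length(d)))
  attributes(a) <- list(dim = dim(a))
  a
}
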