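#' Construct a cohort feature table
#'
#' The central data structure of the pipeline: one row per subject, with a
#' subject identifier, a binary group label (patient = 1, control = 0) and one
#' column per analysis voxel. Voxel columns are named `v<index>` where
#' `<index>` is the 0-based linear index of the voxel in the source grid
#' (column-major, i.e. the first grid dimension varies fastest), so
#' coefficient vectors can always be mapped back to image space.
#'
#' @param matrix Numeric matrix, subjects by voxels. All values must be finite.
#' @param labels Integer/logical vector of group labels, one per row;
#'   patient = 1, control = 0.
#' @param subject_ids Character vector of unique subject identifiers. Defaults
#'   to `s01`, `s02`, ...
#' @param voxel_index_map Integer vector of 0-based linear voxel indices, one
#'   per column, strictly increasing. Defaults to `0:(ncol - 1)`.
#' @param measure_tag Character scalar naming the underlying scalar measure
#'   (e.g. `"MK"`, `"FA"`, `"MD"`, `"synthetic"`).
#'
#' @return A tibble of class `cohort_features` with columns `subject_id`,
#'   `label`, then the voxel columns; the voxel index map and measure tag are
#'   carried as attributes (see [voxel_index_map()], [measure_tag()]).
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2)
#' cohort_features(m, labels = c(1, 0, 0))
cohort_features <- function(matrix, labels, subject_ids = NULL,
                            voxel_index_map = NULL, measure_tag = "synthetic") {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%02d", seq_len(n))
  if (is.null(voxel_index_map)) voxel_index_map <- seq_len(ncol(matrix)) - 1L
  voxel_index_map <- as.integer(voxel_index_map)
  labels <- as.integer(labels)

  if (length(labels) != n) {
    stop("`labels` must have one entry per row of `matrix`.", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must be 0 (control) or 1 (patient).", call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) {
    stop("`subject_ids` must be unique.", call. = FALSE)
  }
  if (length(voxel_index_map) != ncol(matrix)) {
    stop("`voxel_index_map` must have one entry per voxel column.", call. = FALSE)
  }
  if (is.unsorted(voxel_index_map, strictly = TRUE)) {
    stop("`voxel_index_map` must be strictly increasing.", call. = FALSE)
  }
  if (!all(is.finite(matrix))) {
    bad <- which(!is.finite(matrix), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "Non-finite feature value for subject '%s' at voxel index %d.",
      subject_ids[bad[1]], voxel_index_map[bad[2]]
    ), call. = FALSE)
  }

  colnames(matrix) <- paste0("v", voxel_index_map)
  out <- tibble::tibble(
    subject_id = as.character(subject_ids),
    label = labels
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(matrix))
  new_cohort_features(out, voxel_index_map, measure_tag)
}

new_cohort_features <- function(df, voxel_index_map, measure_tag) {
  structure(
    df,
    voxel_index_map = as.integer(voxel_index_map),
    measure_tag = as.character(measure_tag),
    class = c("cohort_features", class(tibble::tibble()))
  )
}

#' Accessors for cohort feature tables
#'
#' @param table A [cohort_features()] tibble.
#' @return `feature_matrix()` returns the subjects-by-voxels numeric matrix
#'   (row names are subject ids); `feature_labels()` the integer label vector;
#'   `voxel_index_map()` the 0-based linear voxel indices of the columns;
#'   `measure_tag()` the measure name.
#' @export
feature_matrix <- function(table) {
  stopifnot(inherits(table, "cohort_features"))
  m <- as.matrix(table[, voxel_columns(table), drop = FALSE])
  rownames(m) <- table$subject_id
  m
}

#' @rdname feature_matrix
#' @export
feature_labels <- function(table) {
  stopifnot(inherits(table, "cohort_features"))
  table$label
}

#' @rdname feature_matrix
#' @export
voxel_index_map <- function(table) attr(table, "voxel_index_map")

#' @rdname feature_matrix
#' @export
measure_tag <- function(table) attr(table, "measure_tag")

voxel_columns <- function(table) paste0("v", voxel_index_map(table))

# Subset rows while keeping class + attributes (columns untouched).
subset_subjects <- function(table, idx) {
  df <- dplyr::slice(tibble::as_tibble(table), idx)
  new_cohort_features(df, voxel_index_map(table), measure_tag(table))
}

#' @export
`[.cohort_features` <- function(x, i, j, ...) {
  vmap <- attr(x, "voxel_index_map")
  mtag <- attr(x, "measure_tag")
  out <- NextMethod()
  keep <- c("subject_id", "label", paste0("v", vmap))
  if (is.data.frame(out) && identical(names(out), keep)) {
    return(new_cohort_features(tibble::as_tibble(out), vmap, mtag))
  }
  out
}

validate_two_classes <- function(table) {
  tab <- table(feature_labels(table))
  if (length(tab) < 2 || any(tab < 2)) {
    stop("Training table must contain at least 2 subjects of each class.",
         call. = FALSE)
  }
  invisible(table)
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf(
    "# Cohort feature table [%s]: %d subjects (%d patients / %d controls) x %d voxels\n",
    measure_tag(x), nrow(x), sum(x$label == 1L), sum(x$label == 0L),
    length(voxel_index_map(x))
  ))
  NextMethod()
}

#' Read and write cohort feature tables as CSV
#'
#' The on-disk format is one row per subject: `subject_id`, `label`, then one
#' column per voxel named `v<linear index>`.
#'
#' @param table A [cohort_features()] tibble.
#' @param path File path.
#' @param measure_tag Measure name to attach on read (the CSV itself only
#'   stores indices and values).
#' @return `write_features()` returns `table` invisibly; `read_features()`
#'   returns a [cohort_features()] tibble.
#' @export
write_features <- function(table, path) {
  stopifnot(inherits(table, "cohort_features"))
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(table)
}

#' @rdname write_features
#' @export
read_features <- function(path, measure_tag = "synthetic") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  idx <- as.integer(sub("^v", "", vcols))
  cohort_features(
    as.matrix(df[, vcols[order(idx)], drop = FALSE]),
    labels = df$label,
    subject_ids = df$subject_id,
    voxel_index_map = sort(idx),
    measure_tag = measure_tag
  )
}
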