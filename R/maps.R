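# Map containers. A map set holds one modality's per-location values for a
# set of subjects as a locations x subjects matrix; a single subject's map is
# one column. Lesion mask stacks use the same layout with binary values over
# the full voxel grid.

#' Construct a map set
#'
#' @param values Numeric matrix, locations in rows, subjects in columns.
#' @param subject_id Character vector of column labels.
#' @param modality One of `"thickness"`, `"FA"`, `"MD"` or a user label.
#' @param space `"surface"` or `"skeleton"`.
#' @param geometry The `wmap_geometry` the locations refer to.
#' @return Object of class `map_set`.
#' @export
map_set <- function(values, subject_id, modality, space, geometry) {
  values <- as.matrix(values)
  if (ncol(values) != length(subject_id)) {
    data_error("map_set: one subject_id per column required")
  }
  if (nrow(values) != n_locations(geometry, space)) {
    data_error(sprintf(
      "map_set: %d rows but geometry has %d %s locations",
      nrow(values), n_locations(geometry, space), space))
  }
  if (modality == "FA" && (min(values) < 0 || max(values) > 1)) {
    data_error("FA values must lie in [0, 1]")
  }
  if (modality %in% c("MD", "thickness") && min(values) < 0) {
    data_error(sprintf("%s values must be non-negative", modality))
  }
  colnames(values) <- subject_id
  structure(list(values = values, subject_id = subject_id,
                 modality = modality, space = space,
                 n_locations = nrow(values)),
            class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  cat(sprintf("<map_set> %s (%s space): %d locations x %d subjects\n",
              x$modality, x$space, x$n_locations, length(x$subject_id)))
  invisible(x)
}

subset_subjects <- function(maps, ids) {
  keep <- match(ids, maps$subject_id)
  if (anyNA(keep)) {
    data_error(sprintf("maps missing subject(s): %s",
                       paste(ids[is.na(keep)], collapse = ", ")))
  }
  maps$values <- maps$values[, keep, drop = FALSE]
  maps$subject_id <- maps$subject_id[keep]
  maps
}

#' Construct a lesion mask stack
#'
#' Binary white-matter-hyperintensity masks over the full voxel grid, one
#' column per subject.
#'
#' @param values Matrix with entries in \{0, 1\}, `prod(grid_shape)` rows.
#' @param subject_id Subject labels (columns).
#' @param geometry A `wmap_geometry` (supplies `grid_shape`, voxel size).
#' @return Object of class `lesion_masks`.
#' @export
lesion_masks <- function(values, subject_id, geometry) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) {
    bad <- which(!(values %in% c(0, 1)))[1]
    vox <- (bad - 1) %% nrow(values) + 1
    subj <- (bad - 1) %/% nrow(values) + 1
    data_error(sprintf("non-binary mask value %g at voxel %d, subject '%s'",
                       values[bad], vox, subject_id[subj]))
  }
  if (nrow(values) != prod(geometry$skeleton$grid_shape)) {
    data_error("lesion mask grid does not match geometry grid_shape")
  }
  colnames(values) <- subject_id
  structure(list(values = values, subject_id = subject_id,
                 grid_shape = geometry$skeleton$grid_shape,
                 voxel_size_mm = geometry$skeleton$voxel_size_mm),
            class = "lesion_masks")
}
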