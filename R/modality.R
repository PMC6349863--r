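# Modality conventions, skeleton masking and surface smoothing.

#' Direction of abnormality for a modality
#'
#' With the raw-minus-predicted W-score convention, damage shows as lower
#' thickness, lower FA and higher MD; this orients one-sided reporting of
#' contrasts only — the tests themselves are two-sided.
#'
#' @param modality `"thickness"`, `"FA"` or `"MD"`.
#' @return `"lower_is_abnormal"` or `"higher_is_abnormal"`.
#' @export
abnormality_direction <- function(modality) {
  switch(modality,
         thickness = "lower_is_abnormal",
         FA = "lower_is_abnormal",
         MD = "higher_is_abnormal",
         config_error(sprintf("unknown modality '%s'", modality)))
}

#' Skeleton analysis mask from a mean FA map
#'
#' Voxels with mean FA strictly above the threshold (default 0.2) are kept,
#' excluding voxels dominated by grey matter or CSF; all skeleton analyses
#' are restricted to this mask.
#'
#' @param mean_fa_map A [map_set()] of modality `"FA"` with a single column
#'   (the control mean FA), or a numeric vector of mean FA values.
#' @param threshold FA threshold (strict `>`).
#' @return Logical vector over skeleton voxels.
#' @export
build_skeleton_mask <- function(mean_fa_map, threshold = 0.2) {
  if (inherits(mean_fa_map, "map_set")) {
    if (mean_fa_map$modality != "FA") {
      data_error("skeleton mask requires an FA map")
    }
    fa <- rowMeans(mean_fa_map$values)
  } else {
    fa <- as.numeric(mean_fa_map)
  }
  fa > threshold
}

#' Smooth a surface map by iterated neighbour averaging
#'
#' Each pass replaces every vertex value by the mean of itself and its
#' grid-graph neighbours. The pass count is chosen from the random-walk
#' variance relation so that the equivalent Gaussian kernel matches the
#' requested FWHM: one pass adds `2 h^2 / (d + 1)` variance per surface
#' axis (`h` = vertex spacing, `d` = degree 4), and a Gaussian of the
#' requested FWHM has per-axis variance `fwhm^2 / (8 log 2)`, so
#' `k = round(fwhm^2 (d+1) / (16 log(2) h^2))`. With `fwhm = 0` the map is
#' returned unchanged. On the closed (toroidal) grid the averaging operator
#' is doubly stochastic: constants, the map mean and total mass are
#' preserved.
#'
#' @param map A surface [map_set()] (or numeric vector/matrix of vertex
#'   values).
#' @param geometry A `wmap_geometry`.
#' @param fwhm_mm Requested full-width-half-maximum in mm (>= 0).
#' @return Same container as the input with smoothed values.
#' @export
smooth_surface_map <- function(map, geometry, fwhm_mm) {
  check_scalar_number(fwhm_mm, "fwhm_mm", min = 0)
  is_set <- inherits(map, "map_set")
  if (is_set && map$space != "surface") {
    data_error("smooth_surface_map() needs a surface-space map")
  }
  values <- if (is_set) map$values else as.matrix(map)
  if (fwhm_mm == 0) return(map)
  k <- smoothing_iterations(fwhm_mm, geometry$surface$spacing_mm)
  if (k == 0L) return(map)
  S <- averaging_operator(geometry)
  for (i in seq_len(k)) values <- as.matrix(S %*% values)
  if (is_set) {
    map$values <- values
    map
  } else if (is.matrix(map)) values else as.vector(values)
}

smoothing_iterations <- function(fwhm_mm, spacing_mm, degree = 4) {
  sigma2 <- fwhm_mm^2 / (8 * log(2))
  step_var <- 2 * spacing_mm^2 / (degree + 1)
  max(0L, as.integer(round(sigma2 / step_var)))
}

averaging_operator <- function(geometry) {
  adj <- geometry$surface$adjacency
  nv <- geometry$surface$n_vertices
  deg <- lengths(adj)
  i <- c(seq_len(nv), rep.int(seq_len(nv), deg))
  j <- c(seq_len(nv), unlist(adj, use.names = FALSE))
  w <- 1 / (deg + 1)
  x <- c(w, rep.int(w, deg))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nv, nv))
}
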