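# Toy analysis geometry: a periodic grid-graph standing in for the cortical
# surface mesh, and a sparse voxel subset of a small 3-D grid standing in for
# the white-matter skeleton.

#' Build the desk-scale analysis geometry
#'
#' The surface is an `nx x ny` grid-graph (4-neighbour connectivity) with a
#' fixed vertex spacing in mm; with `closed = TRUE` (the default) opposite
#' edges are identified (a torus), so every vertex has degree 4 and
#' neighbour-averaging is mass-preserving. The skeleton is a set of unique
#' voxel indices inside a small 3-D grid, emulating a TBSS tract skeleton.
#'
#' @param surface_dims Integer pair `c(nx, ny)`; the surface has `nx * ny`
#'   vertices. Default `c(50, 40)` (2,000 vertices).
#' @param vertex_spacing_mm Distance between neighbouring vertices (mm).
#' @param closed Logical; periodic (toroidal) surface connectivity.
#' @param grid_shape Integer triple, the skeleton's bounding voxel grid.
#' @param voxel_size_mm Isotropic voxel edge length (mm).
#' @param n_skeleton Number of skeleton voxels to place in the grid
#'   (deterministic thinning of a central slab).
#' @return An object of class `wmap_geometry`: list with `surface`
#'   (`n_vertices`, `dims`, `spacing_mm`, `adjacency` neighbour lists,
#'   `closed`) and `skeleton` (`grid_shape`, `voxel_size_mm`, `index`
#'   1-based linear voxel indices, `n_voxels`).
#' @export
toy_geometry <- function(surface_dims = c(50L, 40L),
                         vertex_spacing_mm = 3,
                         closed = TRUE,
                         grid_shape = c(20L, 20L, 20L),
                         voxel_size_mm = 2,
                         n_skeleton = 1500L) {
  surface_dims <- as.integer(surface_dims)
  grid_shape <- as.integer(grid_shape)
  if (length(surface_dims) != 2L || any(surface_dims < 1L)) {
    config_error("'surface_dims' must be two positive integers")
  }
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    config_error("'grid_shape' must be three positive integers")
  }
  check_scalar_number(vertex_spacing_mm, "vertex_spacing_mm", min = 1e-9)
  check_scalar_number(voxel_size_mm, "voxel_size_mm", min = 1e-9)
  nvox <- prod(grid_shape)
  if (n_skeleton < 1L || n_skeleton > nvox) {
    config_error("'n_skeleton' must be between 1 and prod(grid_shape)")
  }

  adjacency <- grid_adjacency(surface_dims[1], surface_dims[2], closed)

  # Skeleton: every k-th voxel of a central slab, a deterministic sparse
  # subset resembling a sheet of tract centres.
  zmid <- seq.int(max(1L, floor(grid_shape[3] / 3)),
                  min(grid_shape[3], ceiling(2 * grid_shape[3] / 3)))
  slab <- which(array(slice.index(array(0, grid_shape), 3) %in% zmid, grid_shape))
  if (length(slab) < n_skeleton) slab <- seq_len(nvox)
  pick <- slab[round(seq(1, length(slab), length.out = n_skeleton))]
  index <- sort(unique(as.integer(pick)))

  structure(list(
    surface = list(n_vertices = prod(surface_dims), dims = surface_dims,
                   spacing_mm = vertex_spacing_mm, adjacency = adjacency,
                   closed = closed),
    skeleton = list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                    index = index, n_voxels = length(index))
  ), class = "wmap_geometry")
}

# Neighbour lists of an nx x ny grid-graph, 4-connectivity, optionally toroidal.
grid_adjacency <- function(nx, ny, closed) {
  id <- function(i, j) (j - 1L) * nx + i
  adj <- vector("list", nx * ny)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      nb <- integer(0)
      if (closed) {
        nb <- c(id(if (i == 1L) nx else i - 1L, j),
                id(if (i == nx) 1L else i + 1L, j),
                id(i, if (j == 1L) ny else j - 1L),
                id(i, if (j == ny) 1L else j + 1L))
        if (nx == 1L || ny == 1L) nb <- unique(nb[nb != id(i, j)])
      } else {
        if (i > 1L) nb <- c(nb, id(i - 1L, j))
        if (i < nx) nb <- c(nb, id(i + 1L, j))
        if (j > 1L) nb <- c(nb, id(i, j - 1L))
        if (j < ny) nb <- c(nb, id(i, j + 1L))
      }
      adj[[id(i, j)]] <- sort(nb)
    }
  }
  adj
}

n_locations <- function(geometry, space) {
  switch(space,
         surface = geometry$surface$n_vertices,
         skeleton = geometry$skeleton$n_voxels,
         config_error(sprintf("unknown space '%s'", space)))
}

validate_geometry <- function(geometry) {
  if (!inherits(geometry, "wmap_geometry")) {
    config_error("'geometry' must be created by toy_geometry()")
  }
  adj <- geometry$surface$adjacency
  for (v in seq_along(adj)) {
    for (u in adj[[v]]) {
      if (!(v %in% adj[[u]])) config_error("surface adjacency is not symmetric")
    }
  }
  idx <- geometry$skeleton$index
  if (anyDuplicated(idx) ||
      any(idx < 1L) || any(idx > prod(geometry$skeleton$grid_shape))) {
    config_error("skeleton voxel indices must be unique and inside the grid")
  }
  invisible(geometry)
}

# Rectangular membership mask for planting localized effects: a block of the
# surface grid, or a box in skeleton-index space.
#' Logical mask for a rectangular region of the geometry
#'
#' Convenience selector used to plant localized group effects and to check
#' their recovery: on the surface a block of grid coordinates, on the
#' skeleton a contiguous run of skeleton voxels.
#'
#' @param geometry A `wmap_geometry`.
#' @param space `"surface"` or `"skeleton"`.
#' @param x_range,y_range Inclusive grid-coordinate ranges (surface).
#' @param frac_range For skeleton space, the inclusive range of the skeleton
#'   index as a fraction of its length, e.g. `c(0.4, 0.6)`.
#' @return Logical vector over the locations of `space`.
#' @export
region_mask <- function(geometry, space = c("surface", "skeleton"),
                        x_range = NULL, y_range = NULL, frac_range = NULL) {
  space <- match.arg(space)
  if (space == "surface") {
    d <- geometry$surface$dims
    if (is.null(x_range)) x_range <- c(1L, d[1])
    if (is.null(y_range)) y_range <- c(1L, d[2])
    i <- rep(seq_len(d[1]), times = d[2])
    j <- rep(seq_len(d[2]), each = d[1])
    i >= x_range[1] & i <= x_range[2] & j >= y_range[1] & j <= y_range[2]
  } else {
    n <- geometry$skeleton$n_voxels
    if (is.null(frac_range)) frac_range <- c(0, 1)
    k <- seq_len(n)
    k >= max(1, ceiling(frac_range[1] * n)) & k <= floor(frac_range[2] * n)
  }
}
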