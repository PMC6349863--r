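# File formats. Covariates and surface maps travel as CSV (comma-separated,
# header row, UTF-8, '.' decimal); volumes (lesion masks, skeleton FA/MD
# maps, stat volumes) as NIfTI-1 with the skeleton index stored as a
# companion binary mask volume; models and summaries as JSON + CSV. Voxel
# order follows the NIfTI data layout (fastest-varying first); all indices
# in files are written 1-based as in R.

#' Read / write the covariate table
#'
#' CSV with header `subject_id, group, age, sex, icv`; `sex` coded 0 = male,
#' 1 = female.
#'
#' @param covariates Covariate data.frame.
#' @param path CSV path.
#' @return `read_covariates` returns the validated data.frame.
#' @export
write_covariates <- function(covariates, path) {
  validate_covariates(covariates)
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) data_error(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_covariates(df)
  df
}

#' Read / write surface map sets
#'
#' One CSV (rows = vertices, one column per subject) plus a JSON sidecar
#' carrying modality, space and the surface geometry summary; the sidecar
#' path is the CSV path with extension `.json`.
#'
#' @param maps A surface [map_set()].
#' @param path CSV path.
#' @param geometry Geometry used to validate on read.
#' @return `read_surface_maps` returns a [map_set()].
#' @export
write_surface_maps <- function(maps, path) {
  if (maps$space != "surface") data_error("write_surface_maps() needs surface maps")
  df <- as.data.frame(maps$values)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(list(modality = maps$modality, space = maps$space,
                            n_vertices = maps$n_locations,
                            subjects = maps$subject_id),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface_maps
#' @export
read_surface_maps <- function(path, geometry) {
  if (!file.exists(path)) data_error(sprintf("no such file: %s", path))
  sidecar <- sub("\\.[^.]+$", ".json", path)
  if (!file.exists(sidecar)) data_error(sprintf("missing JSON sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) != geometry$surface$n_vertices) {
    data_error(sprintf("surface CSV has %d rows, geometry %d vertices (%s)",
                       nrow(df), geometry$surface$n_vertices, path))
  }
  map_set(as.matrix(df), meta$subjects, meta$modality, "surface", geometry)
}

#' Read / write skeleton map sets as NIfTI volumes
#'
#' Skeleton values are scattered into the full grid (zero elsewhere) and
#' written as a 4-D NIfTI (x, y, z, subject); the skeleton index is written
#' once as a companion binary mask volume `<stem>_skeleton_mask.nii.gz`.
#'
#' @param maps A skeleton [map_set()].
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @param geometry Geometry (grid shape, skeleton index, voxel size).
#' @return `read_skeleton_maps` returns a [map_set()].
#' @export
write_skeleton_maps <- function(maps, path, geometry) {
  if (maps$space != "skeleton") data_error("write_skeleton_maps() needs skeleton maps")
  gs <- geometry$skeleton$grid_shape
  idx <- geometry$skeleton$index
  n <- length(maps$subject_id)
  arr <- array(0, dim = c(gs, n))
  for (k in seq_len(n)) {
    vol <- numeric(prod(gs)); vol[idx] <- maps$values[, k]
    arr[, , , k] <- array(vol, gs)
  }
  write_nifti_array(arr, path, geometry)
  mask <- numeric(prod(gs)); mask[idx] <- 1
  write_nifti_array(array(mask, gs), skeleton_mask_path(path), geometry)
  meta <- list(modality = maps$modality, space = "skeleton",
               subjects = maps$subject_id)
  jsonlite::write_json(meta, paste0(strip_nii(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_skeleton_maps
#' @export
read_skeleton_maps <- function(path, geometry) {
  if (!file.exists(path)) data_error(sprintf("no such file: %s", path))
  arr <- RNifti::readNifti(path)
  gs <- geometry$skeleton$grid_shape
  if (!identical(as.integer(dim(arr)[1:3]), gs)) {
    data_error(sprintf("grid shape %s in %s does not match geometry %s",
                       paste(dim(arr)[1:3], collapse = "x"), path,
                       paste(gs, collapse = "x")))
  }
  meta <- jsonlite::read_json(paste0(strip_nii(path), ".json"),
                              simplifyVector = TRUE)
  n <- if (length(dim(arr)) == 4L) dim(arr)[4] else 1L
  idx <- geometry$skeleton$index
  vals <- vapply(seq_len(n), function(k) {
    vol <- if (length(dim(arr)) == 4L) arr[, , , k] else arr
    as.vector(vol)[idx]
  }, numeric(length(idx)))
  map_set(vals, meta$subjects, meta$modality, "skeleton", geometry)
}

skeleton_mask_path <- function(path) paste0(strip_nii(path), "_skeleton_mask.nii.gz")
strip_nii <- function(path) sub("\\.nii(\\.gz)?$", "", path)

write_nifti_array <- function(arr, path, geometry) {
  attr(arr, "pixdim") <- rep(geometry$skeleton$voxel_size_mm, length(dim(arr)))
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write lesion mask stacks as a 4-D NIfTI
#'
#' Values must be exactly 0/1; a non-binary voxel aborts the read with the
#' voxel and subject identified.
#'
#' @param masks A [lesion_masks()] stack.
#' @param path NIfTI path.
#' @param geometry Geometry with the matching grid.
#' @return `read_lesion_masks` returns a [lesion_masks()].
#' @export
write_lesion_masks <- function(masks, path, geometry) {
  gs <- masks$grid_shape
  arr <- array(masks$values, dim = c(gs, ncol(masks$values)))
  write_nifti_array(arr, path, geometry)
  jsonlite::write_json(list(subjects = masks$subject_id),
                       paste0(strip_nii(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lesion_masks
#' @export
read_lesion_masks <- function(path, geometry) {
  if (!file.exists(path)) data_error(sprintf("no such file: %s", path))
  arr <- RNifti::readNifti(path)
  gs <- geometry$skeleton$grid_shape
  if (!identical(as.integer(dim(arr)[1:3]), gs)) {
    data_error(sprintf("mask grid %s does not match geometry %s (%s)",
                       paste(dim(arr)[1:3], collapse = "x"),
                       paste(gs, collapse = "x"), path))
  }
  meta <- jsonlite::read_json(paste0(strip_nii(path), ".json"),
                              simplifyVector = TRUE)
  n <- if (length(dim(arr)) == 4L) dim(arr)[4] else 1L
  vals <- matrix(as.vector(arr), nrow = prod(gs), ncol = n)
  lesion_masks(vals, meta$subjects, geometry)
}

#' Read / write a fitted normative model
#'
#' JSON header (modality, space, n, df, tolerance) plus a CSV of
#' per-location coefficients, residual SD and degeneracy flags.
#'
#' @param model A `normative_model`.
#' @param dir Output directory (created if needed).
#' @return `read_normative_model` returns the model.
#' @export
write_normative_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- model[c("n_controls", "df", "rank", "modality", "space",
                    "sd_tol", "dropped", "control_ids")]
  jsonlite::write_json(header, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- data.frame(t(model$coef), sigma = model$sigma,
                    degenerate = as.integer(model$degenerate))
  names(tab)[1:4] <- c("intercept", "age", "sex", "icv")
  utils::write.csv(tab, file.path(dir, "coefficients.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(dir) {
  hpath <- file.path(dir, "model.json")
  cpath <- file.path(dir, "coefficients.csv")
  if (!file.exists(hpath) || !file.exists(cpath)) {
    data_error(sprintf("not a model directory: %s", dir))
  }
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  tab <- utils::read.csv(cpath)
  model <- list(coef = t(as.matrix(tab[, c("intercept", "age", "sex", "icv")])),
                sigma = tab$sigma, degenerate = tab$degenerate == 1L,
                n_controls = header$n_controls, df = header$df,
                rank = header$rank, dropped = header$dropped,
                modality = header$modality, space = header$space,
                sd_tol = header$sd_tol, control_ids = header$control_ids)
  rownames(model$coef) <- c("(Intercept)", "age", "sex", "icv")
  class(model) <- "normative_model"
  model
}

#' Write a stat map
#'
#' Skeleton/volume maps are written as paired NIfTI volumes (t and p, with
#' the corrected p where present); surface maps as a CSV pair. A JSON
#' summary records the correction, alpha, df and flag count.
#'
#' @param statmap A `stat_map`.
#' @param stem Output path stem (no extension).
#' @param geometry Geometry (needed for volume output).
#' @param location_index For skeleton-space maps, the skeleton voxel index.
#' @return Invisibly, the files written.
#' @export
write_statmap <- function(statmap, stem, geometry = NULL,
                          location_index = NULL) {
  files <- character(0)
  pvals <- statmap$p_corrected %||% statmap$p
  if (!is.null(statmap$grid_shape) || identical(statmap$space, "skeleton")) {
    gs <- statmap$grid_shape %||% geometry$skeleton$grid_shape
    tvol <- numeric(prod(gs)); pvol <- rep(1, prod(gs))
    idx <- if (identical(statmap$space, "skeleton")) {
      location_index %||% geometry$skeleton$index
    } else seq_len(prod(gs))
    tv <- statmap$t; tv[!is.finite(tv)] <- 0
    tvol[idx] <- tv
    pv <- pvals; pv[is.na(pv)] <- 1
    pvol[idx] <- pv
    f1 <- paste0(stem, "_t.nii.gz"); f2 <- paste0(stem, "_p.nii.gz")
    write_nifti_array(array(tvol, gs), f1, geometry)
    write_nifti_array(array(pvol, gs), f2, geometry)
    files <- c(f1, f2)
  } else {
    f1 <- paste0(stem, "_t.csv")
    utils::write.csv(data.frame(t = statmap$t, p = statmap$p,
                                p_corrected = pvals,
                                flag = as.integer(statmap$flag)),
                     f1, row.names = FALSE)
    files <- f1
  }
  summ <- list(correction = statmap$correction, alpha = statmap$alpha,
               df = statmap$df, n_flagged = sum(statmap$flag, na.rm = TRUE),
               n_included = sum(statmap$included), n = statmap$n)
  fj <- paste0(stem, "_summary.json")
  jsonlite::write_json(summ, fj, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fj))
}

#' Write / read a frequency map volume
#'
#' @param fmap A `frequency_map`.
#' @param path NIfTI path.
#' @param geometry Geometry.
#' @return `read_frequency_map` returns a `frequency_map` (group label and
#'   n restored from the JSON sidecar).
#' @export
write_frequency_map <- function(fmap, path, geometry) {
  write_nifti_array(array(fmap$prop, fmap$grid_shape), path, geometry)
  jsonlite::write_json(list(group = fmap$group, n_subjects = fmap$n_subjects),
                       paste0(strip_nii(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frequency_map
#' @export
read_frequency_map <- function(path, geometry) {
  arr <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(strip_nii(path), ".json"),
                              simplifyVector = TRUE)
  structure(list(prop = as.vector(arr), n_subjects = meta$n_subjects,
                 group = meta$group, grid_shape = as.integer(dim(arr))),
            class = "frequency_map")
}
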