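# Ground-truth effect structure for the synthetic cohort: per-modality
# covariate slopes, noise levels, localized additive group effects, and
# per-group lesion probability maps. Serialized alongside generated data so
# recovery tests read the truth back rather than re-deriving it.

#' Specify the generative truth for synthetic maps and lesions
#'
#' Maps are generated as
#' `value = baseline + beta_age*age + beta_sex*sex + beta_icv*icv +
#'  group_effect(location) + N(0, noise_sd)`,
#' with controls receiving zero group effect. Lesion masks are independent
#' voxelwise Bernoulli draws from the subject's group probability map.
#'
#' @param geometry A `wmap_geometry`.
#' @param modalities Named list; one entry per modality label with fields
#'   `space` ("surface"/"skeleton"), `baseline`, `betas` (named c(age, sex,
#'   icv)), `noise_sd` (> 0).
#' @param group_effects Named list `group -> modality -> numeric vector`
#'   (per-location additive shift) or a single number applied everywhere.
#'   Missing entries mean zero effect.
#' @param lesion_prob Named list `group -> per-voxel probability vector`
#'   over the full grid, or a single probability; values in \[0, 1\].
#' @return Object of class `effect_truth`.
#' @export
effect_truth <- function(geometry,
                         modalities = default_modalities(),
                         group_effects = list(),
                         lesion_prob = list()) {
  validate_geometry(geometry)
  for (m in names(modalities)) {
    mod <- modalities[[m]]
    if (is.null(mod$space) || !mod$space %in% c("surface", "skeleton")) {
      config_error(sprintf("modality '%s': bad or missing 'space'", m))
    }
    if (is.null(mod$noise_sd) || mod$noise_sd <= 0) {
      config_error(sprintf("modality '%s': 'noise_sd' must be > 0", m))
    }
    if (is.null(mod$betas) ||
        !all(c("age", "sex", "icv") %in% names(mod$betas))) {
      config_error(sprintf("modality '%s': 'betas' must name age, sex, icv", m))
    }
  }
  for (g in names(group_effects)) {
    for (m in names(group_effects[[g]])) {
      if (!m %in% names(modalities)) {
        config_error(sprintf("group_effects['%s'] names unknown modality '%s'", g, m))
      }
      eff <- group_effects[[g]][[m]]
      L <- n_locations(geometry, modalities[[m]]$space)
      if (!length(eff) %in% c(1L, L)) {
        config_error(sprintf(
          "group_effects['%s']['%s'] length %d does not match %d locations",
          g, m, length(eff), L))
      }
    }
  }
  nvox <- prod(geometry$skeleton$grid_shape)
  for (g in names(lesion_prob)) {
    p <- lesion_prob[[g]]
    if (any(p < 0) || any(p > 1)) {
      config_error(sprintf("lesion_prob['%s'] has probabilities outside [0,1]", g))
    }
    if (!length(p) %in% c(1L, nvox)) {
      config_error(sprintf("lesion_prob['%s'] length %d does not match %d voxels",
                           g, length(p), nvox))
    }
  }
  structure(list(geometry = geometry, modalities = modalities,
                 group_effects = group_effects, lesion_prob = lesion_prob),
            class = "effect_truth")
}

#' Default generative parameters for the three imaging modalities
#'
#' Cortical thickness in mm (baseline 2.5, thinning ~0.005 mm/yr), FA
#' (unitless, baseline 0.45) and MD (1e-3 mm^2/s units, baseline 0.80,
#' rising with age), each with a small ICV slope and Gaussian noise.
#'
#' @return Named list usable as the `modalities` argument of [effect_truth()].
#' @export
default_modalities <- function() {
  list(
    thickness = list(space = "surface", baseline = 2.5,
                     betas = c(age = -0.005, sex = 0.02, icv = 1e-7),
                     noise_sd = 0.1),
    FA = list(space = "skeleton", baseline = 0.45,
              betas = c(age = -0.001, sex = 0.005, icv = 2e-8),
              noise_sd = 0.02),
    MD = list(space = "skeleton", baseline = 0.80,
              betas = c(age = 0.002, sex = -0.005, icv = -2e-8),
              noise_sd = 0.03)
  )
}

truth_group_effect <- function(truth, group, modality) {
  L <- n_locations(truth$geometry, truth$modalities[[modality]]$space)
  eff <- truth$group_effects[[group]][[modality]]
  if (is.null(eff)) return(rep(0, L))
  if (length(eff) == 1L) rep(eff, L) else eff
}

#' Write / read the effect truth as JSON
#'
#' @param truth An `effect_truth`.
#' @param path JSON file path.
#' @return `read_truth_json` returns the per-location fields as plain lists
#'   (geometry is not round-tripped; pass it separately when rebuilding).
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    modalities = truth$modalities,
    group_effects = truth$group_effects,
    lesion_prob = truth$lesion_prob,
    geometry = list(surface_dims = truth$geometry$surface$dims,
                    grid_shape = truth$geometry$skeleton$grid_shape,
                    n_skeleton = truth$geometry$skeleton$n_voxels)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
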