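# Generators for per-subject scalar maps, WMH lesion masks and regional PET
# uptake tables, all pure functions of (cohort, truth, seed).

#' Generate per-subject scalar maps for one modality
#'
#' Implements the linear-Gaussian structure the normative model assumes:
#' per location, `baseline + X beta + group_effect + N(0, noise_sd)`, with
#' controls receiving zero group effect.
#'
#' @param cohort Covariate table from [generate_cohort()].
#' @param truth An [effect_truth()].
#' @param modality Modality label present in `truth$modalities`.
#' @param seed Integer seed.
#' @return A [map_set()] with one column per cohort row.
#' @export
generate_scalar_maps <- function(cohort, truth, modality, seed = 1L) {
  validate_covariates(cohort)
  if (nrow(cohort) == 0L) data_error("cohort is empty")
  mod <- truth$modalities[[modality]]
  if (is.null(mod)) {
    config_error(sprintf("modality '%s' is absent from the effect truth", modality))
  }
  geometry <- truth$geometry
  L <- n_locations(geometry, mod$space)
  n <- nrow(cohort)
  X <- cbind(cohort$age, cohort$sex, cohort$icv)
  fixed <- mod$baseline + as.vector(X %*% mod$betas[c("age", "sex", "icv")])
  values <- with_seed(seed, {
    noise <- matrix(rnorm(L * n, 0, mod$noise_sd), nrow = L, ncol = n)
    v <- sweep(noise, 2, fixed, "+")
    for (g in unique(cohort$group)) {
      if (g == "control") next
      eff <- truth_group_effect(truth, g, modality)
      idx <- which(cohort$group == g)
      v[, idx] <- v[, idx] + eff
    }
    v
  })
  if (modality == "FA") values <- pmin(pmax(values, 0), 1)
  if (modality %in% c("MD", "thickness")) values <- pmax(values, 0)
  map_set(values, cohort$subject_id, modality, mod$space, geometry)
}

#' Generate binary WMH lesion masks
#'
#' Voxelwise independent Bernoulli draws from each subject's group lesion
#' probability map over the full voxel grid.
#'
#' @inheritParams generate_scalar_maps
#' @return A [lesion_masks()] stack.
#' @export
generate_lesion_masks <- function(cohort, truth, seed = 1L) {
  validate_covariates(cohort)
  geometry <- truth$geometry
  nvox <- prod(geometry$skeleton$grid_shape)
  probs <- lapply(unique(cohort$group), function(g) {
    p <- truth$lesion_prob[[g]]
    if (is.null(p)) {
      config_error(sprintf("group '%s' has no lesion probability map", g))
    }
    if (length(p) == 1L) p <- rep(p, nvox)
    p
  })
  names(probs) <- unique(cohort$group)
  values <- with_seed(seed, {
    vapply(seq_len(nrow(cohort)), function(i) {
      rbinom(nvox, 1L, probs[[cohort$group[i]]])
    }, numeric(nvox))
  })
  lesion_masks(values, cohort$subject_id, geometry)
}

#' Optionally smooth a lesion probability map on the voxel grid
#'
#' Simple 6-neighbour box smoothing of a probability volume, iterated
#' `n_iter` times; values stay in \[0, 1\]. Off by default in the generator
#' (lesion voxels are drawn independently).
#'
#' @param prob Per-voxel probabilities over the full grid.
#' @param grid_shape Integer triple.
#' @param n_iter Number of smoothing passes.
#' @return Smoothed probability vector.
#' @export
smooth_lesion_prob <- function(prob, grid_shape, n_iter = 1L) {
  arr <- array(prob, dim = grid_shape)
  for (k in seq_len(n_iter)) {
    acc <- arr
    cnt <- array(1, dim = grid_shape)
    for (d in 1:3) for (s in c(-1L, 1L)) {
      sh <- shift_array(arr, d, s)
      ok <- !is.na(sh)
      acc[ok] <- acc[ok] + sh[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    arr <- acc / cnt
  }
  as.vector(pmin(pmax(arr, 0), 1))
}

shift_array <- function(arr, dim, by) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  src <- idx
  src[[dim]] <- idx[[dim]] - by
  out <- array(NA_real_, d)
  ok <- src[[dim]] >= 1 & src[[dim]] <= d[dim]
  tgt <- idx
  tgt[[dim]] <- idx[[dim]][ok]
  src[[dim]] <- src[[dim]][ok]
  out[tgt[[1]], tgt[[2]], tgt[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Generate a regional PET uptake table
#'
#' Draws, per subject, a global uptake ratio that is above 1.5 with the
#' group's intended probability, then constructs composite-region uptakes
#' whose mean over the composite divided by the cerebellar uptake equals
#' that ratio exactly.
#'
#' @param cohort Covariate table.
#' @param positive_fraction Named numeric vector, intended amyloid-positive
#'   fraction per group, each in \[0, 1\]; groups absent default to 0.
#' @param seed Integer seed.
#' @param regions Composite cortical region labels.
#' @return data.frame: `subject_id`, one uptake column per composite region,
#'   and `cerebellum`.
#' @export
generate_pet_table <- function(cohort, positive_fraction, seed = 1L,
                               regions = c("frontal", "parietal", "temporal",
                                           "posterior_cingulate")) {
  validate_covariates(cohort)
  if (any(positive_fraction < 0) || any(positive_fraction > 1)) {
    config_error("'positive_fraction' values must lie in [0, 1]")
  }
  n <- nrow(cohort)
  with_seed(seed, {
    frac <- unname(positive_fraction[match(cohort$group,
                                           names(positive_fraction))])
    frac[is.na(frac)] <- 0
    pos <- rbinom(n, 1L, frac) == 1L
    ratio <- ifelse(pos, runif(n, 1.55, 2.6), runif(n, 0.95, 1.45))
    cereb <- runif(n, 1.1, 1.6)
    uptake <- matrix(NA_real_, n, length(regions),
                     dimnames = list(NULL, regions))
    for (i in seq_len(n)) {
      f <- runif(length(regions), 0.85, 1.15)
      f <- f / mean(f)  # composite mean equals cereb * ratio exactly
      uptake[i, ] <- cereb[i] * ratio[i] * f
    }
    out <- data.frame(subject_id = cohort$subject_id, uptake,
                      cerebellum = cereb, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
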