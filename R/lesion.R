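# WMH lesion-frequency analysis: per-group frequency maps, voxelwise
# frequency comparison on the binary indicators, and the modified-Fazekas
# eligibility rule.

#' WMH frequency map of a group
#'
#' Voxelwise proportion of subjects with a lesion.
#'
#' @param masks A [lesion_masks()] stack (>= 1 subject).
#' @param group Optional group label stored with the map.
#' @return Object of class `frequency_map`: `prop` in \[0, 1\] per voxel,
#'   `n_subjects`, `group`, `grid_shape`.
#' @export
build_frequency_map <- function(masks, group = NA_character_) {
  if (!inherits(masks, "lesion_masks")) data_error("'masks' must be lesion_masks")
  if (ncol(masks$values) < 1L) data_error("need at least one mask")
  structure(list(prop = rowMeans(masks$values),
                 n_subjects = ncol(masks$values),
                 group = group,
                 grid_shape = masks$grid_shape),
            class = "frequency_map")
}

#' Voxelwise comparison of lesion frequency between two groups
#'
#' Per voxel, a pooled-variance two-sample t statistic on the 0/1 lesion
#' indicators, flagged where the two-sided p is below `alpha` (uncorrected).
#' Voxels whose combined stack is constant (lesioned in nobody, or in
#' everybody) carry no frequency information and are excluded. A voxel with
#' zero pooled variance but different group means (e.g. lesioned in all of
#' one group and none of the other) gets `t = +/-Inf`, `p = 0`.
#'
#' @param masksA,masksB [lesion_masks()] stacks on the same grid, >= 2
#'   subjects each.
#' @param alpha Uncorrected two-sided significance level (default 0.001).
#' @return Object of class `stat_map` with per-voxel `t`, `p`, `flag`
#'   (NA at excluded voxels), `included`, `df`, `alpha`,
#'   `correction = "none"`.
#' @export
compare_lesion_frequency <- function(masksA, masksB, alpha = 0.001) {
  if (!identical(masksA$grid_shape, masksB$grid_shape)) {
    data_error("lesion mask grids differ between groups")
  }
  nA <- ncol(masksA$values); nB <- ncol(masksB$values)
  if (nA < 2L || nB < 2L) {
    config_error("each group needs at least 2 subjects for the frequency comparison")
  }
  check_scalar_number(alpha, "alpha", min = 0, max = 1)
  A <- masksA$values; B <- masksB$values
  countA <- rowSums(A); countB <- rowSums(B)
  total <- countA + countB
  included <- total > 0 & total < nA + nB

  st <- pooled_t_rows(A, B)
  t <- ifelse(included, st$t, NA_real_)
  df <- nA + nB - 2L
  p <- 2 * pt(-abs(t), df)
  p[is.infinite(t)] <- 0
  flag <- p < alpha

  structure(list(t = t, p = p, flag = flag, included = included,
                 df = df, alpha = alpha, correction = "none",
                 contrast = c(masksA$subject_id[1], masksB$subject_id[1]),
                 n = c(nA, nB), grid_shape = masksA$grid_shape,
                 space = "volume"),
            class = "stat_map")
}

# Row-wise pooled two-sample t for location x subject matrices.
# Returns t (Inf where pooled variance is 0 but means differ, NaN where both
# are 0 and means agree) and the pooled variance.
pooled_t_rows <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums(A^2) - nA * mA^2
  ssB <- rowSums(B^2) - nB * mB^2
  vp <- (ssA + ssB) / (nA + nB - 2)
  vp <- pmax(vp, 0)                      # guard tiny negative rounding
  se <- sqrt(vp * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[se == 0 & mA == mB] <- NaN
  list(t = t, vp = vp, mA = mA, mB = mB)
}

#' Modified-Fazekas eligibility from WMH extents
#'
#' Radiologically measured maximal diameters of periventricular and deep
#' WMH (mm). SVCI-eligible requires periventricular >= 10 mm and deep >=
#' 25 mm; control-eligible requires periventricular < 10 mm and deep <
#' 10 mm; anything else is neither.
#'
#' @param periventricular_mm,deep_mm Non-negative extents in mm (vectorized).
#' @return Character vector: `"SVCI_eligible"`, `"control_eligible"` or
#'   `"neither"`.
#' @export
classify_fazekas <- function(periventricular_mm, deep_mm) {
  if (any(periventricular_mm < 0) || any(deep_mm < 0)) {
    data_error("WMH extents must be non-negative")
  }
  out <- rep("neither", length(periventricular_mm))
  out[periventricular_mm >= 10 & deep_mm >= 25] <- "SVCI_eligible"
  out[periventricular_mm < 10 & deep_mm < 10] <- "control_eligible"
  out
}
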