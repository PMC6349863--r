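# The normative W-score model. Per location, ordinary least squares of the
# control maps on (1, age, sex, ICV); a patient's W-score is the residual of
# their raw value from the control prediction, divided by the control
# residual SD:
#
#   W = (raw - predicted_from_controls) / SD(control residuals)
#
# W behaves like a Z-score in controls (mean 0, SD 1; +/-1.65 ~ the 95th/5th
# percentiles) but is adjusted for age, sex and ICV. The sign convention is
# kept raw-minus-predicted throughout, so positive W means larger thickness,
# larger FA, larger MD.

COVARIATES <- c("age", "sex", "icv")

#' Fit per-location normative regressions on controls
#'
#' @param control_maps A [map_set()] restricted to (or containing) control
#'   subjects; only subjects labelled `control` in `covariates` are used.
#' @param covariates Covariate table with a row for every control map.
#' @param sd_tol_scale Degeneracy tolerance: locations whose residual SD is
#'   below `sd_tol_scale` times the map value scale are flagged degenerate
#'   and masked downstream instead of producing unbounded W.
#' @return Object of class `normative_model`: per-location `coef` (4 x L:
#'   intercept, age, sex, icv), `sigma` (residual SD, denominator n - rank),
#'   `degenerate` flags, `n_controls`, `df`, `modality`, `space`.
#' @details The residual SD uses the df-adjusted denominator `n - 4`
#'   (intercept plus three covariates), so the in-sample W-score sample SD
#'   equals `sqrt((n - 4)/(n - 1))` exactly. If a covariate column is
#'   constant across controls (e.g. a single-sex control sample) it is
#'   dropped from the fit with a warning and its coefficient set to 0; the
#'   residual df then use the retained rank.
#' @export
fit_normative_model <- function(control_maps, covariates,
                                sd_tol_scale = 1e-8) {
  validate_covariates(covariates)
  ctrl <- covariates[covariates$group == "control", , drop = FALSE]
  ids <- intersect(control_maps$subject_id, ctrl$subject_id)
  missing_cov <- setdiff(control_maps$subject_id, covariates$subject_id)
  if (length(missing_cov) > 0) {
    data_error(sprintf("no covariate row for subject(s): %s",
                       paste(missing_cov, collapse = ", ")))
  }
  noncontrol <- setdiff(control_maps$subject_id, ctrl$subject_id)
  if (length(noncontrol) > 0) {
    data_error(sprintf("non-control subject(s) in control maps: %s",
                       paste(noncontrol, collapse = ", ")))
  }
  n <- length(ids)
  if (n < 6L) {
    config_error(sprintf("need at least 6 controls to fit the model, got %d", n))
  }
  maps <- subset_subjects(control_maps, ids)
  ctrl <- ctrl[match(ids, ctrl$subject_id), , drop = FALSE]

  X <- design_matrix(ctrl)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col) var(col) > 0))
  if (!all(keep)) {
    warning(sprintf("constant covariate column(s) dropped from normative fit: %s",
                    paste(colnames(X)[!keep], collapse = ", ")))
  }
  Xk <- X[, keep, drop = FALSE]
  qrX <- qr(Xk)
  Yt <- t(maps$values)                              # n x L
  cf <- qr.coef(qrX, Yt)                            # rank x L
  resid <- Yt - Xk %*% cf
  df <- n - qrX$rank
  sigma <- sqrt(colSums(resid^2) / df)

  coef_full <- matrix(0, nrow = ncol(X), ncol = ncol(Yt),
                      dimnames = list(colnames(X), NULL))
  coef_full[keep, ] <- cf

  scale <- max(mean(abs(maps$values)), .Machine$double.eps)
  degenerate <- sigma < sd_tol_scale * scale

  structure(list(coef = coef_full, sigma = sigma, degenerate = degenerate,
                 n_controls = n, df = df, rank = qrX$rank,
                 dropped = colnames(X)[!keep],
                 modality = maps$modality, space = maps$space,
                 sd_tol = sd_tol_scale * scale,
                 control_ids = ids),
            class = "normative_model")
}

design_matrix <- function(covariates) {
  cbind(`(Intercept)` = 1, age = covariates$age, sex = covariates$sex,
        icv = covariates$icv)
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %s (%s): %d locations, %d controls, df = %d, %d degenerate\n",
              x$modality, x$space, length(x$sigma), x$n_controls, x$df,
              sum(x$degenerate)))
  invisible(x)
}

predict_normative <- function(model, covariates) {
  X <- design_matrix(covariates)
  t(X %*% model$coef)                               # L x n
}

#' Compute W-score maps
#'
#' `W = (raw - predicted) / residual SD` at every non-degenerate location;
#' degenerate locations are masked (NA).
#'
#' @param maps A [map_set()] of subject maps (any group).
#' @param covariates Covariate rows for each subject in `maps`.
#' @param model A fitted [fit_normative_model()].
#' @return A `wscore_maps` object: `w` (L x n matrix, NA where masked),
#'   `masked` flags, plus subject/modality/space metadata.
#' @export
compute_wscore <- function(maps, covariates, model) {
  if (!inherits(model, "normative_model")) {
    config_error("'model' must be a normative_model")
  }
  if (maps$modality != model$modality || maps$space != model$space) {
    data_error(sprintf("modality/space mismatch: maps are %s/%s, model is %s/%s",
                       maps$modality, maps$space, model$modality, model$space))
  }
  if (maps$n_locations != length(model$sigma)) {
    data_error("location count mismatch between maps and model")
  }
  validate_covariates(covariates)
  cov <- covariates[match(maps$subject_id, covariates$subject_id), , drop = FALSE]
  if (anyNA(cov$subject_id)) {
    data_error(sprintf("no covariate row for subject(s): %s",
                       paste(setdiff(maps$subject_id, covariates$subject_id),
                             collapse = ", ")))
  }
  pred <- predict_normative(model, cov)
  w <- (maps$values - pred) / model$sigma
  w[model$degenerate, ] <- NA_real_
  colnames(w) <- maps$subject_id
  structure(list(w = w, masked = model$degenerate,
                 subject_id = maps$subject_id,
                 modality = maps$modality, space = maps$space),
            class = "wscore_maps")
}

#' @export
print.wscore_maps <- function(x, ...) {
  cat(sprintf("<wscore_maps> %s (%s): %d locations x %d subjects, %d masked\n",
              x$modality, x$space, nrow(x$w), ncol(x$w), sum(x$masked)))
  invisible(x)
}

#' In-sample (and held-out) W-score calibration
#'
#' For the controls the model was fitted on, OLS algebra fixes the
#' per-location W statistics exactly: the mean is 0 and the sample SD
#' (denominator n - 1) is `sqrt((n - rank)/(n - 1))` — slightly below 1
#' because fitted residuals absorb `rank` degrees of freedom. Held-out
#' controls from the same population have mean ~0 and SD ~1.
#'
#' @param model Fitted [fit_normative_model()].
#' @param control_maps The control [map_set()] (must include the fitting
#'   subjects for the in-sample part).
#' @param covariates Covariate table.
#' @param heldout_maps,heldout_covariates Optional held-out control maps.
#' @return List with `insample` (per-location `mean`, `sd`, and the exact
#'   `expected_sd`) and, when supplied, `heldout` (pooled `mean`, `sd`).
#' @export
control_calibration <- function(model, control_maps, covariates,
                                heldout_maps = NULL,
                                heldout_covariates = NULL) {
  maps <- subset_subjects(control_maps, model$control_ids)
  wm <- compute_wscore(maps, covariates, model)
  ok <- !wm$masked
  res <- list(insample = list(
    mean = rowMeans(wm$w),
    sd = apply(wm$w, 1, sd),
    expected_sd = sqrt((model$n_controls - model$rank) / (model$n_controls - 1))
  ))
  if (!is.null(heldout_maps)) {
    wh <- compute_wscore(heldout_maps, heldout_covariates, model)
    res$heldout <- list(mean = mean(wh$w[!wh$masked, ]),
                        sd = sd(as.vector(wh$w[!wh$masked, ])))
  }
  res$n_unmasked <- sum(ok)
  res
}

#' Global mean W-score per subject
#'
#' Mean W over non-masked locations (optionally restricted to an analysis
#' mask), the per-subject summary entering the global ANCOVA.
#'
#' @param wmaps A `wscore_maps` object.
#' @param mask Optional logical location mask.
#' @return Named numeric vector, one value per subject.
#' @export
global_mean_wscore <- function(wmaps, mask = NULL) {
  keep <- !wmaps$masked
  if (!is.null(mask)) keep <- keep & mask
  colMeans(wmaps$w[keep, , drop = FALSE])
}
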