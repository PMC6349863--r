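# Synthetic cohort generation: demographics with group-specific age/sex/ICV
# distributions, emulating a small-vessel-disease study design in which the
# monogenic (CADASIL-like) group is substantially younger than the sporadic
# (SVCI-like) groups.

#' Specify a synthetic cohort
#'
#' @param n_controls Number of cognitively normal controls (>= 1).
#' @param group_sizes Named integer vector, patients per group label.
#' @param age_mean_sd Named list mapping each group label (and `"control"`)
#'   to `c(mean, sd)` in years.
#' @param sex_proportion Named numeric vector, proportion of female subjects
#'   (coded 1) per group, each in \[0, 1\].
#' @param icv_mean_sd `c(mean, sd)` of intracranial volume in mm^3, shared by
#'   all groups.
#' @param seed Integer RNG seed; identical seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 56L,
                        group_sizes = c(typical_CADASIL = 11L,
                                        SVCI_with_variants = 15L,
                                        SVCI_without_variants = 101L),
                        age_mean_sd = list(control = c(68, 7),
                                           typical_CADASIL = c(57, 7),
                                           SVCI_with_variants = c(72, 8),
                                           SVCI_without_variants = c(74, 7)),
                        sex_proportion = c(control = 0.60,
                                           typical_CADASIL = 0.455,
                                           SVCI_with_variants = 0.60,
                                           SVCI_without_variants = 0.614),
                        icv_mean_sd = c(1.45e6, 1.3e5),
                        seed = 1L) {
  if (!is.numeric(n_controls) || length(n_controls) != 1L || n_controls < 1) {
    config_error("invalid cohort spec: 'n_controls' must be >= 1")
  }
  if (length(group_sizes) < 1L || is.null(names(group_sizes)) ||
      any(!nzchar(names(group_sizes))) || any(group_sizes < 1)) {
    config_error("invalid cohort spec: 'group_sizes' must be named counts >= 1")
  }
  groups <- c("control", names(group_sizes))
  for (g in groups) {
    ms <- age_mean_sd[[g]]
    if (is.null(ms) || length(ms) != 2L || ms[2] < 0) {
      config_error(sprintf("invalid cohort spec: 'age_mean_sd' missing or bad for group '%s'", g))
    }
    p <- sex_proportion[[g]]
    if (is.null(p) || is.na(p) || p < 0 || p > 1) {
      config_error(sprintf("invalid cohort spec: 'sex_proportion' for group '%s' must be in [0,1]", g))
    }
  }
  if (length(icv_mean_sd) != 2L || icv_mean_sd[1] <= 0 || icv_mean_sd[2] < 0) {
    config_error("invalid cohort spec: 'icv_mean_sd' must be c(mean > 0, sd >= 0)")
  }
  check_scalar_number(seed, "seed")
  structure(list(n_controls = as.integer(n_controls),
                 group_sizes = group_sizes,
                 age_mean_sd = age_mean_sd,
                 sex_proportion = sex_proportion,
                 icv_mean_sd = icv_mean_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a covariate table from a cohort specification
#'
#' Ages are drawn from each group's normal law, truncated below at 18 years
#' by redrawing; sex is Bernoulli (female = 1); ICV is normal. The result is
#' a deterministic function of the spec (including its seed).
#'
#' @param spec A `cohort_spec`.
#' @return A data.frame with columns `subject_id`, `group`, `age`, `sex`
#'   (0 = male, 1 = female), `icv` (mm^3).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    config_error("'spec' must be a cohort_spec")
  }
  groups <- c(control = spec$n_controls, spec$group_sizes)
  with_seed(spec$seed, {
    rows <- lapply(names(groups), function(g) {
      n <- as.integer(groups[[g]])
      ms <- spec$age_mean_sd[[g]]
      age <- rnorm_trunc(n, ms[1], ms[2], lower = 18)
      sex <- rbinom(n, 1L, spec$sex_proportion[[g]])
      icv <- rnorm(n, spec$icv_mean_sd[1], spec$icv_mean_sd[2])
      data.frame(group = g, age = age, sex = sex, icv = icv,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

# Truncated-normal draw by redrawing values below `lower`; degenerate sd = 0
# returns the mean (clamped at lower).
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

validate_covariates <- function(covariates) {
  need <- c("subject_id", "group", "age", "sex", "icv")
  miss <- setdiff(need, names(covariates))
  if (length(miss) > 0) {
    data_error(sprintf("covariate table missing column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(covariates$subject_id)) {
    data_error("covariate table has duplicated subject_id values")
  }
  if (any(covariates$age <= 0) || any(covariates$icv <= 0) ||
      !all(covariates$sex %in% c(0, 1))) {
    data_error("covariates out of range: need age > 0, icv > 0, sex in {0,1}")
  }
  invisible(covariates)
}
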