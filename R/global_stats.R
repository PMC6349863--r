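# Global-mean statistics: ANCOVA on per-subject global W with age/sex
# adjustment and Bonferroni post hoc pairwise contrasts, plus the
# distributional checks (Lilliefors-corrected Kolmogorov-Smirnov normality,
# Bartlett variance homogeneity).

#' Global-mean ANCOVA with Bonferroni post hoc contrasts
#'
#' Fits `value ~ age + sex + group`, reports the F test for the group
#' factor (added last) and all pairwise group contrasts from the adjusted
#' model, each with its raw p multiplied by the number of comparisons
#' (capped at 1).
#'
#' @param values Per-subject global mean W-scores (numeric).
#' @param groups Group labels (>= 2 levels; F test needs >= 2).
#' @param age,sex Covariates, same length as `values`.
#' @return List: `F`, `p` (group factor), `df`, `pairwise` data.frame
#'   (`contrast`, `estimate`, `t`, `p_raw`, `p_bonferroni`), `n_comparisons`,
#'   and the fitted `model`.
#' @export
global_ancova <- function(values, groups, age, sex) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) config_error("need at least 2 groups")
  dat <- data.frame(value = values, group = groups, age = age, sex = sex)
  if (anyNA(dat)) data_error("ANCOVA inputs contain missing values")
  fit0 <- lm(value ~ age + sex, data = dat)
  fit1 <- lm(value ~ age + sex + group, data = dat)
  if (fit1$rank < 2 + nlevels(groups)) {
    data_error(sprintf(
      "singular ANCOVA design (rank %d < %d); check group/covariate confounding",
      fit1$rank, 2 + nlevels(groups)))
  }
  an <- anova(fit0, fit1)
  Fg <- an$F[2]; pg <- an$`Pr(>F)`[2]

  lev <- levels(groups)
  pairs <- combn(lev, 2, simplify = FALSE)
  m <- length(pairs)
  V <- vcov(fit1)
  cf <- coef(fit1)
  dfres <- fit1$df.residual
  rows <- lapply(pairs, function(pr) {
    # contrast: mean(pr[2]) - mean(pr[1]) at fixed covariates
    cvec <- setNames(rep(0, length(cf)), names(cf))
    for (s in c(1, -1)) {
      g <- pr[if (s == 1) 2 else 1]
      nm <- paste0("group", g)
      if (nm %in% names(cvec)) cvec[nm] <- cvec[nm] + s
    }
    est <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    praw <- 2 * pt(-abs(tval), dfres)
    data.frame(contrast = paste(pr[2], "-", pr[1]), estimate = est,
               t = tval, p_raw = praw,
               p_bonferroni = min(1, m * praw),
               stringsAsFactors = FALSE)
  })
  list(F = Fg, p = pg, df = c(an$Df[2], dfres),
       pairwise = do.call(rbind, rows), n_comparisons = m, model = fit1)
}

#' Normality check of W-scores
#'
#' Kolmogorov-Smirnov test with estimated mean and SD using the Lilliefors
#' null (`nortest::lillie.test`). Because W-scores are nominally
#' standardized, a plain KS test against N(0, 1) is also available via
#' `method = "ks_standard"`. A constant sample is maximally non-normal and
#' returns p = 0.
#'
#' @param values Numeric sample, n >= 5.
#' @param method `"lilliefors"` (default) or `"ks_standard"`.
#' @return The test p-value.
#' @export
check_normality <- function(values, method = c("lilliefors", "ks_standard")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 5L) {
    config_error("normality check needs at least 5 observations")
  }
  if (sd(values) == 0) return(0)
  if (method == "lilliefors") {
    nortest::lillie.test(values)$p.value
  } else {
    suppressWarnings(ks.test(values, "pnorm", 0, 1)$p.value)
  }
}

#' Bartlett test of equal variances across groups
#'
#' @param values Numeric vector, or a list of per-group numeric vectors.
#' @param groups Group labels (ignored when `values` is a list).
#' @return List with `statistic` (chi-square), `df`, `p`.
#' @export
check_variance_homogeneity <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    glist <- values
  } else {
    glist <- split(values, groups)
  }
  if (length(glist) < 2L) config_error("need at least 2 groups")
  sizes <- lengths(glist)
  if (any(sizes < 2L)) config_error("every group needs at least 2 observations")
  zero <- vapply(glist, function(g) var(g) == 0, logical(1))
  if (any(zero)) {
    data_error(sprintf("zero variance in group(s): %s",
                       paste(names(glist)[zero], collapse = ", ")))
  }
  bt <- bartlett.test(glist)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p = bt$p.value)
}
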