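# Mass-univariate group inference on W-score maps: uncorrected pooled-t
# contrasts, Benjamini-Hochberg FDR over surface vertices, and max-statistic
# permutation FWE over skeleton voxels.

#' Mass-univariate two-sample t contrast
#'
#' Per location, a pooled-variance two-sample t with `nA + nB - 2` df and a
#' two-sided p. Positive t means group A exceeds group B.
#'
#' @param wmapsA,wmapsB `wscore_maps` (or plain location x subject matrices)
#'   sharing space and location count; >= 2 subjects each.
#' @param mask Optional logical location mask; masked-out locations get NA.
#' @param alpha Significance level stored with the map (uncorrected flags).
#' @return Object of class `stat_map` with `t`, `p`, `flag`, `included`,
#'   `df`, `alpha`, `correction = "none"`.
#' @export
massuni_ttest <- function(wmapsA, wmapsB, mask = NULL, alpha = 0.05) {
  A <- extract_w(wmapsA); B <- extract_w(wmapsB)
  spA <- attr(A, "space"); spB <- attr(B, "space")
  if (!is.null(spA) && !is.null(spB) && !identical(spA, spB)) {
    data_error(sprintf("maps live in different spaces: %s vs %s", spA, spB))
  }
  if (nrow(A) != nrow(B)) data_error("location counts differ between groups")
  nA <- ncol(A); nB <- ncol(B)
  if (nA < 2L || nB < 2L) config_error("each group needs at least 2 subjects")
  included <- stats::complete.cases(A) & stats::complete.cases(B)
  if (!is.null(mask)) included <- included & mask

  st <- pooled_t_rows(A, B)
  t <- ifelse(included, st$t, NA_real_)
  t[included & is.nan(t)] <- 0           # zero variance, equal means
  df <- nA + nB - 2L
  p <- 2 * pt(-abs(t), df)
  p[is.infinite(t)] <- 0
  structure(list(t = t, p = p, flag = p < alpha, included = included,
                 df = df, alpha = alpha, correction = "none",
                 n = c(nA, nB), space = spA %||% "unknown"),
            class = "stat_map")
}

extract_w <- function(x) {
  if (inherits(x, "wscore_maps")) {
    out <- x$w
    attr(out, "space") <- x$space
    out
  } else as.matrix(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s-corrected, alpha = %g: %d/%d locations flagged\n",
              x$correction, x$alpha, sum(x$flag, na.rm = TRUE),
              sum(x$included)))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction of a stat map
#'
#' Step-up BH over the raw p-values of all included locations: flags are
#' set where the BH-adjusted p is at most `q`, equivalently for all
#' `p <= p_(k*)` with `k*` the largest `k` such that `p_(k) <= k q / m`.
#'
#' @param statmap A `stat_map` with raw p-values.
#' @param q FDR level (default 0.05).
#' @return The `stat_map` with `flag` replaced, `q_adjusted` added,
#'   `correction = "FDR"`, `alpha = q`.
#' @export
correct_fdr <- function(statmap, q = 0.05) {
  check_scalar_number(q, "q", min = 0, max = 1)
  p <- statmap$p
  idx <- which(statmap$included & !is.na(p))
  adj <- rep(NA_real_, length(p))
  adj[idx] <- p.adjust(p[idx], method = "BH")
  statmap$q_adjusted <- adj
  statmap$flag <- !is.na(adj) & adj <= q
  statmap$correction <- "FDR"
  statmap$alpha <- q
  statmap
}

#' Max-statistic permutation FWE correction
#'
#' Two-sample contrast with family-wise error control by the permutation
#' distribution of the maximum |t| over the mask. Group labels are permuted
#' at the subject level; per location the corrected p is
#' `(1 + #\{perm max |t| >= |t_obs|\}) / (n_perm + 1)`. When the number of
#' distinct group assignments `choose(nA + nB, nA)` is at most `n_perm`,
#' all assignments are enumerated instead and the corrected p is the exact
#' proportion `#\{max |t| >= |t_obs|\} / n_assignments` (the identity
#' assignment included).
#'
#' @inheritParams massuni_ttest
#' @param n_perm Number of random permutations (>= 1; default 5000).
#' @param seed Integer seed (required: permutation draws must be
#'   reproducible).
#' @param alpha FWE level; flags where corrected p < alpha.
#' @return A `stat_map` with `correction = "FWE"`, per-location
#'   `p_corrected`, the permutation `max_null` distribution, and `exact`
#'   indicating full enumeration.
#' @export
correct_fwe_permutation <- function(wmapsA, wmapsB, mask = NULL,
                                    n_perm = 5000L, seed, alpha = 0.05) {
  if (n_perm < 1L) config_error("'n_perm' must be >= 1")
  if (missing(seed)) config_error("'seed' is required for permutation inference")
  A <- extract_w(wmapsA); B <- extract_w(wmapsB)
  nA <- ncol(A); nB <- ncol(B); n <- nA + nB
  if (nA < 2L || nB < 2L) config_error("each group needs at least 2 subjects")
  obs <- massuni_ttest(A, B, mask = mask)
  idx <- which(obs$included)
  Y <- t(cbind(A, B)[idx, , drop = FALSE])            # n x L (subjects rows)
  tobs <- abs(obs$t[idx])

  # tolerance for ties: the observed statistic recomputed along the
  # permutation path can differ by ~1e-15, which must still count as >=
  tie_eps <- 1e-8
  n_total <- choose(n, nA)
  exact <- is.finite(n_total) && n_total <= n_perm
  if (exact) {
    assign_idx <- combn(n, nA)
    maxnull <- perm_max_t(Y, assign_idx, nA, nB)
    denom <- ncol(assign_idx)
    p_corr_in <- vapply(tobs, function(t0) {
      sum(maxnull >= t0 - tie_eps * max(1, t0)) / denom
    }, numeric(1))
  } else {
    assign_idx <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) sort(sample.int(n, nA)), integer(nA))
    })
    maxnull <- perm_max_t(Y, assign_idx, nA, nB)
    p_corr_in <- vapply(tobs, function(t0) {
      (1 + sum(maxnull >= t0 - tie_eps * max(1, t0))) / (n_perm + 1)
    }, numeric(1))
  }
  p_corr <- rep(NA_real_, length(obs$t))
  p_corr[idx] <- p_corr_in

  obs$p_corrected <- p_corr
  obs$flag <- !is.na(p_corr) & p_corr < alpha
  obs$correction <- "FWE"
  obs$alpha <- alpha
  obs$n_perm <- if (exact) ncol(assign_idx) else n_perm
  obs$exact <- exact
  obs$max_null <- maxnull
  obs
}

# Max |t| over locations for each column of assign_idx (subjects of group A),
# computed with matrix products in chunks to bound memory.
perm_max_t <- function(Y, assign_idx, nA, nB, chunk = 1024L) {
  n <- nrow(Y)
  tot <- colSums(Y)
  totsq <- colSums(Y^2)
  B <- ncol(assign_idx)
  out <- numeric(B)
  for (start in seq(1L, B, by = chunk)) {
    cols <- start:min(B, start + chunk - 1L)
    G <- matrix(0, length(cols), n)
    for (k in seq_along(cols)) G[k, assign_idx[, cols[k]]] <- 1
    S1 <- G %*% Y                      # group-A sums, chunk x L
    Q1 <- G %*% (Y^2)
    m1 <- S1 / nA
    m2 <- sweep(-S1, 2, tot, "+") / nB
    ss1 <- Q1 - nA * m1^2
    ss2 <- sweep(-Q1, 2, totsq, "+") - nB * m2^2
    vp <- pmax((ss1 + ss2) / (n - 2), 0)
    se <- sqrt(vp * (1 / nA + 1 / nB))
    tmat <- abs(m1 - m2) / se
    tmat[se == 0 & m1 == m2] <- 0
    out[cols] <- apply(tmat, 1, max)
  }
  out
}
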