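# Shared fixtures and independently-coded oracles. Oracles are deliberately
# written as plain scalar loops / textbook formulas, not by calling the
# package's own vectorized paths.

subset_wmap <- function(maps, ids) wscoremap:::subset_subjects(maps, ids)

tiny_geometry <- function(nx = 6, ny = 5, grid = c(6L, 6L, 6L),
                          n_skeleton = 40L) {
  toy_geometry(surface_dims = c(nx, ny), vertex_spacing_mm = 3,
               closed = TRUE, grid_shape = grid, voxel_size_mm = 2,
               n_skeleton = n_skeleton)
}

tiny_cohort <- function(n_controls = 20L, groups = c(A = 8L, B = 8L),
                        seed = 42L) {
  ams <- c(list(control = c(68, 7)),
           setNames(rep(list(c(70, 7)), length(groups)), names(groups)))
  sp <- c(control = 0.5, setNames(rep(0.5, length(groups)), names(groups)))
  cohort_spec(n_controls = n_controls, group_sizes = groups,
              age_mean_sd = ams, sex_proportion = sp, seed = seed)
}

# OLS via explicit normal equations, one location at a time
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  list(beta = as.vector(beta),
       sigma = sqrt(sum(resid^2) / (nrow(X) - ncol(X))))
}

# Pooled two-sample t, scalar formula
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Benjamini-Hochberg step-up, literal definition
oracle_bh_flags <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= (seq_len(m)) * q / m)
  flags <- rep(FALSE, m)
  if (length(ks) > 0) flags[o[seq_len(max(ks))]] <- TRUE
  flags
}

# Bartlett chi-square statistic, textbook closed form
oracle_bartlett <- function(groups) {
  k <- length(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  vi <- vapply(groups, var, numeric(1))
  sp2 <- sum((ni - 1) * vi) / (N - k)
  num <- (N - k) * log(sp2) - sum((ni - 1) * log(vi))
  C <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  num / C
}

# Exhaustive max-|t| permutation p-values for a two-group contrast
oracle_perm_fwe <- function(A, B) {
  n <- ncol(A) + ncol(B)
  nA <- ncol(A)
  Y <- cbind(A, B)
  L <- nrow(Y)
  tobs <- vapply(seq_len(L), function(l) {
    abs(oracle_pooled_t(A[l, ], B[l, ]))
  }, numeric(1))
  splits <- combn(n, nA)
  maxt <- apply(splits, 2, function(ia) {
    max(vapply(seq_len(L), function(l) {
      abs(oracle_pooled_t(Y[l, ia], Y[l, -ia]))
    }, numeric(1)))
  })
  vapply(tobs, function(t0) mean(maxt >= t0), numeric(1))
}

# Simple map builder: fixed control structure plus optional group shift
make_maps <- function(cohort, geometry, space = "surface",
                      modality = "thickness", baseline = 2.5,
                      betas = c(age = -0.005, sex = 0.02, icv = 1e-7),
                      noise_sd = 0.1, group_effects = list(), seed = 9L) {
  truth <- effect_truth(
    geometry,
    modalities = setNames(list(list(space = space, baseline = baseline,
                                    betas = betas, noise_sd = noise_sd)),
                          modality),
    group_effects = lapply(group_effects, function(e) setNames(list(e), modality)))
  generate_scalar_maps(cohort, truth, modality, seed = seed)
}
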