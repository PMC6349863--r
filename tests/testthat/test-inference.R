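# Mass-univariate contrasts, FDR, permutation FWE, global ANCOVA and
# distributional checks.

rand_w <- function(L, n, shift = 0, seed) {
  set.seed(seed)
  matrix(rnorm(L * n), L, n) + shift
}

test_that("massuni t: identical groups, orientation, and scalar oracle", {
  A <- rand_w(10, 5, seed = 1)
  sm <- massuni_ttest(A, A)
  expect_true(all(abs(sm$t) < 1e-12))
  expect_true(all(sm$p > 0.999999))

  B <- rand_w(10, 40, seed = 2)
  Ashift <- rand_w(10, 40, shift = 1, seed = 3)
  sm2 <- massuni_ttest(Ashift, B)
  expect_true(all(sm2$t > 0))               # positive t means A > B
  expect_true(all(sm2$p < 0.05))

  # small instance vs independent scalar implementation
  a <- rand_w(5, 4, seed = 4); b <- rand_w(5, 4, seed = 5)
  sm3 <- massuni_ttest(a, b)
  expect_equal(sm3$df, 6)
  for (l in 1:5) {
    t0 <- oracle_pooled_t(a[l, ], b[l, ])
    expect_equal(sm3$t[l], t0, tolerance = 1e-12)
    expect_equal(sm3$p[l], 2 * pt(-abs(t0), 6), tolerance = 1e-12)
  }
  expect_error(massuni_ttest(a[, 1, drop = FALSE], b),
               class = "wscoremap_config_error")
})

test_that("BH step-up: worked example and oracle equivalence", {
  p4 <- c(0.001, 0.002, 0.2, 0.9)
  sm <- list(p = p4, included = rep(TRUE, 4), t = rep(1, 4),
             flag = rep(FALSE, 4), df = 10, alpha = 0.05,
             correction = "none")
  class(sm) <- "stat_map"
  out <- correct_fdr(sm, q = 0.05)
  expect_equal(out$flag, c(TRUE, TRUE, FALSE, FALSE))

  allhalf <- sm; allhalf$p <- rep(0.5, 100)
  allhalf$included <- rep(TRUE, 100); allhalf$t <- rep(1, 100)
  expect_equal(sum(correct_fdr(allhalf, 0.05)$flag), 0)

  # exhaustive at length <= 3 on a coarse grid, randomized sweeps to length 8
  grid <- seq(0.01, 0.99, by = 0.07)
  for (m in 1:3) {
    combos <- as.matrix(expand.grid(rep(list(grid), m)))
    for (r in seq_len(nrow(combos))) {
      p <- as.numeric(combos[r, ])
      smx <- sm; smx$p <- p; smx$included <- rep(TRUE, m); smx$t <- rep(1, m)
      expect_equal(correct_fdr(smx, 0.05)$flag, oracle_bh_flags(p, 0.05))
    }
  }
  set.seed(20)
  for (r in 1:300) {
    m <- sample(2:8, 1)
    p <- round(runif(m), 2)
    p[p == 0] <- 0.01
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    smx <- sm; smx$p <- p; smx$included <- rep(TRUE, m); smx$t <- rep(1, m)
    expect_equal(correct_fdr(smx, q)$flag, oracle_bh_flags(p, q))
  }
})

test_that("FDR and FWE flags are subsets of uncorrected flags", {
  A <- rand_w(40, 8, shift = 0.8, seed = 6)
  B <- rand_w(40, 8, seed = 7)
  un <- massuni_ttest(A, B, alpha = 0.05)
  fdr <- correct_fdr(un, q = 0.05)
  fwe <- correct_fwe_permutation(A, B, n_perm = 500, seed = 3L, alpha = 0.05)
  expect_true(all(!fdr$flag | un$flag))
  expect_true(all(!fwe$flag | un$flag))
  expect_true(all(!fwe$flag | fdr$flag | un$flag))
})

test_that("identical groups give permutation corrected p of 1 everywhere", {
  A <- rand_w(12, 3, seed = 8)
  out <- correct_fwe_permutation(A, A, n_perm = 100, seed = 1L)
  expect_true(all(out$p_corrected == 1))
  expect_equal(sum(out$flag), 0)
})

test_that("3+3 subjects trigger full enumeration matching the exhaustive oracle", {
  A <- rand_w(6, 3, shift = 1.5, seed = 9)
  B <- rand_w(6, 3, seed = 10)
  out <- correct_fwe_permutation(A, B, n_perm = 100, seed = 2L)
  expect_true(out$exact)
  expect_equal(out$n_perm, 20)
  pc <- out$p_corrected
  expect_true(all(abs(pc * 20 - round(pc * 20)) < 1e-9))  # multiples of 1/20
  expect_equal(pc, oracle_perm_fwe(A, B), tolerance = 1e-12)
})

test_that("4+4 full enumeration matches the oracle and p bounds hold", {
  A <- rand_w(5, 4, shift = 1, seed = 11)
  B <- rand_w(5, 4, seed = 12)
  out <- correct_fwe_permutation(A, B, n_perm = 100, seed = 4L)
  expect_true(out$exact)
  expect_equal(out$p_corrected, oracle_perm_fwe(A, B), tolerance = 1e-12)

  big <- correct_fwe_permutation(rand_w(10, 10, shift = 1, seed = 13),
                                 rand_w(10, 10, seed = 14),
                                 n_perm = 199, seed = 5L)
  expect_false(big$exact)
  expect_true(all(big$p_corrected >= 1 / 200))
  expect_true(all(big$p_corrected <= 1))
  # monotone non-increasing in |t|
  o <- order(abs(big$t))
  expect_true(all(diff(big$p_corrected[o]) <= 1e-12))
  expect_error(correct_fwe_permutation(A, B, n_perm = 0, seed = 1L),
               class = "wscoremap_config_error")
  expect_error(correct_fwe_permutation(A, B, n_perm = 10),
               class = "wscoremap_config_error")
})

test_that("permutation inference is deterministic given the seed", {
  A <- rand_w(15, 9, shift = 0.5, seed = 15)
  B <- rand_w(15, 9, seed = 16)
  o1 <- correct_fwe_permutation(A, B, n_perm = 300, seed = 7L)
  o2 <- correct_fwe_permutation(A, B, n_perm = 300, seed = 7L)
  expect_identical(o1$p_corrected, o2$p_corrected)
  o3 <- correct_fwe_permutation(A, B, n_perm = 300, seed = 8L)
  expect_false(identical(o1$max_null, o3$max_null))
})

test_that("global ANCOVA: F equals the RSS oracle; Bonferroni multiplies", {
  set.seed(17)
  n <- 60
  g <- factor(rep(c("a", "b", "c"), each = n / 3))
  age <- rnorm(n, 70, 8); sex <- rbinom(n, 1, 0.5)
  y <- 0.3 * (g == "b") - 0.2 * (g == "c") - 0.01 * age + rnorm(n, 0, 0.5)
  res <- global_ancova(y, g, age, sex)

  X0 <- cbind(1, age, sex)
  X1 <- cbind(X0, g == "b", g == "c")
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  F_oracle <- ((rss(X0) - rss(X1)) / 2) / (rss(X1) / (n - 5))
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(F_oracle, 2, n - 5, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$n_comparisons, 3)
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, 3 * res$pairwise$p_raw))
  # worked multiplication: raw 0.02 with 3 comparisons -> 0.06
  expect_equal(min(1, 3 * 0.02), 0.06)
})

test_that("ANCOVA removes a group difference that is pure age confounding", {
  set.seed(18)
  reps <- 50
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- factor(rep(c("young", "old"), each = 25))
    age <- c(rnorm(25, 55, 3), rnorm(25, 75, 3))
    sex <- rbinom(50, 1, 0.5)
    y <- age + rnorm(50, 0, 1)      # group differs only through age
    ps[r] <- global_ancova(y, g, age, sex)$p
  }
  expect_gt(mean(ps > 0.05), 0.85)  # near-uniform p after adjustment
})

test_that("singular ANCOVA designs are diagnosed", {
  set.seed(22)
  g <- factor(rep(c("a", "b"), each = 5))
  y <- rnorm(10)
  # age exactly constant within group is collinear with the group factor
  age <- ifelse(g == "a", 60, 70)
  expect_error(global_ancova(y, g, age, rbinom(10, 1, 0.5)),
               class = "wscoremap_data_error")
  expect_error(global_ancova(y, factor(rep("a", 10)), rnorm(10), rep(0, 10)),
               class = "wscoremap_config_error")
})

test_that("normality check calibrates on normal and rejects exponential", {
  set.seed(19)
  pn <- replicate(60, check_normality(rnorm(1000)))
  expect_gte(mean(pn > 0.05), 0.9)
  pe <- replicate(30, check_normality(rexp(1000)))
  expect_gte(mean(pe < 0.05), 0.99)
  expect_equal(check_normality(rep(2, 10)), 0)
  expect_error(check_normality(rnorm(4)), class = "wscoremap_config_error")
  # plain KS variant against N(0,1)
  expect_gt(check_normality(qnorm(ppoints(200)), method = "ks_standard"), 0.9)
})

test_that("Bartlett test matches the closed form and its trivial cases", {
  x <- c(1.1, 2.3, 0.4, 1.9, 2.2)
  same <- check_variance_homogeneity(list(a = x, b = x))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  set.seed(21)
  gl <- list(a = rnorm(8, 0, 1), b = rnorm(12, 0, 2), c = rnorm(10, 0, 1.5))
  res <- check_variance_homogeneity(gl)
  expect_equal(res$statistic, oracle_bartlett(gl), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_error(check_variance_homogeneity(list(a = rep(1, 5), b = rnorm(5))),
               class = "wscoremap_data_error")
  expect_error(check_variance_homogeneity(list(a = rnorm(5))),
               class = "wscoremap_config_error")
})
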