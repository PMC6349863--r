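# Synthetic cohort, scalar map, lesion and PET generators.

test_that("cohort generation respects degenerate SDs and is deterministic", {
  spec <- cohort_spec(n_controls = 5L, group_sizes = c(g1 = 3L),
                      age_mean_sd = list(control = c(70, 0), g1 = c(60, 0)),
                      sex_proportion = c(control = 0, g1 = 1),
                      icv_mean_sd = c(1.4e6, 0), seed = 3L)
  ch <- generate_cohort(spec)
  expect_equal(ch$age[ch$group == "control"], rep(70, 5))
  expect_equal(ch$age[ch$group == "g1"], rep(60, 3))
  expect_equal(ch$sex, c(rep(0, 5), rep(1, 3)))
  expect_equal(ch$icv, rep(1.4e6, 8))

  s7a <- generate_cohort(cohort_spec(seed = 7L))
  s7b <- generate_cohort(cohort_spec(seed = 7L))
  expect_identical(s7a, s7b)
  s8 <- generate_cohort(cohort_spec(seed = 8L))
  expect_false(identical(s7a, s8))
})

test_that("invalid cohort specs fail with the offending field named", {
  expect_error(cohort_spec(n_controls = 0), class = "wscoremap_config_error")
  expect_error(cohort_spec(n_controls = 0), "n_controls")
  expect_error(cohort_spec(sex_proportion = c(control = 1.2,
                                              typical_CADASIL = 0.5,
                                              SVCI_with_variants = 0.5,
                                              SVCI_without_variants = 0.5)),
               "sex_proportion")
  expect_error(cohort_spec(age_mean_sd = list(control = c(68, -1),
                                              typical_CADASIL = c(57, 7),
                                              SVCI_with_variants = c(72, 8),
                                              SVCI_without_variants = c(74, 7))),
               "age_mean_sd")
})

test_that("group age means match the design over replicates (3 SE)", {
  # CADASIL-like 57 +/- 7 (n = 11), SVCI-like 74 +/- 7 (n = 101)
  reps <- 500
  sums <- c(typical_CADASIL = 0, SVCI_without_variants = 0)
  spec0 <- cohort_spec(n_controls = 6L,
                       group_sizes = c(typical_CADASIL = 11L,
                                       SVCI_without_variants = 101L),
                       age_mean_sd = list(control = c(68, 7),
                                          typical_CADASIL = c(57, 7),
                                          SVCI_without_variants = c(74, 7)),
                       sex_proportion = c(control = 0.5,
                                          typical_CADASIL = 0.455,
                                          SVCI_without_variants = 0.614))
  for (r in seq_len(reps)) {
    spec0$seed <- 1000L + r
    ch <- generate_cohort(spec0)
    for (g in names(sums)) sums[g] <- sums[g] + mean(ch$age[ch$group == g])
  }
  # truncation at 18 is negligible at these means; SE of the mean of means
  se <- c(7 / sqrt(11 * reps), 7 / sqrt(101 * reps))
  expect_lt(abs(sums[1] / reps - 57), 3 * se[1])
  expect_lt(abs(sums[2] / reps - 74), 3 * se[2])
})

test_that("scalar maps follow the linear-Gaussian generative model", {
  geo <- tiny_geometry()
  spec <- cohort_spec(n_controls = 6L, group_sizes = c(g1 = 2L),
                      age_mean_sd = list(control = c(70, 5), g1 = c(60, 5)),
                      sex_proportion = c(control = 0.5, g1 = 0.5), seed = 2L)
  ch <- generate_cohort(spec)

  # near-zero noise, zero betas: every value is the baseline
  m0 <- make_maps(ch, geo, baseline = 2.5,
                  betas = c(age = 0, sex = 0, icv = 0), noise_sd = 1e-12)
  expect_equal(max(abs(m0$values - 2.5)), 0, tolerance = 1e-9)

  # linearity in age: difference between two subjects is beta_age * delta_age
  ch2 <- ch[1:2, ]; ch2$age <- c(60, 70); ch2$sex <- 0; ch2$icv <- 1.4e6
  ch2$group <- "control"
  m1 <- make_maps(ch2, geo, betas = c(age = -0.01, sex = 0, icv = 0),
                  noise_sd = 1e-12)
  expect_equal(m1$values[, 1] - m1$values[, 2], rep(0.1, geo$surface$n_vertices),
               tolerance = 1e-6)

  expect_error(generate_scalar_maps(ch, effect_truth(geo), "bogus"),
               class = "wscoremap_config_error")
})

test_that("generated betas are recovered by the normative fit within 3 SE", {
  geo <- tiny_geometry(10, 10, n_skeleton = 30L)
  spec <- cohort_spec(n_controls = 200L, group_sizes = c(g1 = 2L),
                      age_mean_sd = list(control = c(70, 8), g1 = c(60, 5)),
                      sex_proportion = c(control = 0.5, g1 = 0.5),
                      icv_mean_sd = c(1.45e6, 1.3e5), seed = 5L)
  ch <- generate_cohort(spec)
  truth_betas <- c(age = -0.005, sex = 0.02, icv = 1e-7)
  maps <- make_maps(ch, geo, betas = truth_betas, noise_sd = 0.1, seed = 11L)
  ctrl_ids <- ch$subject_id[ch$group == "control"]
  fit <- fit_normative_model(subset_wmap(maps, ctrl_ids), ch)
  ctrl <- ch[ch$group == "control", ]
  X <- cbind(1, ctrl$age, ctrl$sex, ctrl$icv)
  XtXi <- solve(t(X) %*% X)
  for (j in 2:4) {
    se_j <- sqrt(XtXi[j, j]) * 0.1
    dev <- abs(fit$coef[j, ] - truth_betas[j - 1])
    expect_lt(max(dev) / se_j, 5)          # per-location, 100 locations
    expect_lt(abs(mean(fit$coef[j, ]) - truth_betas[j - 1]), 3 * se_j)
  }
  expect_equal(mean(fit$sigma), 0.1, tolerance = 0.01)
})

test_that("lesion masks are Bernoulli draws from the group probability map", {
  geo <- tiny_geometry()
  nvox <- prod(geo$skeleton$grid_shape)
  spec <- cohort_spec(n_controls = 6L, group_sizes = c(g1 = 4L),
                      age_mean_sd = list(control = c(70, 5), g1 = c(60, 5)),
                      sex_proportion = c(control = 0.5, g1 = 0.5), seed = 4L)
  ch <- generate_cohort(spec)

  t0 <- effect_truth(geo, lesion_prob = list(control = 0, g1 = 0))
  expect_true(all(generate_lesion_masks(ch, t0, seed = 1L)$values == 0))
  t1 <- effect_truth(geo, lesion_prob = list(control = 1, g1 = 1))
  expect_true(all(generate_lesion_masks(ch, t1, seed = 1L)$values == 1))

  # binomial frequency check at p = 0.3, n = 1000 subjects
  big <- cohort_spec(n_controls = 1000L, group_sizes = c(g1 = 2L),
                     age_mean_sd = list(control = c(70, 5), g1 = c(60, 5)),
                     sex_proportion = c(control = 0.5, g1 = 0.5), seed = 6L)
  chb <- generate_cohort(big)
  pv <- rep(0, nvox); pv[17] <- 0.3
  tb <- effect_truth(geo, lesion_prob = list(control = pv, g1 = pv))
  mk <- generate_lesion_masks(chb[chb$group == "control", ], tb, seed = 8L)
  fhat <- mean(mk$values[17, ])
  expect_lt(abs(fhat - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  expect_true(all(mk$values[-17, ] == 0))

  bad <- effect_truth(geo)
  expect_error(generate_lesion_masks(ch, bad), class = "wscoremap_config_error")
  expect_error(effect_truth(geo, lesion_prob = list(control = 1.2)),
               class = "wscoremap_config_error")
})

test_that("PET tables hit the intended positivity fractions", {
  spec <- cohort_spec(n_controls = 6L, group_sizes = c(g1 = 101L),
                      age_mean_sd = list(control = c(70, 5), g1 = c(74, 7)),
                      sex_proportion = c(control = 0.5, g1 = 0.5), seed = 10L)
  ch <- generate_cohort(spec)
  p0 <- classify_pet_table(generate_pet_table(ch, c(control = 0, g1 = 0), seed = 1L))
  expect_true(all(!p0$positive))
  p1 <- classify_pet_table(generate_pet_table(ch, c(control = 1, g1 = 1), seed = 1L))
  expect_true(all(p1$positive))

  # mean positive rate over 500 replicates ~ 0.32 (Monte-Carlo error)
  reps <- 500; tot <- 0
  for (r in seq_len(reps)) {
    tab <- generate_pet_table(ch[ch$group == "g1", ],
                              c(g1 = 0.32), seed = 2000L + r)
    tot <- tot + sum(classify_pet_table(tab)$positive)
  }
  rate <- tot / (reps * 101)
  expect_lt(abs(rate - 0.32), 3 * sqrt(0.32 * 0.68 / (reps * 101)))
})

test_that("effect truth round-trips through its JSON serialization", {
  geo <- tiny_geometry()
  tr <- effect_truth(geo, group_effects = list(
    g1 = list(thickness = rep(c(0, -0.1), length.out = geo$surface$n_vertices))),
    lesion_prob = list(g1 = 0.2))
  path <- tempfile(fileext = ".json")
  write_truth_json(tr, path)
  back <- read_truth_json(path)
  expect_equal(back$modalities$thickness$noise_sd, 0.1)
  expect_equal(back$group_effects$g1$thickness,
               tr$group_effects$g1$thickness)
  expect_equal(back$lesion_prob$g1, 0.2)
})
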