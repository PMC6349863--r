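# Normative model fitting, W-score computation and calibration.

test_that("constant control maps give a fully degenerate model", {
  geo <- tiny_geometry()
  ch <- generate_cohort(tiny_cohort())
  ctrl <- ch[ch$group == "control", ]
  vals <- matrix(10, geo$surface$n_vertices, nrow(ctrl))
  maps <- map_set(vals, ctrl$subject_id, "thickness", "surface", geo)
  fit <- fit_normative_model(maps, ch)
  expect_equal(unname(fit$coef["(Intercept)", ]),
               rep(10, geo$surface$n_vertices), tolerance = 1e-9)
  expect_equal(max(abs(fit$coef[2:4, ])), 0, tolerance = 1e-9)
  expect_equal(max(fit$sigma), 0, tolerance = 1e-9)
  expect_true(all(fit$degenerate))
})

test_that("exact linear data recovers the slope to machine precision", {
  geo <- tiny_geometry()
  ch <- generate_cohort(tiny_cohort(n_controls = 20L))
  ctrl <- ch[ch$group == "control", ]
  vals <- matrix(rep(3.5 - 0.01 * ctrl$age, each = geo$surface$n_vertices),
                 geo$surface$n_vertices)
  maps <- map_set(vals, ctrl$subject_id, "thickness", "surface", geo)
  fit <- fit_normative_model(maps, ch)
  expect_equal(unname(fit$coef["age", ]), rep(-0.01, geo$surface$n_vertices),
               tolerance = 1e-10)
  expect_true(all(fit$degenerate))
})

test_that("fit matches the explicit normal-equations oracle per location", {
  geo <- tiny_geometry(5, 4)   # 20 locations
  ch <- generate_cohort(tiny_cohort(n_controls = 30L, seed = 12L))
  maps <- make_maps(ch, geo, noise_sd = 0.1, seed = 13L)
  ctrl_ids <- ch$subject_id[ch$group == "control"]
  fit <- fit_normative_model(subset_wmap(maps, ctrl_ids), ch)
  ctrl <- ch[match(ctrl_ids, ch$subject_id), ]
  X <- cbind(1, ctrl$age, ctrl$sex, ctrl$icv)
  Y <- subset_wmap(maps, ctrl_ids)$values
  for (l in seq_len(nrow(Y))) {
    o <- oracle_ols(X, Y[l, ])
    expect_equal(unname(fit$coef[, l]), o$beta, tolerance = 1e-8)
    expect_equal(fit$sigma[l], o$sigma, tolerance = 1e-10)
  }
})

test_that("fit preconditions and data errors are enforced", {
  geo <- tiny_geometry()
  ch <- generate_cohort(tiny_cohort(n_controls = 6L))
  maps <- make_maps(ch, geo)
  ctrl_ids <- ch$subject_id[ch$group == "control"]
  expect_error(fit_normative_model(subset_wmap(maps, ctrl_ids[1:5]), ch),
               class = "wscoremap_config_error")
  expect_error(fit_normative_model(subset_wmap(maps, ctrl_ids),
                                   ch[-1, , drop = FALSE]),
               regexp = ch$subject_id[1])
  # patient maps passed as controls
  expect_error(fit_normative_model(maps, ch), class = "wscoremap_data_error")
})

test_that("single-sex control sample drops the constant column with beta 0", {
  geo <- tiny_geometry()
  ch <- generate_cohort(tiny_cohort(n_controls = 20L))
  ch$sex[ch$group == "control"] <- 1
  maps <- make_maps(ch, geo, seed = 21L)
  ctrl_ids <- ch$subject_id[ch$group == "control"]
  expect_warning(fit <- fit_normative_model(subset_wmap(maps, ctrl_ids), ch),
                 "sex")
  expect_equal(max(abs(fit$coef["sex", ])), 0)
  expect_equal(fit$df, 20L - 3L)
})

test_that("W-scores equal (raw - prediction) / sd with masking", {
  geo <- tiny_geometry(4, 3)
  ch <- generate_cohort(tiny_cohort(n_controls = 25L, groups = c(A = 6L)))
  maps <- make_maps(ch, geo, seed = 31L)
  ctrl_ids <- ch$subject_id[ch$group == "control"]
  fit <- fit_normative_model(subset_wmap(maps, ctrl_ids), ch)
  pat <- subset_wmap(maps, ch$subject_id[ch$group == "A"])
  wm <- compute_wscore(pat, ch, fit)

  # brute-force per-location, per-subject scalar recomputation
  patcov <- ch[match(pat$subject_id, ch$subject_id), ]
  for (s in seq_along(pat$subject_id)) {
    x <- c(1, patcov$age[s], patcov$sex[s], patcov$icv[s])
    for (l in seq_len(pat$n_locations)) {
      expected <- (pat$values[l, s] - sum(x * fit$coef[, l])) / fit$sigma[l]
      expect_equal(wm$w[l, s], expected, tolerance = 1e-10)
    }
  }

  # subject equal to the model prediction everywhere -> w = 0
  pred <- wscoremap:::predict_normative(fit, patcov[1, , drop = FALSE])
  flat <- pat; flat$values <- pred; flat$subject_id <- pat$subject_id[1]
  flat$values <- matrix(pred, ncol = 1, dimnames = list(NULL, flat$subject_id))
  w0 <- compute_wscore(flat, ch, fit)
  expect_equal(max(abs(w0$w)), 0, tolerance = 1e-10)
})

test_that("a unit-SD zero-mean model maps a raw 1.65 to W = 1.65", {
  # the value identified with the 95th percentile of the control distribution
  geo <- tiny_geometry(2, 2)
  fit <- structure(list(
    coef = matrix(0, 4, 4, dimnames = list(c("(Intercept)", "age", "sex", "icv"),
                                           NULL)),
    sigma = rep(1, 4), degenerate = rep(FALSE, 4), n_controls = 10L,
    df = 6L, rank = 4L, dropped = character(0), modality = "thickness",
    space = "surface", sd_tol = 1e-8, control_ids = character(0)),
    class = "normative_model")
  ch <- data.frame(subject_id = "P1", group = "A", age = 70, sex = 1,
                   icv = 1.4e6)
  maps <- map_set(matrix(1.65, 4, 1), "P1", "thickness", "surface", geo)
  w <- compute_wscore(maps, ch, fit)
  expect_equal(unname(w$w[, 1]), rep(1.65, 4))
  expect_equal(stats::pnorm(1.65), 0.95, tolerance = 0.002)
})

test_that("modality and location mismatches are rejected", {
  geo <- tiny_geometry()
  ch <- generate_cohort(tiny_cohort())
  maps <- make_maps(ch, geo)
  ctrl_ids <- ch$subject_id[ch$group == "control"]
  fit <- fit_normative_model(subset_wmap(maps, ctrl_ids), ch)
  md <- make_maps(ch, geo, modality = "MD", baseline = 0.8,
                  betas = c(age = 0.002, sex = 0, icv = 0), noise_sd = 0.03)
  expect_error(compute_wscore(md, ch, fit), class = "wscoremap_data_error")
})

test_that("in-sample calibration: mean 0 and SD sqrt((n-4)/(n-1)) exactly", {
  geo <- tiny_geometry(8, 6)
  for (n in c(20L, 56L, 100L)) {
    ch <- generate_cohort(tiny_cohort(n_controls = n, seed = 100L + n))
    maps <- make_maps(ch, geo, seed = 200L + n)
    ctrl_ids <- ch$subject_id[ch$group == "control"]
    cmaps <- subset_wmap(maps, ctrl_ids)
    fit <- fit_normative_model(cmaps, ch)
    cal <- control_calibration(fit, cmaps, ch)
    expect_lt(max(abs(cal$insample$mean)), 1e-10)
    expect_equal(cal$insample$expected_sd, sqrt((n - 4) / (n - 1)))
    expect_equal(unname(cal$insample$sd),
                 rep(sqrt((n - 4) / (n - 1)), geo$surface$n_vertices),
                 tolerance = 1e-12)
  }
})

test_that("held-out controls calibrate near mean 0, SD 1", {
  geo <- tiny_geometry(8, 6)
  ch <- generate_cohort(tiny_cohort(n_controls = 400L, seed = 77L))
  maps <- make_maps(ch, geo, seed = 78L)
  ctrl_ids <- ch$subject_id[ch$group == "control"]
  fit_ids <- ctrl_ids[1:200]
  held_ids <- ctrl_ids[201:400]
  fit <- fit_normative_model(subset_wmap(maps, fit_ids), ch)
  cal <- control_calibration(fit, subset_wmap(maps, fit_ids), ch,
                             heldout_maps = subset_wmap(maps, held_ids),
                             heldout_covariates = ch)
  expect_lt(abs(cal$heldout$mean), 0.05)
  expect_gt(cal$heldout$sd, 0.9)
  expect_lt(cal$heldout$sd, 1.1)
})

test_that("W-scores are invariant to affine rescaling of covariates", {
  geo <- tiny_geometry()
  ch <- generate_cohort(tiny_cohort(n_controls = 30L, groups = c(A = 5L)))
  maps <- make_maps(ch, geo, seed = 91L)
  ctrl_ids <- ch$subject_id[ch$group == "control"]
  pat_ids <- ch$subject_id[ch$group == "A"]
  w1 <- compute_wscore(subset_wmap(maps, pat_ids), ch,
                       fit_normative_model(subset_wmap(maps, ctrl_ids), ch))
  ch2 <- ch
  ch2$age <- ch$age / 10 + 1
  ch2$icv <- ch$icv / 1e6
  w2 <- compute_wscore(subset_wmap(maps, pat_ids), ch2,
                       fit_normative_model(subset_wmap(maps, ctrl_ids), ch2))
  expect_equal(w1$w, w2$w, tolerance = 1e-8)
})
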