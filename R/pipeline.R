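# End-to-end pipeline: synthetic cohort -> WMH frequency maps and group
# comparison -> normative fits and W-score maps -> corrected mass-univariate
# contrasts -> global ANCOVA and distributional checks, with a deterministic
# results layout and a provenance record.

#' Default synthetic pipeline configuration
#'
#' Emulates the study design: a control cohort plus a young monogenic
#' (CADASIL-like) group and two older sporadic (SVCI-like) groups, with
#' diffuse DTI deficits and cortical thinning in the SVCI-like groups, a
#' posterior lesion hot-spot in the CADASIL-like group, and the three
#' pairwise contrasts. Every stochastic stage draws from `seed`.
#'
#' @param seed Integer master seed.
#' @param n_perm Permutations for the FWE stage.
#' @param geometry Optional `wmap_geometry` (defaults to [toy_geometry()]).
#' @return A named list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, n_perm = 1000L,
                                    geometry = NULL) {
  geometry <- geometry %||% toy_geometry()
  nvox <- prod(geometry$skeleton$grid_shape)
  base_p <- rep(0.02, nvox)
  hot <- function(frac_lo, frac_hi, p) {
    v <- base_p
    k <- seq(max(1, ceiling(frac_lo * nvox)), floor(frac_hi * nvox))
    v[k] <- p
    v
  }
  thin_region <- region_mask(geometry, "surface", x_range = c(10, 25),
                             y_range = c(10, 25))
  dti_region <- region_mask(geometry, "skeleton", frac_range = c(0.2, 0.8))
  list(
    seed = as.integer(seed),
    alpha = 0.05, q = 0.05, freq_alpha = 0.001, n_perm = as.integer(n_perm),
    fwhm_mm = 0,
    fa_threshold = 0.2,
    contrasts = list(c("SVCI_without_variants", "SVCI_with_variants"),
                     c("typical_CADASIL", "SVCI_without_variants"),
                     c("typical_CADASIL", "SVCI_with_variants")),
    correction = c(surface = "FDR", skeleton = "FWE"),
    synthetic = list(
      cohort = cohort_spec(seed = as.integer(seed)),
      geometry = geometry,
      truth = effect_truth(
        geometry,
        group_effects = list(
          SVCI_without_variants = list(
            thickness = ifelse(thin_region, -0.12, 0),
            FA = ifelse(dti_region, -0.025, 0),
            MD = ifelse(dti_region, 0.035, 0)),
          SVCI_with_variants = list(
            thickness = ifelse(thin_region, -0.10, 0),
            FA = ifelse(dti_region, -0.025, 0),
            MD = ifelse(dti_region, 0.035, 0)),
          typical_CADASIL = list(FA = ifelse(dti_region, -0.008, 0),
                                 MD = ifelse(dti_region, 0.010, 0))),
        lesion_prob = list(control = rep(0.005, nvox),
                           typical_CADASIL = hot(0.55, 0.75, 0.45),
                           SVCI_with_variants = hot(0.25, 0.55, 0.35),
                           SVCI_without_variants = hot(0.25, 0.55, 0.35))),
      pet_positive_fraction = c(SVCI_with_variants = 2 / 15,
                                SVCI_without_variants = 32 / 101)
    )
  )
}

validate_config <- function(config) {
  for (f in c("alpha", "q", "freq_alpha")) {
    v <- config[[f]]
    if (is.null(v) || v <= 0 || v >= 1) {
      config_error(sprintf("config field '%s' must lie in (0, 1)", f))
    }
  }
  if (is.null(config$seed)) config_error("config must carry a 'seed'")
  if (is.null(config$contrasts) || length(config$contrasts) < 1L) {
    config_error("config must list at least one contrast")
  }
  if (is.null(config$synthetic) &&
      (is.null(config$paths) || is.null(config$paths$covariates))) {
    config_error("config needs either a 'synthetic' block or input 'paths'")
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [default_pipeline_config()]; a `synthetic: default: true`
#' block requests the built-in synthetic design with the file's seed.
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  if (isTRUE(raw$synthetic$default)) {
    cfg <- default_pipeline_config(seed = raw$seed %||% 1L,
                                   n_perm = raw$n_perm %||% 1000L)
    for (f in c("alpha", "q", "freq_alpha", "fwhm_mm")) {
      if (!is.null(raw[[f]])) cfg[[f]] <- raw[[f]]
    }
    return(validate_config(cfg))
  }
  validate_config(raw)
}

config_hash <- function(config) {
  # geometry adjacency is bulky and derived; hash the canonical scalar parts
  keep <- config[setdiff(names(config), "synthetic")]
  syn <- config$synthetic
  if (!is.null(syn)) {
    keep$synthetic <- list(cohort = unclass(syn$cohort),
                           pet = syn$pet_positive_fraction,
                           dims = syn$geometry$surface$dims,
                           grid = syn$geometry$skeleton$grid_shape)
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) generate or load the cohort, maps, lesion masks and PET
#' table; (2) WMH frequency maps per group and pairwise frequency
#' comparisons at `freq_alpha` uncorrected; (3) per-modality normative fit
#' on controls, W-score maps for patients, in-sample calibration; (4)
#' pairwise mass-univariate contrasts — FDR-corrected on the surface,
#' max-statistic permutation FWE on the skeleton restricted to the mean-FA
#' > `fa_threshold` mask; (5) global-mean ANCOVA (age/sex-adjusted,
#' Bonferroni post hoc), KS normality and Bartlett variance checks. Results
#' and a provenance record land in `out_dir`; deterministic stages re-run
#' bit-identically for the same config.
#'
#' @param config Config list (see [default_pipeline_config()]) or a YAML
#'   path.
#' @param out_dir Output directory.
#' @param write_maps Write full map/mask volumes (slower, larger); summary
#'   tables and stat maps are always written.
#' @return Invisibly, the in-memory results list (`cohort`, `models`,
#'   `wscores`, `freqmaps`, `freq_stats`, `contrast_stats`, `global`,
#'   `summary`).
#' @export
run_pipeline <- function(config, out_dir, write_maps = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("models", "wmaps", "freqmaps", "statmaps")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c(class(e)[1], "wscoremap_error", "error")))
    })
  }

  syn <- config$synthetic
  geometry <- syn$geometry
  seed <- config$seed

  cohort <- stage("simulate", {
    ch <- generate_cohort(syn$cohort)
    write_covariates(ch, file.path(out_dir, "covariates.csv"))
    ch
  })
  modalities <- names(syn$truth$modalities)
  maps <- stage("simulate", {
    ms <- lapply(seq_along(modalities), function(i) {
      generate_scalar_maps(cohort, syn$truth, modalities[i], seed = seed + i)
    })
    names(ms) <- modalities
    ms
  })
  masks <- stage("simulate",
                 generate_lesion_masks(cohort, syn$truth, seed = seed + 100L))
  pet <- stage("simulate", {
    if (is.null(syn$pet_positive_fraction)) NULL else
      generate_pet_table(cohort, syn$pet_positive_fraction, seed = seed + 200L)
  })

  groups <- setdiff(unique(cohort$group), "control")

  # --- WMH frequency maps and comparisons -----------------------------------
  freqmaps <- stage("freqmap", {
    fm <- lapply(groups, function(g) {
      sub <- lesion_masks(masks$values[, cohort$group == g, drop = FALSE],
                          cohort$subject_id[cohort$group == g],
                          geometry)
      m <- build_frequency_map(sub, group = g)
      write_frequency_map(m, file.path(out_dir, "freqmaps",
                                       paste0(g, ".nii.gz")), geometry)
      m
    })
    names(fm) <- groups
    fm
  })
  freq_stats <- stage("freq-compare", {
    fs <- lapply(config$contrasts, function(pr) {
      sel <- function(g) lesion_masks(
        masks$values[, cohort$group == g, drop = FALSE],
        cohort$subject_id[cohort$group == g], geometry)
      sm <- compare_lesion_frequency(sel(pr[1]), sel(pr[2]),
                                     alpha = config$freq_alpha)
      sm$contrast <- pr
      write_statmap(sm, file.path(out_dir, "statmaps",
                                  paste0("wmhfreq_", pr[1], "_vs_", pr[2])),
                    geometry)
      sm
    })
    names(fs) <- vapply(config$contrasts, paste, collapse = "_vs_", "")
    fs
  })

  # --- Normative models and W-scores ----------------------------------------
  ctrl_ids <- cohort$subject_id[cohort$group == "control"]
  skeleton_masks <- list()
  models <- list(); wscores <- list(); calib <- list()
  for (m in modalities) {
    stage(paste0("fit-normative/", m), {
      mm <- maps[[m]]
      if (mm$space == "surface" && config$fwhm_mm > 0) {
        mm <- smooth_surface_map(mm, geometry, config$fwhm_mm)
      }
      ctrl_maps <- subset_subjects(mm, ctrl_ids)
      model <- fit_normative_model(ctrl_maps, cohort)
      write_normative_model(model, file.path(out_dir, "models", m))
      models[[m]] <- model
      calib[[m]] <- control_calibration(model, ctrl_maps, cohort)
      pat_ids <- cohort$subject_id[cohort$group != "control"]
      wscores[[m]] <- compute_wscore(subset_subjects(mm, pat_ids), cohort, model)
      if (m == "FA") {
        skeleton_masks$fa <- build_skeleton_mask(
          rowMeans(ctrl_maps$values), threshold = config$fa_threshold)
      }
      if (write_maps) {
        wm <- wscores[[m]]
        wset <- map_set(ifelse(is.na(wm$w), 0, wm$w), wm$subject_id,
                        paste0(m, "_w"), wm$space, geometry)
        if (wm$space == "surface") {
          write_surface_maps(wset, file.path(out_dir, "wmaps",
                                             paste0(m, "_w.csv")))
        } else {
          write_skeleton_maps(wset, file.path(out_dir, "wmaps",
                                              paste0(m, "_w.nii.gz")), geometry)
        }
      }
    })
  }

  # --- Mass-univariate contrasts --------------------------------------------
  contrast_stats <- list()
  perm_counter <- 0L
  for (m in modalities) {
    space <- models[[m]]$space
    corr <- config$correction[[space]] %||% if (space == "surface") "FDR" else "FWE"
    mask <- if (space == "skeleton" && !is.null(skeleton_masks$fa)) {
      skeleton_masks$fa
    } else NULL
    for (pr in config$contrasts) {
      key <- paste0(m, ":", pr[1], "_vs_", pr[2])
      stage(paste0("compare/", key), {
        wA <- wscores[[m]]$w[, cohort$group[match(wscores[[m]]$subject_id,
                                                  cohort$subject_id)] == pr[1],
                             drop = FALSE]
        wB <- wscores[[m]]$w[, cohort$group[match(wscores[[m]]$subject_id,
                                                  cohort$subject_id)] == pr[2],
                             drop = FALSE]
        perm_counter <- perm_counter + 1L
        sm <- if (corr == "FDR") {
          correct_fdr(massuni_ttest(wA, wB, mask = mask), q = config$q)
        } else {
          correct_fwe_permutation(wA, wB, mask = mask,
                                  n_perm = config$n_perm,
                                  seed = seed + 1000L + perm_counter,
                                  alpha = config$alpha)
        }
        sm$contrast <- pr
        sm$space <- space
        write_statmap(sm, file.path(out_dir, "statmaps", gsub(":", "_", key)),
                      geometry,
                      location_index = geometry$skeleton$index)
        contrast_stats[[key]] <- sm
      })
    }
  }

  # --- Global statistics ----------------------------------------------------
  global <- stage("global-stats", {
    pat <- cohort[cohort$group != "control", , drop = FALSE]
    out <- list()
    for (m in modalities) {
      gw <- global_mean_wscore(wscores[[m]],
                               mask = if (models[[m]]$space == "skeleton")
                                 skeleton_masks$fa else NULL)
      gw <- gw[pat$subject_id]
      anc <- global_ancova(gw, pat$group, pat$age, pat$sex)
      ksp <- vapply(split(gw, pat$group), function(v) {
        if (length(v) >= 5) check_normality(v) else NA_real_
      }, numeric(1))
      bart <- tryCatch(check_variance_homogeneity(gw, pat$group),
                       wscoremap_error = function(e) list(statistic = NA,
                                                          df = NA, p = NA))
      out[[m]] <- list(global_w = gw, ancova = anc, ks_p = ksp,
                       bartlett = bart)
    }
    if (!is.null(pet)) {
      cls <- classify_pet_table(pet)
      out$pet <- merge(cls, cohort[, c("subject_id", "group")],
                       by = "subject_id")
    }
    out
  })

  summary <- build_summary(config, cohort, freq_stats, contrast_stats,
                           calib, global, modalities)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(list(cohort = cohort, maps = maps, masks = masks, pet = pet,
                 models = models, wscores = wscores, calib = calib,
                 freqmaps = freqmaps, freq_stats = freq_stats,
                 contrast_stats = contrast_stats, global = global,
                 skeleton_mask = skeleton_masks$fa, summary = summary))
}

build_summary <- function(config, cohort, freq_stats, contrast_stats, calib,
                          global, modalities) {
  demo <- lapply(split(cohort, cohort$group), function(d) {
    list(n = nrow(d), age_mean = mean(d$age), age_sd = sd(d$age),
         female_pct = pct(sum(d$sex), nrow(d)))
  })
  list(
    provenance = list(package = "wscoremap",
                      version = as.character(utils::packageVersion("wscoremap")),
                      r_version = as.character(getRversion()),
                      seed = config$seed,
                      config_md5 = config_hash(config)),
    demographics = demo,
    calibration = lapply(calib, function(cc) list(
      insample_mean_max_abs = max(abs(cc$insample$mean)),
      insample_sd_mean = mean(cc$insample$sd),
      insample_sd_expected = cc$insample$expected_sd)),
    wmh_frequency = lapply(freq_stats, function(s) list(
      contrast = s$contrast, alpha = s$alpha,
      n_flagged = sum(s$flag, na.rm = TRUE), n_included = sum(s$included))),
    contrasts = lapply(contrast_stats, function(s) list(
      contrast = s$contrast, space = s$space, correction = s$correction,
      alpha = s$alpha, n_flagged = sum(s$flag, na.rm = TRUE),
      n_included = sum(s$included))),
    global = lapply(global[modalities], function(g) list(
      ancova_F = g$ancova$F, ancova_p = g$ancova$p,
      bonferroni = setNames(g$ancova$pairwise$p_bonferroni,
                            g$ancova$pairwise$contrast),
      ks_p = g$ks_p, bartlett_p = g$bartlett$p))
  )
}
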