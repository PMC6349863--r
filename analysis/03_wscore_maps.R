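#!/usr/bin/env Rscript
# Stage 3: normative models and W-score maps.
#
# Fits the per-location control regression (value ~ age + sex + ICV) for
# each modality, verifies the in-sample calibration identity (W mean 0,
# SD sqrt((n-4)/(n-1))), computes patient W-score maps, and records each
# group's mean global W. The FA skeleton analysis mask (mean control
# FA > 0.2) is saved for the contrast stage.

suppressMessages(library(wscoremap))

geometry <- toy_geometry()
cohort <- read_covariates("results/data/covariates.csv")
ctrl_ids <- cohort$subject_id[cohort$group == "control"]
pat <- cohort[cohort$group != "control", ]
dir.create("results/models", recursive = TRUE, showWarnings = FALSE)
dir.create("results/wmaps", recursive = TRUE, showWarnings = FALSE)

read_modality <- function(m) {
  p_csv <- file.path("results/data", paste0(m, ".csv"))
  if (file.exists(p_csv)) read_surface_maps(p_csv, geometry)
  else read_skeleton_maps(file.path("results/data", paste0(m, ".nii.gz")),
                          geometry)
}
keep <- function(maps, ids) {
  i <- match(ids, maps$subject_id)
  maps$values <- maps$values[, i, drop = FALSE]
  maps$subject_id <- maps$subject_id[i]
  maps
}

rows <- list(); fa_mask <- NULL
for (m in c("thickness", "FA", "MD")) {
  maps <- read_modality(m)
  cmaps <- keep(maps, ctrl_ids)
  fit <- fit_normative_model(cmaps, cohort)
  write_normative_model(fit, file.path("results/models", m))
  cal <- control_calibration(fit, cmaps, cohort)
  if (m == "FA") {
    fa_mask <- build_skeleton_mask(rowMeans(cmaps$values), threshold = 0.2)
    writeLines(as.character(as.integer(fa_mask)), "results/models/fa_mask.txt")
  }
  w <- compute_wscore(keep(maps, pat$subject_id), cohort, fit)
  gw <- global_mean_wscore(w, mask = if (maps$space == "skeleton") fa_mask)
  for (g in unique(pat$group)) {
    rows[[paste(m, g)]] <- data.frame(
      modality = m, group = g,
      direction = abnormality_direction(m),
      mean_global_w = mean(gw[pat$subject_id[pat$group == g]]),
      insample_sd = cal$insample$expected_sd,
      n_controls = fit$n_controls)
  }
  stopifnot(max(abs(cal$insample$mean)) < 1e-10)
}
tab <- do.call(rbind, rows)
tab$mean_global_w <- round(tab$mean_global_w, 3)
write.csv(tab, "results/global_wscores.csv", row.names = FALSE)
cat("Group mean global W-scores (controls calibrate to 0):\n")
print(tab, row.names = FALSE)
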