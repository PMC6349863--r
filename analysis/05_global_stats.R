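#!/usr/bin/env Rscript
# Stage 5: global-mean statistics.
#
# Per-subject global mean W per modality, compared across the three patient
# groups by ANCOVA adjusted for age and sex with Bonferroni post hoc
# contrasts; Kolmogorov-Smirnov (Lilliefors) normality per group and
# Bartlett's variance-homogeneity test; PET amyloid positivity rates.

suppressMessages(library(wscoremap))

geometry <- toy_geometry()
cohort <- read_covariates("results/data/covariates.csv")
pat <- cohort[cohort$group != "control", ]
fa_mask <- as.integer(readLines("results/models/fa_mask.txt")) == 1L

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

rows <- list()
for (m in c("thickness", "FA", "MD")) {
  maps <- read_modality(m)
  fit <- read_normative_model(file.path("results/models", m))
  w <- compute_wscore(keep(maps, pat$subject_id), cohort, fit)
  gw <- global_mean_wscore(w, mask = if (maps$space == "skeleton") fa_mask)
  gw <- gw[pat$subject_id]
  anc <- global_ancova(gw, pat$group, pat$age, pat$sex)
  ksp <- vapply(split(gw, pat$group), check_normality, numeric(1))
  bart <- check_variance_homogeneity(gw, pat$group)
  rows[[m]] <- data.frame(
    modality = m,
    ancova_F = round(anc$F, 2), ancova_p = signif(anc$p, 3),
    min_bonferroni_p = signif(min(anc$pairwise$p_bonferroni), 3),
    ks_p_min = signif(min(ksp), 3), ks_p_max = signif(max(ksp), 3),
    bartlett_p = signif(bart$p, 3))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/global_statistics.csv", row.names = FALSE)
cat("Global-mean W statistics (ANCOVA adjusted for age and sex):\n")
print(tab, row.names = FALSE)

pet <- read.csv("results/data/pet_uptake.csv")
cls <- classify_pet_table(pet)
grp <- cohort$group[match(cls$subject_id, cohort$subject_id)]
pos <- tapply(cls$positive, grp, sum)
n <- tapply(cls$positive, grp, length)
pet_tab <- data.frame(group = names(pos), n = as.integer(n),
                      pib_positive = as.integer(pos),
                      pib_positive_pct = pct(as.integer(pos), as.integer(n), 0))
write.csv(pet_tab, "results/pet_positivity.csv", row.names = FALSE)
cat("\nPiB positivity (uptake ratio > 1.5):\n")
print(pet_tab, row.names = FALSE)
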