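#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a control cohort plus three patient groups whose demographics
# mirror the study design (a young monogenic CADASIL-like group, two older
# sporadic SVCI-like groups), per-subject thickness/FA/MD maps with known
# covariate structure, WMH lesion masks, and a regional PET uptake table.
# Everything is written under results/data/ with the generating truth, so
# the later stages are a pure function of these files.

suppressMessages(library(wscoremap))

seed <- 20260929L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_pipeline_config(seed = seed)
geometry <- cfg$synthetic$geometry
cohort <- generate_cohort(cfg$synthetic$cohort)
write_covariates(cohort, file.path(out, "covariates.csv"))
write_truth_json(cfg$synthetic$truth, file.path(out, "truth.json"))

for (m in names(cfg$synthetic$truth$modalities)) {
  maps <- generate_scalar_maps(cohort, cfg$synthetic$truth, m,
                               seed = seed + match(m, names(cfg$synthetic$truth$modalities)))
  if (maps$space == "surface") {
    write_surface_maps(maps, file.path(out, paste0(m, ".csv")))
  } else {
    write_skeleton_maps(maps, file.path(out, paste0(m, ".nii.gz")), geometry)
  }
}
masks <- generate_lesion_masks(cohort, cfg$synthetic$truth, seed = seed + 100L)
write_lesion_masks(masks, file.path(out, "wmh_masks.nii.gz"), geometry)
pet <- generate_pet_table(cohort, cfg$synthetic$pet_positive_fraction,
                          seed = seed + 200L)
write.csv(pet, file.path(out, "pet_uptake.csv"), row.names = FALSE)

# Demographic summary in the style of a cohort table
demo <- do.call(rbind, lapply(split(cohort, cohort$group), function(d) {
  data.frame(group = d$group[1], n = nrow(d),
             age_mean = round(mean(d$age), 1), age_sd = round(sd(d$age), 1),
             female_n = sum(d$sex), female_pct = pct(sum(d$sex), nrow(d)))
}))
write.csv(demo, "results/table1_demographics.csv", row.names = FALSE)
cat("Cohort generated:\n")
print(demo, row.names = FALSE)
cat(sprintf("\nPET positivity: %s\n",
            paste(capture.output(print(
              tapply(classify_pet_table(pet)$positive,
                     cohort$group[match(pet$subject_id, cohort$subject_id)],
                     mean))), collapse = "\n")))
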