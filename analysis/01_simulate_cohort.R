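#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study cohort.
#
# Four arms (dual-targeted vs IgG-control particles, statin vs untreated;
# n = 8/8/5/5), imaged at weeks 10/15/20/30 after cuff implantation on the
# right carotid, left carotid untreated as internal control. Histology is
# generated at the final imaging week. A reduced 40x40x32 grid keeps the
# driver quick while exercising the identical code paths as full-size
# 256x256x64 volumes.

library(plaquemra)

seed <- 42L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- cohort_design()
config <- phantom_config(grid_shape = c(40, 40, 32), lumen_radius = 5)
cohort <- generate_cohort(design, config, seed = seed)

utils::write.csv(cohort$truth, file.path(out, "truth.csv"), row.names = FALSE)
utils::write.csv(cohort$histology, file.path(out, "histology.csv"),
                 row.names = FALSE)

# export one example animal as NIfTI + landmark sidecars, as a real study
# export would look
ex <- cohort$animals[["DT_none_01"]]
vol_dir <- file.path(out, "example_volumes")
dir.create(vol_dir, showWarnings = FALSE)
scan <- ex$scans[["30"]]
for (side in c("RCCA", "LCCA")) {
  stem <- sprintf("%s_w30_%s", ex$animal_id, side)
  write_volume(scan[[side]]$pre, file.path(vol_dir, paste0(stem, "_pre.nii.gz")))
  write_volume(scan[[side]]$post, file.path(vol_dir, paste0(stem, "_post.nii.gz")))
  write_landmarks(scan[[side]]$landmarks,
                  file.path(vol_dir, paste0(stem, "_landmarks.yaml")),
                  meta = list(animal_id = ex$animal_id, side = side, week = 30))
}

tr <- cohort$truth
cat("Simulated", length(cohort$animals), "animals x",
    length(design$weeks), "weeks (seed", seed, ")\n")
cat("Mean inserted hypointense voxels at week 30, untreated DT arm:\n")
w30 <- tr[tr$week == 30 & tr$probe == "DT-MPIO" & tr$treatment == "none" &
            tr$side == "RCCA", ]
print(round(tapply(w30$truth_count, w30$region, mean), 1))
cat("Control (LCCA) and IgG arms carry zero inserted signal:",
    all(tr$truth_count[tr$side == "LCCA" | tr$probe == "IgG-MPIO"] == 0), "\n")
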