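#!/usr/bin/env Rscript
# Step 4 - atlas-library ranking.
#
# For every test patient, ranks the 14 atlas-library patients by the
# Gower-style clinical/anthropometric profile distance (stage, tumor
# localization, sex, age, weight, height, BMI, fertility state, plus the
# sacro-coccygeal and inter-iliac distances). This automates the selection
# step of atlas-based segmentation; propagation itself is out of scope.

source("analysis/00_config.R")

cohort <- generate_cohort(study_config())
prof <- cohort$profiles
lib <- prof[prof$role == "atlas", ]
tests <- prof[prof$role == "test", ]
ranges <- profile_ranges(prof)

ranking <- do.call(rbind, lapply(seq_len(nrow(tests)), function(i) {
  rank_atlas(tests[i, ], lib, ranges = ranges)
}))
write.csv(ranking, file.path(RESULTS_DIR, "atlas_ranking.csv"),
          row.names = FALSE)

best <- ranking[ranking$rank == 1L, ]
cat("best atlas match per test patient (first 10):\n")
print(utils::head(best, 10), row.names = FALSE)
cat(sprintf("\nmean best-match distance: %.3f (library n = %d)\n",
            mean(best$distance), nrow(lib)))
cat("atlas usage frequency as best match:\n")
print(sort(table(best$atlas_id), decreasing = TRUE))
cat("written:", file.path(RESULTS_DIR, "atlas_ranking.csv"), "\n")
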