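#!/usr/bin/env Rscript
# Stage 1: build and curate the compound libraries.
#
# A reference library of target actives and a larger search library
# (emulating repurposing candidates: other-target actives plus approved
# drugs) are generated with planted curation violations, then pushed
# through the curation funnel: molecular-weight window 160-1000 g/mol,
# canonical deduplication (desalted, neutralized parents), and removal of
# actives weaker than 100 uM. Drugs are exempt from the activity criterion.

library(repurposekit)
dir.create("results", showWarnings = FALSE)

ref_raw <- gen_library(n_scaffolds = 4, decorations_per_scaffold = 6,
                       duplicate_fraction = 0.15,
                       mw_violation_fraction = 0.15,
                       high_activity_fraction = 0.15,
                       source_class = "PTP1B", seed = 101,
                       file = "results/reference_raw.csv")
search_raw <- gen_library(n_scaffolds = 8, decorations_per_scaffold = 8,
                          duplicate_fraction = 0.10,
                          mw_violation_fraction = 0.10,
                          source_class = "drug", seed = 202,
                          file = "results/search_raw.csv")

curate <- function(df, drugs) {
  lib <- compound_library(df$id, df$smiles, df$activity_um,
                          df$activity_type, df$source_class)
  curate_library(lib, apply_activity_filter = !drugs)
}

ref <- curate(ref_raw, drugs = FALSE)
search <- curate(search_raw, drugs = TRUE)

write_library(ref, "results/reference_curated.csv",
              "results/reference_report.json")
write_library(search, "results/search_curated.csv",
              "results/search_report.json")

cat("Reference library funnel:\n"); print(ref)
cat("\nSearch library funnel (activity criterion not applied to drugs):\n")
print(search)
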