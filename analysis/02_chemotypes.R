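#!/usr/bin/env Rscript
# Stage 2: chemotype classification and overlap selection.
#
# Both curated libraries are decomposed into Bemis-Murcko chemotypes
# (side chains pruned; bond orders, atom types and ring-ring connectors
# preserved; exocyclic double-bonded groups on rings/linkers retained).
# Search compounds sharing a chemotype with the reference actives are
# selected for docking; acyclic compounds can never be selected.

library(repurposekit)

ref <- read.csv("results/reference_curated.csv")
search <- read.csv("results/search_curated.csv")

ref_tab <- classify_chemotypes(ref)
search_tab <- classify_chemotypes(search)

cat("Reference library: "); print(ref_tab)
cat("Search library: "); print(search_tab)

selected <- chemotype_overlap(ref_tab, search_tab)
cat(sprintf("\n%d of %d search compounds share a chemotype with the actives\n",
            length(selected), nrow(search)))

write.csv(as.data.frame(ref_tab), "results/reference_chemotypes.csv",
          row.names = FALSE)
write.csv(as.data.frame(search_tab), "results/search_chemotypes.csv",
          row.names = FALSE)
write.csv(data.frame(id = selected), "results/docking_candidates.csv",
          row.names = FALSE)
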