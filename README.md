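# repurposekit

Analytics for structure-based drug-repurposing screens against enzyme
targets — the motivating case is PTP1B (protein tyrosine phosphatase 1B,
a negative regulator of insulin/leptin signaling and a type-2-diabetes
target). The package implements everything *around* the heavy engines:
docking programs, MD codes and plate readers are consumed as tables of
scores, coordinates and responses, never executed.

Five analysis stages, each a module of plain R functions:

1. **Library curation** — parse SMILES/SDF/CSV compound libraries;
   molecular-weight window 160–1000 g/mol; canonical deduplication on
   desalted, charge-neutralized parents (most potent duplicate wins);
   removal of actives weaker than 100 µM (annotated drugs exempt); an
   auditable per-step count report.
2. **Chemotype decomposition and overlap** — Bemis–Murcko scaffolds
   (side chains pruned; bond orders, atom types and ring–ring connectors
   preserved) with retention of exocyclic double-bonded groups
   (carbonyl, thiocarbonyl, imine, sulfone/sulfoxide) on rings and
   linkers; selection of search-library compounds sharing a chemotype
   with the reference actives.
3. **Consensus docking funnel** — orientation-aware min–max
   normalization (best → 1, worst → 0, per program: ΔG-like scores
   lower-is-better, fitness scores higher-is-better), best-quartile
   gating (`floor(N/4)`; 268 from 1075), consensus = mean of normalized
   scores, top-N hit list.
4. **Inhibition kinetics** — percent inhibition `(1 − A_t/A_c)·100`;
   Hill dose–response fits for IC50,
   `%I = A100 / (1 + (IC50/I)^s)`; global Michaelis–Menten inhibition
   fits, e.g. competitive `v = Vmax·S / (Km·(1 + I/Ki) + S)`, with
   uncompetitive/noncompetitive/mixed variants, AICc mechanism
   selection, Lineweaver–Burk diagnostics and the Cheng–Prusoff
   relation `IC50 = Ki·(1 + S/Km)`.
5. **Structural post-processing** — Kabsch superposition (proper
   rotations only), pose RMSD, backbone (C, CA, N) trajectory RMSD/RMSF,
   4 Å ligand-contact occupancy with frame windows, and MM/PBSA
   combination `ΔG_bind = ΔE_MM + ΔG_solv − TΔS` from per-frame
   component tables.

A sixth module generates every input synthetically with planted ground
truth (scaffold-decorated libraries, rank-correlated score tables, noisy
kinetic datasets, harmonic toy trajectories, Gaussian energy
components), so the whole pipeline is testable offline and to known
answers.

Chemistry plumbing (SMILES/SDF parsing, canonicalization, molecular
weights) rides on ChemmineR/ChemmineOB (OpenBabel); fitting on
minpack.lm; PDB I/O on bio3d.

## Worked example

Curate a four-compound active library, classify chemotypes, and select
repurposing candidates sharing a chemotype:

```r
library(repurposekit)

lib <- compound_library(
  id = c("act1", "act2", "salt", "weak"),
  smiles = c("CCCCCCCCc1ccccc1", "CCCCCCCCCCc1ccncc1",
             "CCCCCCCCc1ccccc1.[Na+]", "ClCCCCCCCCc1ccncc1"),
  activity_um = c(12, 3, 45, 250), activity_type = "IC50",
  source_class = "PTP1B")
cur <- curate_library(lib)
print(cur)
#> Compound library: 2 records
#> Curation report:
#>             step n_records
#>            input         4
#>           parsed         4
#>        mw_filter         4
#>      deduplicate         3
#>  activity_filter         2
```

The sodium salt deduplicated onto `act1` (same desalted parent; the more
potent 12 µM annotation survives) and the 250 µM compound fell to the
activity threshold. Chemotype overlap then picks, from a search library,
exactly the compounds whose scaffold occurs among the actives:

```r
ref <- classify_chemotypes(cur)
search <- classify_chemotypes(data.frame(
  id = c("drugA", "drugB", "drugC"),
  smiles = c("CC(C)CCCCCCCCc1ccccc1", "OCCCCCCCCCC1CCCCC1", "CCCCCC")))
chemotype_overlap(ref, search)
#> [1] "drugA"
```

`drugA` shares the benzene chemotype; `drugB` (cyclohexane scaffold) and
the acyclic `drugC` do not. The numbered drivers under `analysis/`
(`01_build_library.R` … `05_structural.R`) run the five stages end to
end on synthetic inputs and write their tables under `results/`.

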