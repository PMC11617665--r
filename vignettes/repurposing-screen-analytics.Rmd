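---
title: "Methods: drug-repurposing screen analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-repurposing screen analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurposekit)
```

`repurposekit` implements the quantitative analysis layer of a
structure-based drug-repurposing screen against an enzyme target (the
motivating case is PTP1B, the protein tyrosine phosphatase that negatively
regulates insulin and leptin signaling). The docking engines, molecular
dynamics engines and plate readers that produce the raw numbers are out of
scope by design: the package consumes their outputs (score tables,
coordinate sets, absorbance-derived responses, per-frame energy
components) and implements everything downstream — curation, chemotype
selection, consensus ranking, kinetic model fitting and structural
post-processing — plus a synthetic-data module that can fabricate every
input with planted ground truth, which is how the package tests itself.

## Library curation

Screening databases are curated with three criteria: a molecular-weight
window of 160–1000 g/mol (inclusive at both bounds), removal of duplicate
structures, and removal of annotated actives weaker than 100 µM (strictly
greater than the threshold is removed; the boundary value is kept).
Approved drugs carry no activity annotation and are exempt from the third
criterion.

Several choices here are deliberately conservative where the procedure is
usually left unstated:

* **Canonicalization.** Records are compared on the canonical SMILES of
  the desalted parent: the largest contiguous fragment is kept and formal
  charges are neutralized where valence-legal (both via OpenBabel).
  Screening libraries contain salts, and two entries of one drug
  frequently differ only by counter-ion. Stereochemistry is left as
  given — canonical form distinguishes stereoisomers, and no
  standardization beyond canonicalization is attempted.
* **Duplicate resolution.** Among duplicates carrying activities, the most
  potent (lowest value) survives; this is conservative for a reference set
  of actives, where the best measured potency is the reason a chemotype is
  interesting. Without activities, first-by-input-order wins, which keeps
  curation order-stable.
* **Molecular weight** is the average-atomic-weight MW of the desalted
  parent, so a salt's counter-ion never decides the window.
* **Mixed activity types** (IC50 vs Ki vs EC50) are compared on raw µM
  values without conversion; the threshold is a coarse gate, not a potency
  model.

Curation is idempotent and order-stable, and each step appends its count
to a report table; those invariants are tested.

## Chemotype (scaffold) decomposition

The chemotype of a molecule is its ring systems plus the connectors
between them, with side chains deleted; bond orders and atom types are
preserved. On top of the classical scaffold, exocyclic double-bonded
groups — carbonyl, thiocarbonyl, imine, sulfone/sulfoxide oxygens, and
exocyclic C=C — are treated as part of the cyclic system *when the
ring-or-linker atom carries them*; a carbonyl on a plain side chain is
pruned with the chain.

The implementation computes the kept set directly: (i) ring atoms are the
endpoints of non-bridge edges (bridges via `igraph`); (ii) linkers are
whatever survives iterative deletion of terminal non-ring atoms (exactly
the atoms on acyclic paths whose endpoints are ring atoms); (iii) the
partner of any bond of order ≥ 2 from a kept atom is added, with the
double bond but without the partner's own substituents. The pruned
subgraph is handed back to OpenBabel for a canonical SMILES key. Keys
compare with no stereochemistry — a chemotype is a constitution-level
concept. Acyclic molecules have no scaffold; they are reported separately
and can never be selected by chemotype overlap.

Two readings of the retention rule are possible for groups like
acetophenone's carbonyl (on a side-chain carbon attached to a ring, not on
the ring itself): the package prunes it, because the carrier atom is
neither ring nor linker. This interpretation, and the whole pruning
semantics, is pinned down by an independent test oracle: a brute-force
algorithm that deletes one eligible terminal atom per pass (ring and
linker atoms found by brute-force connectivity checks) until a fixed
point, run over 200+ enumerated small molecules. The suite requires exact
agreement, plus the fixed-point property (the scaffold of a scaffold is
itself) and invariance under alkyl decoration.

Formal charges are not rewritten into the scaffold's MOL block; after
neutralization the rare survivors (e.g. quaternary nitrogens) may
canonicalize to an uncharged tautomer of the key, which is acceptable at
the constitution level at which chemotypes are compared.

## Consensus docking funnel

Scores from different programs live on different scales and orientations:
binding energies (more negative is better) versus fitness scores (larger
is better). The funnel arithmetic is:

1. **Quartile gate.** Compounds are sorted best-first on the fast
   program's scores and the best `floor(N/4)` form Q1; with N = 1075 this
   is 268 compounds — the only quartile-size rule consistent with that
   pair of counts. The remainder after Q1–Q3 lands in Q4. Ties sort
   lexicographically by compound id, so the gate is deterministic.
2. **Normalization.** Each program's scores are min–max normalized over
   its own table *before* any intersection, mapping its best compound to 1
   and worst to 0. Normalizing before intersection keeps one program's
   missing entries from distorting another's scale. Identical scores
   across a whole table are a degenerate range and an error, not a
   silent division by zero.
3. **Consensus.** The unweighted arithmetic mean of the per-program
   normalized scores. A mean is the simplest aggregation that treats the
   programs symmetrically; since normalized tables are retained in the
   ranking object, any other aggregation can be recomputed from them.
   Ties break by the first program's normalized score, then by id.
4. **Top-N.** The first `n` (default 50) ids by rank.

Normalization is invariant under affine rescaling of raw scores, the
ranking is a permutation independent of input row order, and the
end-to-end funnel agrees with a brute-force enumeration; all tested.

## Inhibition kinetics

Percent inhibition from corrected absorbances is
$\%I = (1 - A_t/A_c)\times 100$. Dose–response curves follow the Hill
form
$$\%I(I) = \frac{A_{100}}{1 + (\mathrm{IC}_{50}/I)^s},$$
increasing in $I$, equal to $A_{100}/2$ at $I = \mathrm{IC}_{50}$, and 0
at $I = 0$ by continuity. (The form with the ratio inverted decreases
with inhibitor concentration and cannot describe an inhibition assay;
this orientation is therefore the only admissible one.)

Rate data are fitted globally — all inhibitor levels simultaneously —
under the standard laws; for competitive inhibition
$$v = \frac{V_{\max} S}{K_m (1 + I/K_i) + S},$$
with uncompetitive, noncompetitive and mixed variants available. Global
fitting uses fewer parameters than per-curve apparent-Km fits and is what
"nonlinear regression" means for such grids in practice.

Numerical choices:

* **Positivity by log-parameterization.** All parameters are fitted on
  the log scale (Levenberg–Marquardt, `minpack.lm::nls.lm`, up to 1000
  iterations, `ftol = ptol = 1e-14`), which enforces positivity without
  active-set bounds. Standard errors come from the Gauss–Newton
  covariance at the optimum (central-difference Jacobian) mapped to the
  natural scale by the delta method; a singular normal matrix yields `NA`
  standard errors rather than a crash.
* **Starting values.** $V_{\max,0} = 1.2\max(v)$, $K_{m,0} =
  \mathrm{median}(S)$, $K_{i,0} = \min I_{>0}$; for dose–response
  $A_{100,0} = \max$ response, $\mathrm{IC}_{50,0}$ the concentration
  nearest half-max, $s_0 = 1$.
* **Model comparison.** $\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k +
  2k(k+1)/(n-k-1)$; `model = "auto"` fits all four mechanisms and keeps
  the lowest.
* **Degenerate inputs.** All-zero responses are a flat-data error;
  responses that decrease with concentration are an inverted-data error;
  fewer than 4 distinct positive concentrations, a missing $I = 0$
  series, or fewer than 4 substrate levels are refused.
* **Least squares is unweighted.** The synthetic noise is multiplicative,
  so weighted least squares would match the error model slightly better;
  unweighted is kept as the plain reading of "nonlinear regression fit",
  and at 2 % CV the difference is immaterial next to the identifiability
  structure discussed below.

**Identifiability at the bench design.** The assay grids are
$S \in \{0.10,\dots,0.50\}$ mM and $I \in \{0, 0.005, 0.040, 0.060\}$ mM
while the reported $K_m$ is 25.71 mM, so $S \le 0.02\,K_m$ and the rate
law is, to within about 2 %, $v \approx (V_{\max}/K_m)\,S/(1+I/K_i)$.
The data then pin down the *ratio* $V_{\max}/K_m$ and $K_i$ tightly, but
$V_{\max}$ and $K_m$ individually only through the ~2 % curvature in
$S$ — at a 2 % noise CV their Fisher-bound relative standard errors are
around 70 %. The package reports what the data support: in the
simulation studies $K_i$ comes back within a few percent and
$V_{\max}/K_m$ within ~5 %, while individual $V_{\max}$ and $K_m$
estimates scatter widely with large reported standard errors. This is a
property of the experimental design being emulated, not of the fitter;
the zero-noise tests confirm exact recovery (≤ 1e-6 relative) when the
information limit is removed. One stated unit in the source estimates is
dimensionally impossible ($K_m$ printed in mM/min); it is treated as mM.

**Lineweaver–Burk** double-reciprocal fits are provided as the classical
diagnostic: per-level OLS of $1/v$ on $1/S$, with the pattern heuristic
(shared ordinate intercept → competitive; parallel slopes →
uncompetitive; shared abscissa intercept → noncompetitive; otherwise
mixed, with a 5 % relative-spread tolerance). On exact competitive data
the intercepts agree to better than 1e-8 relative spread. On noisy data
with $S \ll K_m$ the intercepts are long extrapolations and the
diagnostic is unreliable — parameter and mechanism calls should come from
the nonlinear fits and AICc. (The classical plot patterns are also easy
to mislabel: parallel lines diagnose *uncompetitive*, not competitive,
inhibition. The package reports what the data show rather than encoding
any verbal claim.)

**Mechanism discrimination study.** The AICc-discrimination simulations
use $K_m = 0.3$ mM — mid-substrate-grid — with the other parameters at
their defaults. This is a deliberate design choice: a textbook-informative
assay has substrate spanning $K_m$. On a grid with $S \le 0.02\,K_m$ an
uncompetitive inhibitor's maximal effect on $v$ is under 7 %, which 2 %
noise cannot resolve; no analysis method can discriminate mechanisms from
an assay that barely expresses them. At the informative design, AICc
identifies the generating mechanism in well over 90 % of seeded
simulations (100 runs in the test suite).

**Cheng–Prusoff.** For competitive inhibition
$\mathrm{IC}_{50} = K_i(1 + S/K_m)$, used as a cross-consistency check
between the two assays. When dose–response data are simulated *from the
competitive mechanism itself*, the fitted IC50 matches the Cheng–Prusoff
prediction to ~1 %. The package's generator defaults take IC50 = 0.044 mM
and $K_i$ = 0.0234 mM from their respective source assays; at
$S \ll K_m$ ideal competitive kinetics would make those nearly equal, so
the factor-of-two gap the stage-4 analysis prints reflects a tension
between the source estimates themselves, which the package surfaces
rather than hides.

## Structural post-processing

* **Superposition** is the Kabsch least-squares fit via SVD with the
  determinant correction, so the result is always a proper rotation
  (never a reflection). Near-degenerate (collinear) selections trigger a
  conditioning warning. The test oracle is Horn's closed-form quaternion
  method — an independent route to the same optimum.
* **Pose RMSD** (docking validation) uses identity atom correspondence in
  input order and *no* superposition, matching re-docking conventions
  where the pose is compared in the crystal frame. Graph-symmetry
  correction (equivalent-atom relabeling) is out of scope and would make
  reported values conservative upper bounds for symmetric ligands.
* **Trajectory RMSD/RMSF** default to the backbone atom-name selection
  C, CA, N. RMSF aligns frames to their time-mean (two passes of
  align-then-remean) and averages atomic fluctuations within residues.
  RMSF is invariant under per-frame global rigid motion (tested); note
  that genuine large-amplitude motion of a chain *terminus* partially
  aliases into the rigid-body fit — with a handful of residues a terminal
  wobble is partly absorbed by alignment, which is why planted-amplitude
  checks in the suite run on pre-aligned data (`align = FALSE`) and the
  alignment path is tested by its invariance property instead.
* **Contacts** count a residue in a frame when any heavy-atom pair
  (residue vs ligand) is within the cutoff (default 4 Å), and report
  per-residue occupancy over a frame window, supporting early/late
  window splits.
* **MM/PBSA combination** takes per-frame component triples (complex,
  receptor, ligand) and forms $\Delta X = X_{\mathrm{cpx}} -
  X_{\mathrm{rec}} - X_{\mathrm{lig}}$ per component, then
  $\Delta E_{MM} = \Delta E_{\mathrm{int}} + \Delta E_{\mathrm{elec}} +
  \Delta E_{\mathrm{vdw}}$, $\Delta G_{\mathrm{solv}} = \Delta G_{PB} +
  \Delta G_{SA}$, and $\Delta G_{\mathrm{bind}} = \Delta E_{MM} + \Delta
  G_{\mathrm{solv}} - T\Delta S$, reporting means and standard deviations
  over frames. The entropy term is accepted as a scalar or per-frame
  column; normal-mode analysis is not reimplemented (it needs force-field
  Hessians the package does not contain), and without it the result is
  flagged as an enthalpy-only estimate. The combiner is agnostic to
  whether components came from single- or multi-trajectory extraction —
  it consumes whatever consistent table is supplied.

## What the synthetic data do and do not emulate

The generators produce: scaffold-decorated libraries (ring cores with
saturated alkyl/halide chains, planted duplicates and criterion
violators); three-program score tables driven by a shared latent affinity
with the mixing weight calibrated so the inter-program Spearman
correlation hits its target (Pearson $\rho = 2\sin(\pi\rho_s/6)$);
kinetic datasets with multiplicative Gaussian noise (CV-parameterized —
the standard first-order error model for absorbance-derived rates);
harmonic toy trajectories (square or sine waveforms, whole cycles, so
expected RMSF has a closed form — amp or amp/√2); and Gaussian energy
components. Seeds make every generator byte-reproducible.

They do **not** emulate: real chemical diversity (decorations are
homologous chains, so scaffold membership is unambiguous by
construction); docking-score pathologies (size bias, scoring-function
disagreement beyond rank decorrelation); kinetic misbehavior
(tight-binding depletion, substrate inhibition, slow-binding onset);
solvent or force-field physics in trajectories (displacements are
kinematic, not dynamical); or correlated frame-to-frame noise in energy
components. Passing tests therefore demonstrate that the *analysis
arithmetic* is correct and recoverable under its stated error model — not
that the pipeline is robust to every pathology of real screening data.

## Problem sizes

The test-suite and analysis-script problem sizes are chosen to exercise
the documented behaviors at comfortable margins: 1075-compound score
tables (the size at which the quartile gate yields 268), 200+ molecules
in the scaffold-oracle sweep, 100 seeded simulations for mechanism
discrimination, 20-point kinetic grids in triplicate, and trajectories of
40–200 frames with 8–40 residues. All fixtures are generated in code at
run time; nothing binary ships with the package.
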