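---
title: "Methods: models, parameters and design choices in phabkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in phabkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phabkit)
```

# Scope

phabkit implements the computational stages of an in vitro
antibody-engineering workflow for acid-labile phospho-epitopes such as
3-phosphohistidine (3-pHis): variable-domain numbering and CDR grafting
with Vernier-zone back-mutation planning, soft-randomization phage
library mathematics, selection-pool substitution analysis, 1:1 Langmuir
biolayer-interferometry (BLI) kinetics, ELISA curve utilities, and
antibody-antigen interface geometry under explicit contact criteria.
Wet-lab stages (peptide chemistry, phage propagation, crystallographic
refinement, QM/MM and free-energy simulation) are out of scope; where
the workflow consumes their outputs we consume standard file formats
instead.

# Numbering and grafting

## Model

A query V-domain is numbered by global alignment
(Needleman-Wunsch, BLOSUM62, gap open 10 / extend 0.5 via Biostrings)
against a shipped curated reference: a 113-residue heavy-chain
consensus occupying Kabat H1-H113 with no insertion codes and a
107-residue kappa consensus occupying L1-L107.  Positions transfer
across aligned columns; residues falling between reference positions
receive insertion codes.  Inside each CDR the assignment is then
rewritten with the scheme's canonical insertion anchors (H1: 35, H2:
52, H3: 100; L1: 27, L3: 95): the loop fills from its start up to the
anchor, extra residues become `a`, `b`, ... insertions at the anchor,
and the tail fills from the region end backwards.  This reproduces the
standard behaviour that, for example, a CDR-H3 two residues longer than
the reference gains 100a and 100b.  An alignment scoring below 40% of
the reference self-score is rejected as "not a V-domain".

The references are curated germline-consensus-style sequences written
for this package (conserved cysteines at H22/H92 and L23/L88, FR4
`WGQGT...`/`FGQGT...`); they are synthetic data, so insertion-code
agreement with any specific published alignment of a particular
antibody is not claimed.  A profile HMM would be the heavier
alternative; the alignment-plus-anchor transfer is deterministic,
dependency-free and adequate for single V-domains, which is all this
workflow requires.

IMGT numbering uses a fixed curated residue-to-IMGT-position mapping
for the same references (anchored on Cys23/Cys104 and the FR4
Trp/Phe at 118, with gap positions placed by the both-ends loop-filling
rule).  Loop residues beyond the reference span receive insertion
letters at the loop anchor rather than IMGT's `111.1`-style dot codes;
this keeps one insertion notation across both schemes and is a
documented simplification.

## Grafting and Vernier sets

`graft_cdrs()` takes donor residues at every CDR position — donor
insertions included, so loop-length-changing grafts are allowed
(rabbit and human CDR-H3 lengths commonly differ) — and acceptor
residues elsewhere.  `apply_back_mutations()` restores donor residues
at framework positions; requesting a CDR position is an error, and
positions where donor and acceptor already agree are skipped silently
so that "back-mutate this list" is idempotent.  The Vernier-zone set
ships as an editable CSV (a curated Foote-Winter-derived set of
framework positions beneath the CDRs) rather than as code, because
published campaigns typically back-mutate a project-specific set: users
supply their own table when reproducing a particular antibody.
Mutation notation follows the field's convention, e.g. `L46R^L`.

# Soft-randomization library design

Each diversified nucleotide position is a doped synthesis mixture:
wild-type base at fraction $w$ (default 0.7) and the three other bases
at $(1-w)/3$ each.  Per-base independence within and across codons
reflects per-nucleotide resin doping.  The amino-acid distribution of a
doped codon is computed by exact enumeration of all 64 codons under the
standard genetic code (no organism-specific codon weighting; none is
implied by mixed-resin synthesis).  At $w = 0.7$ the wild-type codon
survives with probability $0.7^3 = 0.343$ and the wild-type amino acid
is retained about half the time averaged over the 61 sense codons
(the package computes both the per-codon values and the mean, since
"retained roughly 50% of the time" can be read either way).

Stop templates replace the first codon of each region to be mutagenized
with TAA, so that only clones repaired by a mutagenic oligo display.
Oligo specs emit exact template flanks plus explicit percentage
mixtures (`A70/C10/G10/T10`); soft mixtures are not expressible in
IUPAC degeneracy codes.  Oligos are reported in template-strand
orientation with a reverse-complement flag, since Kunkel-strand
conventions vary between labs.  The seeded sampler draws each
diversified base independently, which is the generative model the
closed-form distributions describe; a chi-square goodness-of-fit test
at $n = 50{,}000$ ties the two together in the test suite.

# Selection analysis

Clone pools are equal-length translated sequences aligned to a
template; clones with indels are excluded with a logged count (these
libraries are substitution-only by construction).  The substitution
matrix counts non-template residues per Kabat position.  Binding
association uses per-substitution 2x2 tables with Haldane-corrected
odds ratios, two-sided Fisher exact p-values and Benjamini-Hochberg
q-values; binder labels are external input (a fold-change $\ge 2$
phage-ELISA threshold is a reasonable convention, not a measurement of
this package).

The selection simulator exists to give the analyzers a ground truth: it
resamples pools with probability proportional to the product of
per-substitution enrichment factors.  Under this model an allele at
frequency $f$ with factor $s$ follows $f' = sf/(1 + (s-1)f)$, so the
round-over-round odds ratio estimates $s$; the test suite verifies
recovery within 15% at pool size 10,000 over 5 rounds, and that the
neutral model ($s = 1$) preserves frequencies in expectation
(martingale property, averaged over 200 seeded runs).  Simulated pools
are much smaller than the $10^9$-$10^{10}$ diversity of real phage
libraries; passing tests demonstrate correctness of the estimators, not
realism of desk-scale pool sizes.

# BLI kinetics

The 1:1 Langmuir model:
association $R(t) = R_{eq}\,(1 - e^{-(k_a C + k_d)t})$ with
$R_{eq} = R_{max} C/(C + K_D)$, dissociation
$R(t) = R(t_{assoc})\,e^{-k_d (t - t_{assoc})}$, and $K_D = k_d/k_a$.
Fitting is global: one $(k_a, k_d, R_{max})$ across all traces,
least squares on the log-parameter scale (Levenberg-Marquardt via
minpack.lm).  Initialization is deterministic: $k_d$ from log-linear
regression of the dissociation tails, $k_a$ from the regression of
apparent rates on concentration, followed by three restarts with
$\pm 10\times$ perturbations; the best residual wins.  A flat trace is
rejected ("no signal") rather than fitted.  Fitting a single
concentration far below $K_D$ identifies only $k_a C + k_d$; the fitter
still returns values but the test suite documents the wide
identifiability rather than asserting failure.

Mass-transport and bivalent-analyte models are out of scope; bivalent
IgG "affinities" are avidity-inflated apparent values (published
IgG-format values at the instrument floor of $10^{-12}$ M illustrate
this), which is why the shipped kinetics table
(`fab_kinetics_table()`) contains monovalent Fab measurements.

ELISA utilities: the standard-curve linear range is the longest
contiguous run of at least 3 standards with straight-line $R^2 \ge
0.98$ (default); unknowns outside the range are flagged, not
extrapolated.  The 4-parameter logistic EC50 fit uses the same
LM machinery.

# Interface geometry

Default contact criteria are implemented exactly as stated by the
source analysis pipeline this toolkit mirrors: hydrogen bonds at
donor-acceptor distance $\le 2.5$ Å with donor (D-H···A) and acceptor
(H···A-X) angles within 120-180°; water bridges at $\le 2.8$ Å per leg
with the same windows; π-cation within 4.5 Å of a ring centroid; π-π
with centroid distance 3.5-5 Å.  The 2.5 Å heavy-atom cutoff is
unusually short by field convention (3.5 Å is common); it is kept
literally as the default for fidelity, with
`conventional_criteria()` as the documented escape hatch.  The π-π
shape thresholds (parallel < 30°, T-shaped > 60°) are not part of the
stated criteria; they were chosen so that published T-shaped stackings
at 68-86° and face-to-face stackings near 0° classify as named.

Hydrogen positions: detection uses hydrogens when present; when a model
lacks them the angle tests are skipped with a warning (distance-only
fallback).  Synthetic fixtures always carry explicit hydrogens, so the
full criteria are exercised in tests.  The acceptor-angle antecedent is
taken as the best over atoms covalently bonded to the acceptor
(relevant for waters, whose only bonded atoms are hydrogens).

Ring offset is the PLIP-style lateral displacement of the partner
centroid projected onto the reference ring plane (tools differ slightly
in this definition; this one is documented and round-trips the
constructive fixtures).  Rings come from His/Phe/Tyr/Trp templates
(Trp contributes two rings, evaluated separately) plus user-supplied
templates for ligand residues.

Kabsch superposition is the standard SVD solution constrained to proper
rotations; RMSD is re-verified in tests by brute-force recomputation
and against an independent least-squares fit (bio3d).  SASA is
Shrake-Rupley with a deterministic golden-spiral lattice (default 960
points/atom) and a 1.7 Å probe, the radius used for buried-surface
analysis of Fab complexes; buried surface is
$SASA(A)+SASA(B)-SASA(AB)$, halved only on request.  At 960 points the
isolated-sphere error is below 1% and two-sphere burial agrees with the
analytic spherical-cap value within 2% (both asserted in tests).

# Synthetic fixtures

All tests run offline on fixtures the package generates:

* chains: edits/insertions of the shipped references with ground-truth
  numbering emitted alongside;
* pools: seeded draws from soft-randomization designs, optionally run
  through the selection simulator with known enrichment factors;
* sensorgrams: closed-form traces plus seeded Gaussian noise;
* interfaces: atoms placed constructively so the requested geometry
  holds to 1e-6 (PDB writing quantizes coordinates to 3 decimals, so
  file round-trip assertions allow 2e-3 Å).

What the fixtures do not emulate: real sequencing noise, real
libraries' position-specific diversification tables (published
supplementary tables; users supply their own), instrument drift and
reference-well artifacts in BLI, and crystallographic coordinate error.
Passing tests therefore validate the algorithms and their stated
criteria, not robustness to those real-data effects.  Published
crystal-structure measurements (e.g. a 5.0 Å / 75° T-shaped stacking
at a heavy/light interface, V_H Cα RMSDs below 1 Å) are reproducible
only against deposited structures and are exercised here as
constructive round-trips of the same geometry instead.

# Problem sizes and determinism

Default validation sizes: 100 seeded noisy re-fits for kinetics
recovery, 50,000 clones for sampler consistency, pool size 10,000 and 5
rounds for enrichment recovery, 200 runs for the martingale average,
960 SASA points/atom.  These sizes make the full validation complete in
minutes on a laptop while leaving comfortable statistical margins.
Every stochastic path takes an explicit integer seed, restores the
caller's RNG state, and produces byte-identical output for identical
inputs and seed.
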