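---
title: "Methods: consensus virtual screening for AhR ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus virtual screening for AhR ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind `ahrscreen`, the tunable
parameters, the numerical choices, what the synthetic benchmark does and
does not emulate, and the design decisions taken where several reasonable
options existed. It states no empirical results beyond what the package's
tests and acceptance script themselves compute.

## The screening model

The screen assumes that new AhR ligands resemble known AhR binders either
in substructure content, in global physicochemical properties, or in their
predicted receptor-binding energetics, and that demanding agreement between
at least two of these three views suppresses the false positives each view
produces alone. The reference panel consists of compounds with competitive
binding potency (the lowest of IC50, Ki, or Kd) at or below 10 µM — an
inclusive boundary; weaker values are too uncertain for hydrophobic,
poorly soluble ligands. Reference binders split into a *typical* majority
(small, rigid, halogenated-aromatic and polycyclic structures) and an
*atypical* minority (flexible heteroaromatics with additional hydrogen-bond
acceptors) that falls outside the property space of the majority and needs
its own filtration branch.

### Curation

Counter ions are removed by keeping the largest carbon-containing fragment
(ties: heavy-atom count, then canonical-SMILES order). "Strong acids
deprotonated, strong bases protonated" is operationalized as a fixed
transformation list — carboxylic, sulfonic, and phosphonic acid OH groups
lose a proton; aliphatic amines, amidines, and guanidines gain one —
applied after salt stripping. Deduplication keys on the canonical SMILES of
the standardized structure with stereochemistry retained; the surviving
record is the one with the lexicographically smallest identifier, so
output is independent of input order, and the minimum (most potent) of
duplicate potencies is kept. The element exclusion list (Al, As, Ba, Bi,
Cd, Co, Cr, Mn, Ni, Pb, Sb, Sn, Sr, Ti, Zr) is checked against the full
input structure, counter ions included. Unparseable records are counted
and reported, never silently dropped.

### Descriptors and fingerprints

The default registry holds 68 two-dimensional descriptors covering
hydrophobicity (Crippen logP, molar refractivity), surface polarity
(PEOE_VSA1–14 partial-charge surface-area bins), shape and branching
(Balaban J, Kier κ1–κ3, connectivity χ indices, Bertz complexity), size
(molecular weight, heavy atoms, Labute ASA), aromaticity (aromatic ring
and bond counts), flexibility (rotatable bonds, sp³ carbon fraction),
hydrogen bonding (donors, acceptors, TPSA), and composition (halogens,
heteroatoms, ring-type counts, SMR/SlogP bins). The registry is an
argument, not a constant: any list of resolvable descriptor names may be
substituted. Exact PEOE_VSA bin boundaries follow the open-toolkit
defaults; like the MACCS dialect below, bin-definition differences against
commercial toolkits are treated as registry properties, not errors.

Fingerprints are the public 166-key MACCS structural keys as implemented
in RDKit; the test suite cross-checks them bit-for-bit (>99% agreement)
against OpenBabel's independent implementation. Commercial MACCS dialects
differ in a handful of key definitions; Tanimoto coefficients computed
from different dialects agree to about ±0.02, and that tolerance is used
wherever a dialect-sensitive value is asserted. Both computations run in a
bundled Python/RDKit helper behind the R interface; results return as
plain matrices.

### Chemical-space model and applicability domain

PCA is fitted to the mean-centered, unit-variance-scaled descriptor
matrix (scaling is an argument; constant columns are dropped with a
warning). A component is significant when its eigenvalue is at least 2 —
it must explain at least two descriptors' worth of variance — with a floor
of one component. Two statistics define the 95% applicability domain (AD):

* **Hotelling T²** = Σₐ tₐ²/λₐ over the significant components, with limit
  `A(N²−1)/(N(N−A)) · F₀.₉₅(A, N−A)` for `N` training compounds and `A`
  components.
* **DModX**: the compound's residual standard deviation off the model
  plane, `√(Σⱼeᵢⱼ²/(p−A))`, divided by the pooled training residual SD
  `s₀ = √(ΣΣe²/((N−A−1)(p−A)))`; limit
  `√(F₀.₉₅(p−A, (N−A−1)(p−A)))`. Exact-fit compounds get DModX 0; if the
  training residual variance is zero the limit is undefined and a warning
  is raised.

A compound is inside the AD only if both statistics are at or below their
limits. The F-approximations used by commercial chemometrics software for
DModX are unpublished; the formulas above are conventional
degrees-of-freedom bookkeeping, stated here precisely and verified in the
test suite against an independent first-principles recomputation. On
Gaussian data ≥ 85–95% of the training set falls inside its own domain; on
real descriptor matrices, whose residuals are heavier-tailed than normal,
the DModX criterion is noticeably stricter and is the binding constraint
of the typical filtration branch.

### Initial filtration

The typical branch fits the PCA on the binder reference panel alone and
projects candidates into it, because the applicability domain is defined
relative to the binders; candidates inside the 95% AD pass. The atypical
branch fits a PCA on the atypical references *together with* all
candidates — the atypical panel alone is far too small to define a stable
model — using log-transformed descriptors, and passes candidates within
Euclidean distance 1.5 (inclusive) of any atypical reference in
significant-component score space. The log transform (natural log; columns
already log-scaled, matched by name pattern, pass through; columns with
non-positive values are shifted by `x → log(x − min(x) + 1)`) compresses
extreme values, which is why this branch uses a much smaller distance
cutoff than the nearest-neighbor enrichment. Constant columns trigger a
warning but still pass through the monotone rule, so a column of ones maps
to zeros. The two branches are unioned, counting overlap once. When the
user does not name the atypical references, `run_screen()` detects them as
the panel members outside the 95% AD of a PCA on the full panel — the same
situation that motivates the branch.

### Parallel enrichments

*Fingerprint screen*: a candidate is a hit when its maximum Tanimoto
coefficient against the references is ≥ 0.60, inclusive, matching the
"at or below"-style boundary conventions used throughout the protocol;
the maximizing reference is recorded for attribution. *Nearest-neighbor
screen*: scores come from one shared PCA (fitted on references plus
filtered candidates, untransformed unit-variance descriptors, the
significant components); per reference, candidates with ED ≤ 5.0 are kept,
sorted ascending, truncated to 10 neighbors, with distance ties at the
capacity boundary broken by candidate-id lexicographic order so results
are permutation-invariant. *Docking gate*: per compound the minimum
ΔG_bind over all stereoisomers and poses is selected (stereoisomer ties to
the lexicographically smallest id); the cutoff is the reference panel's
mean plus one *sample* (n−1) standard deviation — whether the original
convention was sample or population SD is not determinable from a printed
mean/cutoff pair, and at panel sizes near 65 the difference is negligible —
and the gate is inclusive at the cutoff. Compounds with no score records
are reported as failed in docking and excluded downstream. The docking
computation itself is deliberately out of scope: the module defines the
score-table contract so any engine (or the synthetic generator) can feed
it.

### Clustering, consensus, evaluation

Structure-based hits are clustered with the binders on Tanimoto distance
(1 − TC, the standard binary-fingerprint dissimilarity) under
Lance–Williams flexible-beta linkage with β = 0.25, α = (1−β)/2 = 0.375,
γ = 0 (γ is not part of the flexible-beta family). Since 2α + β = 1, the
monotonicity condition holds with equality and merge heights never
decrease — asserted on every run. Merge ties go to the smallest pair of
cluster indices (leaves in input order, then merged clusters in creation
order). The cut rule is the user's choice of `k` or height — the
reference analysis reports a cluster count without its cut criterion —
with canonical labels ordered by each cluster's smallest member id.

Consensus voting counts per-compound method memberships; ≥ 2 of 3 defines
the consensus set. Evaluation computes accuracy, sensitivity, and
specificity over the labeled filtered universe; ambiguous labels
(compounds reported both active and inactive) are excluded on read, a
metric with zero denominator is reported as undefined rather than zero,
and display rounding is half-away-from-zero at two decimals.

## The synthetic benchmark

The generator emulates the study conditions end to end: a 66-compound
reference panel (61 typical — halogenated biphenyls, dibenzodioxins and
-furans, diphenyl ethers, PAHs, flavones, fluorenes, dibenzothiophenes,
xanthones, azo dyes, with substituents drawn from H/Cl/Br/F/methyl/
methoxy/hydroxy/nitro/cyano/ethyl — plus 5 atypical flexible
heteroaromatics), a 1000-compound candidate library containing 60 planted
single-substituent-edit analogs of the references, aliphatic and
small-polar decoys, 40 borderline monocyclic aromatics, and 5
excluded-element decoys that exercise curation. Docking scores are drawn
per compound from Normal(−112.5, 13.2) kcal/mol for binder-like compounds
— anchored to the reference-panel mean the protocol's cutoff derives from
— and Normal(−70, 15) for decoys, a generator artifact chosen to give
clear but tail-overlapping separation (decoy gate pass-rate ≈ 2–5%); ten
poses per stereoisomer add non-negative jitter above the compound's base
value so best-pose selection recovers it. Labels are noisy by design:
planted analogs are active with probability 0.8, decoys 0.1, keeping
evaluation metrics non-trivial. Analog edits touch only H, methyl, and
halogen sites — heteroatom substituents are preserved — because removing
an oxygen- or nitrogen-bearing group from a sparse-key polycyclic parent
collapses fingerprint similarity; with this rule planted analogs reach
TC ≥ 0.60 to their parent in ≥ 90% of cases by construction. All
randomness derives from a single integer seed (sub-seeded per stage, so
each table is reproducible independently), and generation restores the
caller's RNG state.

What the benchmark does *not* emulate: the composition of any real
industrial inventory, tautomerism and stereochemical enumeration,
activity cliffs, or assay-specific label structure. Its planted analogs
separate from its decoys far more cleanly than real actives separate from
real inactives — in particular the strict applicability domain passes
almost exclusively planted analogs, so the synthetic evaluation universe
is dominated by them and its specificity is near zero by construction.
Passing tests therefore demonstrate correctness and calibration of the
machinery, not expected real-world enrichment rates.

## Problem sizes and runtime choices

Unit and property tests run on libraries of 8–300 molecules; the
generator-calibration and recovery checks run the full pipeline on the
1000-compound default library, the size at which the planted-analog
consensus precision ≥ 0.7 / recall ≥ 0.6 bounds are asserted (documented
seeds; stochastic properties are asserted at the default generator scale,
where their sampling variability is small). Oracle comparisons use sizes
where brute force is exact and fast: all-pairs similarity on full
libraries, eigendecomposition at n = 50 × p = 10, naive recursive
Lance–Williams at n ≤ 8.

## Known limitations

* The 68-descriptor registry reproduces every descriptor family named for
  the protocol but is not the proprietary original; with a different
  registry the PCA rotation, significant-component count, and AD
  membership shift accordingly.
* Quantum-chemical descriptors (HOMO/LUMO/GAP) and 3D shape descriptors
  are out of scope, as is the docking computation itself.
* The protocol ranks candidates by resemblance to known binders; it cannot
  distinguish agonists from antagonists, and compounds activating AhR
  without binding it are invisible to all three methods.
* DModX limits follow the documented F-approximation; other chemometrics
  software will draw slightly different 95% boundaries.
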