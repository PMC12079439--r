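---
title: "Screening re-scaffolded serine-hydrolase designs: methods and design choices"
author: "ScaffoldScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening re-scaffolded serine-hydrolase designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ScaffoldScreen)
```

## The problem this package addresses

PET hydrolases such as the leaf-branch compost cutinase (LCC, 258 residues,
27.78 kDa) hydrolyze the ester bonds of polyethylene terephthalate with a
conserved Ser-His-Asp catalytic triad (S165/H242/D210 in that template).
Generative protein design can re-scaffold such a triad: the template
segments carrying the catalytic machinery are kept fixed, and an inpainting
model fills in a new - typically much shorter - protein around them. Most
generated sequences are not viable, so the workflow lives or dies by its
computational triage: of the candidate pool only a small fraction survives
screening, and sequence-level artifacts that escape the screen surface later
as unexpressible or inactive protein.

ScaffoldScreen implements that triage as a testable pipeline. It covers:

1. **Motif specification** - which template segments are retained, the triad
   role assignment, and the contig strings handed to an external inpainting
   model.
2. **Static structural quality** - prediction confidence (mean pLDDT, pTM)
   and motif-fidelity RMSD after optimal superposition.
3. **Active-site audit** - nucleophilic attack distance, oxyanion-hole
   donors, triad hydrogen-bond geometry, docking-energy window.
4. **Stability** - trajectory C\\(\alpha\\)-RMSD against a gate within a time
   horizon.
5. **Surface and sequence pathology** - solvent-accessible surface area,
   exposed hydrophobic patches, single-amino-acid repeats (SAAR) and
   consecutive hydrophobic runs (CHAA), and redesign masks for iterative
   refinement.
6. **Kinetics** - Michaelis-Menten fitting of rate data for the designs
   that make it to the bench.

The deep-learning generators themselves (inpainting, structure prediction,
sequence design), the docking engine and the MD engine are deliberately out
of scope; their outputs enter through file interfaces (PDB, FASTA, tabular
energies, multi-model PDB trajectories).

## Screening model and assumptions

A candidate carries up to seven scores and passes through four gates in a
fixed order, mirroring the design workflow's narrative: static quality,
docking, stability, pathology. The default thresholds are:

| Criterion | Default | Boundary semantics |
|---|---|---|
| mean pLDDT | > 70 | strict: exactly 70 fails |
| pTM | > 0.7 | strict |
| motif RMSD | <= 2.5 A | inclusive: exactly 2.5 passes (only *larger* values are discarded) |
| docking energy | [-4, 0] kcal/mol | inclusive at both ends |
| attack distance | < 4 A | strict |
| oxyanion donors | >= 2 backbone N within 3.5 A | inclusive |
| trajectory RMSD | <= 5 A within 20 ns | strict exceedance fails; excursions after the horizon are ignored |

The boundary semantics follow the wording of the thresholds themselves
("greater than", "larger than ... discarded", a closed energy range); where
the wording leaves a boundary open we chose the inclusive reading and fixed
it here. The screen short-circuits at the first failed gate by default;
`ScreenConfig(exhaustive = TRUE)` evaluates all stages for diagnostics.
Tightening any single threshold can only shrink the accepted set; this
monotonicity is property-tested.

Assumptions worth knowing:

* **Heavy atoms only.** All geometry criteria use heavy-atom distances;
  hydrogens are never required or modelled. The oxyanion-hole criterion is
  operationalized as at least two backbone amide nitrogens within 3.5 A of
  the ester carbonyl oxygen (prolines excluded - no amide H). Structural
  figures of docked designs typically show exactly two such NH donors; the
  required count is configurable because the original criterion is stated
  qualitatively.
* **Canonical triad arrangement.** His NE2 faces the Ser nucleophile, His
  ND1 hydrogen-bonds the Asp carboxylate; the Asp contact takes the nearer
  of OD1/OD2.
* **Mean pLDDT.** The model-level confidence gate uses the arithmetic mean
  of C\\(\alpha\\) B-factors. Whether the original gate was mean- or
  minimum-based is not stated; the mean matches how model-level pLDDT is
  conventionally reported, and the choice is isolated in `meanPlddt()`.
* **Candidates without a score for a later stage** (no docked pose, no
  trajectory) are not failed by that stage - the criterion is simply not
  assessed. Candidates without a sequence skip the pathology stage.

## Superposition and motif fidelity

`kabschSuperpose()` computes the least-squares rigid superposition by
singular value decomposition, constrained to a proper rotation
(det = +1). `motifRmsd()` extracts the backbone atoms of the retained
segments on both sides - by default the full backbone {N, CA, C, O} rather
than C\\(\alpha\\) only, since "backbone atoms" is the stated basis of the
fidelity measure - and reports the minimized RMSD. Degenerate (collinear)
point sets are refused rather than silently resolved. The implementation is
cross-checked in the test suite against a numeric minimizer over rotation
angles and translations (agreement to 1e-6 A) and against the property that
no random rigid transform beats the returned RMSD.

Correspondence between template and design residues comes from design
metadata (`motifCorrespondence()` with the design's kept-segment table);
when omitted, identical author numbering is assumed. Sequence-alignment
-based recovery of a lost correspondence is a non-goal.

## Contig strings

`contigString()` emits the alternating kept-segment / gap-range grammar
used by common inpainting tools (`A150-175/24-35/...`). Gap budgets are
distributed as evenly as possible over the slots before, between and after
the kept segments, so that choosing every minimal (maximal) gap reproduces
the target minimum (maximum) total length exactly; `parseContigString()`
inverts the grammar and is round-trip-tested. For the bundled template
spec - three segments totalling 44 residues on a 258-residue template - a
140-185 residue budget yields designs 28-46% shorter than the template.

## SASA and hydrophobic patches

`shrakeRupleySasa()` is a classic Shrake-Rupley implementation: each atom's
accessible sphere (van der Waals radius + 1.4 A probe) is sampled with a
deterministic golden-spiral lattice (default 960 points, chosen so that an
isolated atom reproduces its analytic sphere area to well under 0.5% and
doubling the density moves a 30-residue structure's total by less than 2%);
points occluded by any neighbour's accessible sphere are removed. Bondi-type
van der Waals radii are built in; an unknown element is an error, not a
default. Relative exposure divides each residue's area by a fixed
theoretical maximum per residue type (Tien et al.-style table), so values
slightly above 1 are possible and meaningful.

`hydrophobicPatches()` clusters exposed hydrophobic residues (default set
{ALA, VAL, LEU, ILE, MET, PHE, TRP} - cysteine excluded because its burial
statistics are dominated by disulfides; relative exposure >= 0.25) by
single linkage on C\\(\beta\\) distance (C\\(\alpha\\) for glycine) at 8 A.
Single linkage at a cutoff equals connected components of the
"distance <= cutoff" graph, which is how the oracle in the test suite
computes it. Patch membership is a partition, and patches are reported
largest-area first, since the largest exposed patch is the usual
aggregation suspect.

## Sequence pathology and redesign masks

Inpainting models tend to emit homopolymeric repeats (SAAR, e.g.
`LLLLLLL`) and uninterrupted hydrophobic runs (CHAA, e.g. `LVVLV`), which
correlate with misfolding and poor expression. `findSaar()`/`findChaa()`
report maximal runs at a default minimum length of 5 - the published
examples are 5-8 residues long, but no hard threshold is printed, so the
value is a documented, configurable choice rather than a claim. A run that
is both (a homopolymer over hydrophobic letters) is reported once, as SAAR.

`redesignMask()` marks flagged spans plus surface-patch positions for
re-inpainting, extends each by a 2-residue flank so the generator can
rebuild local context, and forces motif positions to stay fixed; conflicts
resolve in favour of protection and are reported. All positions in this
package are 1-based inclusive, the natural R convention. The emitted contig
uses fixed-length gaps (`11-11`) so that redesign preserves overall length.

## Kinetics

`fitMichaelisMenten()` fits \\(v = V_{max} S / (K_m + S)\\) by
Levenberg-Marquardt nonlinear least squares on the untransformed model -
Lineweaver-Burk linearization is avoided because it distorts the error
structure and biases both parameters. Substrate load is in g/L: PET is
polymeric and insoluble, so molar substrate concentrations are undefined.
Starting values default to `vmax0 = max(rate)` and the substrate load at
half-maximal rate. Standard errors come from the Jacobian at the optimum,
and a fit whose \\(K_m\\) exceeds the sampled substrate range warns that
\\(V_{max}\\) is extrapolated.

`catalyticEfficiency()` is defined strictly as \\(V_{max}/K_m\\), in
(uM/min)/(g/L). Published efficiencies for PET hydrolases are often quoted
in L g^-1 min^-1 after normalizing by enzyme concentration; that conversion
requires the enzyme load, which this package does not model, so no such
normalization is attempted or implied.

## Synthetic fixtures: what they emulate, and what they do not

The generators in this package exist so that every screening operation is
testable without downloads, with known ground truth:

* `makeToyScaffold()` builds an ideal helical backbone with a planted
  Ser/His/Asp pseudo-triad whose hydrogen-bond distances hit their targets
  exactly, plus optional planted hydrophobic surface patches. A small
  seeded coordinate jitter (SD 0.02 A) makes scaffolds differ across seeds
  without disturbing the planted geometry.
* `perturbToRmsd()` adds a random displacement field whose scale is set by
  one-dimensional root finding on the *post-superposition* RMSD of the
  measured atom set, so the advertised RMSD is guaranteed to 1e-3 A rather
  than approximated. `makeDriftTrajectory()` chains this into trajectories
  with prescribed RMSD schedules.
* `makePoseAtDistance()` plants a six-atom ester fragment - the smallest
  unit that exercises ester auto-annotation - at an exact attack distance,
  clash-free at 2.4 A (the engineered nucleophile-carbonyl contact itself
  exempted when the requested distance is below 2.4 A).
* `makeMmDataset()` generates Michaelis-Menten rates with multiplicative
  Gaussian noise and records the generating truth.
* `makeCandidateBatch()` plants prescribed failure counts per screening
  stage so bookkeeping can be checked exactly.

These fixtures validate the *decision machinery*, not the biology: a toy
helix is not a cutinase fold, planted pseudo-atoms carry no rotamer
physics, drift trajectories are not thermodynamic ensembles, and planted
score distributions do not reproduce the correlations of real design
pools. Passing tests therefore demonstrate that the gates compute and
compose correctly at their thresholds - they say nothing about whether a
particular real design will express or hydrolyze PET.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
toy scaffolds of 24-60 residues, SASA convergence on 30 residues at
960 vs 4000 sphere points, kinetics recovery over 200 replicates of
8-point datasets at 5% noise, and screening batches of 20-50 candidates.
These sizes were chosen as the smallest at which each property is
non-trivially exercised (multiple segments, multiple patches, identifiable
fits), and they keep the full suite under a minute of compute on a single
core.

Other numerical choices: superposition tolerances are absolute (1e-8 A for
rigid-motion identities, 1e-6 A against the numeric oracle); percent
reductions round half away from zero to match integer reporting
conventions; candidate ranking breaks full ties lexicographically by id so
reports are byte-identical across runs; and every generator restores the
caller's RNG state.

## Known limitations

* PDB is the only structure dialect (models, chains, altlocs, insertion
  codes); mmCIF, assemblies and hydrogens are out of scope. Altloc policy:
  highest occupancy wins, first-encountered on ties.
* Binary trajectory formats (XTC/DCD) are not read; trajectories enter as
  multi-model PDB.
* The pathology detectors are pattern-based; they do not predict disorder
  or aggregation propensity beyond the run/patch definitions above.
* `sequenceMass()` is undefined for sequences containing non-standard
  residues (`X`) rather than guessing a placeholder mass.
* The screen consumes scores; computing every score from raw artifacts
  end-to-end (docking, MD) is the user's pipeline, not the package's.
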