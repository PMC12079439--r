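# ScaffoldScreen

Computational triage for *de novo* enzyme designs that re-scaffold the
catalytic machinery of a template serine hydrolase — the setting is
PET-hydrolase engineering, where the Ser-His-Asp triad of a cutinase-class
template (e.g. leaf-branch compost cutinase, 258 aa, 27.78 kDa) is kept
fixed and a generative model inpaints a new, smaller protein around it.
Most generated sequences fail; this package implements the multi-criteria
screen that decides which survive, for structural bioinformaticians running
such design campaigns.

## What it computes

A candidate design passes four gates, in order:

1. **Static quality** — mean pLDDT > 70, pTM > 0.7, and motif RMSD
   ≤ 2.5 Å, where the motif RMSD is the backbone (N, CA, C, O) RMSD of the
   retained template segments after optimal rigid-body superposition
   (Kabsch, via SVD):
   `RMSD = min over rotations R, translations t of sqrt(mean ||a_i − (R b_i + t)||²)`.
2. **Active site** — docking energy within [−4, 0] kcal/mol; nucleophilic
   attack distance d(Ser Oγ, ester carbonyl C) < 4 Å; an oxyanion hole of
   ≥ 2 backbone amide N within 3.5 Å of the carbonyl O; triad H-bonds
   (Ser Oγ–His NE2, His ND1–Asp Oδ) at ≤ 3.5 Å.
3. **Stability** — trajectory Cα RMSD never exceeding 5 Å within a 20 ns
   horizon.
4. **Sequence pathology** — no single-amino-acid repeats (SAAR, `LLLLLLL`)
   or consecutive hydrophobic runs (CHAA, `LVVLV`) of length ≥ 5; exposed
   hydrophobic surface patches (Shrake–Rupley SASA + single-linkage
   clustering) feed a redesign mask for iterative re-inpainting.

Supporting machinery: PDB/FASTA/multi-model-PDB I/O, contig-string
generation for inpainting, per-design size metrics, deterministic ranking
and TSV/JSON reports, Michaelis–Menten fitting
(v = Vmax·S/(Km + S), nonlinear least squares), and synthetic-fixture
generators (toy scaffolds with planted triads, exact-RMSD perturbations,
drifting trajectories, poses at prescribed attack distances, rate data with
known truth) so the whole pipeline is testable without external data.

## Worked example

```r
library(ScaffoldScreen)

## the retained catalytic motifs of a 258-residue template
spec <- MotifSpec(
  segments  = data.frame(chain = "A", start = c(150, 205, 239),
                         end = c(175, 215, 245)),
  catalytic = data.frame(role = c("nucleophile", "base", "acid"),
                         chain = "A", resnum = c(165, 210, 242)))
unlist(specSummary(spec, templateLength = 258))
#>   retained_count retained_percent
#>               44               17

## contig handed to the inpainting model for 140-185 residue designs
contigString(spec, templateLength = 258, targetLength = c(140, 185))
#> [1] "24-36/A150-175/24-35/A205-215/24-35/A239-245/24-35"

## motif fidelity of a (synthetic) design perturbed to 2.0 A
template <- makeToyScaffold(nResidues = 60, seed = 7)
design   <- perturbToRmsd(template, 2.0, seed = 8)
allres <- MotifSpec(data.frame(chain = "A", start = 1, end = 60),
                    data.frame(role = c("nucleophile", "base", "acid"),
                               chain = "A", resnum = c(10, 12, 14)))
motifRmsd(template, design, allres)
#> [1] 2        # <= 2.5 A: passes the fidelity gate

## screen a 20-candidate batch with planted failures
batch  <- makeCandidateBatch(n = 20, nLowPlddt = 5, nHighRmsd = 4,
                             nBadEnergy = 3, nUnstable = 2, seed = 1)
report <- runScreen(batch)
report
#> ScreenReport: 20 candidates | static 11, docked 8, stable 6, accepted 6
head(rankCandidates(report), 3)
#> [1] "cand11" "cand19" "cand06"

## Michaelis-Menten fit of rate data (substrate in g/L, rate in uM/min)
fit <- fitMichaelisMenten(makeMmDataset(vmax = 0.55, km = 0.72,
          substrateGrid = seq(0.1, 5, length.out = 8)))
fit
#> MMFit: Vmax = 0.55 +/- 1.2e-16 uM/min, Km = 0.72 +/- 6.9e-16 g/L (converged)
catalyticEfficiency(fit)   # Vmax/Km, (uM/min)/(g/L)
#> [1] 0.7638889
```

Reading the numbers: the three retained segments cover 44 residues (17% of
the template); the contig string budgets gaps so designs span 140–185
residues (28–46% shorter than the template). The screen report shows the
staged attrition of the planted batch — 9 static failures, 3 docking
failures, 2 stability failures, 6 accepted — and the ranking orders
accepted designs by motif fidelity, then binding energy, then confidence.
The kinetics fit recovers the generating parameters exactly on noiseless
data; `catalyticEfficiency()` is the plain Vmax/Km ratio (see the vignette
for why no enzyme-concentration normalization is applied).

The methods vignette (`vignettes/scaffold-screening.Rmd`) documents the
model, parameter defaults, boundary semantics, numerical choices and the
limits of what the synthetic fixtures demonstrate.

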