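Package: ScaffoldScreen
Title: Computational Screening of Re-Scaffolded Serine-Hydrolase Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational triage of de novo enzyme designs
    that re-scaffold the catalytic machinery of a template serine hydrolase
    (e.g. a PET-degrading cutinase). Covers catalytic-motif extraction and
    contig specification for inpainting, rigid-body (Kabsch) superposition
    and motif-RMSD fidelity screening, active-site geometric audits
    (nucleophilic attack distance, oxyanion-hole donors, triad hydrogen
    bonds, docking-energy windows), trajectory Calpha-RMSD stability gates,
    Shrake-Rupley solvent-accessible surface area with hydrophobic-patch
    detection, sequence-pathology detection (single-amino-acid repeats and
    hydrophobic runs) with redesign-mask generation, Michaelis-Menten
    kinetics fitting, and a multi-criteria screening pipeline with
    deterministic reports. Includes generators for synthetic scaffolds,
    poses, trajectories and rate data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'StructureModel-methods.R'
    'active-site.R'
    'motif-scaffold.R'
    'fixtures.R'
    'kinetics.R'
    'model-io.R'
    'sequence-pathology.R'
    'stability-surface.R'
    'screening.R'
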