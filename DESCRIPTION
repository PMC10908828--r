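Package: ChaperoneDynamics
Title: Interaction Energetics, Implicit Solvation and Cavity Analysis of
    Chaperone-Client Complexes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of molecular-dynamics trajectories and
    cryo-EM models of chaperone-client assemblies such as the
    RAF1-HSP90-CDC37 complex. Provides residue-pairwise decomposition of
    coulombic and van der Waals interaction energies with multi-replica
    statistics, MM-GBSA binding free energies with OBC-II generalized-Born
    solvation and Shrake-Rupley surface areas, RMSF-based B-factors with
    cross-state normalization, essential-dynamics principal component
    analysis, voxel-grid volumetrics of interfacial (luminal) cavities with
    client occupancy, alignment-guided Kabsch superposition and RMSD,
    peptide physicochemical descriptors, and a deterministic synthetic-data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: StructuralBioinformatics, Proteomics, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ChaperoneDynamics-package.R'
    'cavity.R'
    'fluctuations.R'
    'comparative.R'
    'core-io.R'
    'descriptors.R'
    'gbsa.R'
    'pair-energetics.R'
    'parameters.R'
    'pipeline.R'
    'selections.R'
    'synthetic.R'
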