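Package: ttbscan
Title: Detection and Energy Estimation of Backbone C=O...C=O Tetrel Bonds
    in Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies carbonyl-carbonyl (n->pi*, tetrel-bond) contacts in
    peptide and protein backbones from multi-model PDB structures, scores
    their Burgi-Dunitz approach geometry, and estimates interaction energies
    through an electron-density calibration fitted on small bimolecular model
    complexes with a half-energy partition for ancillary contacts. Includes
    per-residue-pair distance distributions over conformational ensembles,
    RMSD-based hierarchical clustering of frames, and a synthetic backbone
    generator producing alpha-helical and disordered ensembles from internal
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
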