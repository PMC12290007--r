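Package: surfpep
Title: Sequence Effects in Peptide Adsorption on TiO2 Surfaces from MD
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics studies of
    hexapeptide adsorption on hydroxylated anatase TiO2 (101) surfaces.
    Builds residue-permutation sequence libraries with reverse-pair
    deduplication and motif statistics, computes per-frame surface
    separation distance (SSD) and end-to-end distance (EED) with
    bound-state classification and binding-fraction ranking, clusters
    adsorbed conformations with the GROMOS neighbor-count algorithm on
    Kabsch-superposed RMSDs, computes typed-atom radial distribution
    functions against surface oxygens including conditional RDFs for
    bridging sodium ions, constructs hydroxylated anatase (101) slab
    models, and generates synthetic trajectories with planted ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
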