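Package: ahrscreen
Title: Consensus Virtual Screening for Aryl Hydrocarbon Receptor Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand- and structure-informed consensus virtual-screening
    pipeline for prioritizing potential aryl hydrocarbon receptor (AhR)
    ligands in industrial-chemical inventories. The pipeline standardizes
    chemical libraries, computes 2D molecular descriptors and 166-key
    structural fingerprints, filters candidates through a principal-component
    applicability domain (Hotelling T2 and DModX at 95 percent), enriches
    hits by three parallel methods (MACCS/Tanimoto fingerprint similarity,
    nearest neighbors in principal-component property space, and a
    docking-score gate on externally computed binding free energies), groups
    hits by flexible-beta hierarchical clustering, fuses the methods by
    k-of-n consensus voting, and evaluates predictions against activity
    labels with accuracy, sensitivity, and specificity. A seeded synthetic
    library generator provides self-contained benchmarks with planted
    binder analogs and decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR
SystemRequirements: Python (>= 3.8) with the RDKit package, available as
    'python' on the PATH (override with option 'ahrscreen.python' or the
    AHRSCREEN_PYTHON environment variable).
Config/testthat/edition: 3
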