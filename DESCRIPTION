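Package: mirrorsep
Title: Separating Properly Oriented and Mirror-Image Protein Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting and filtering mirror-image artifacts in protein
    structure ensembles reconstructed from residue-residue contact maps. Contact
    maps encode distances but not chirality, so reconstruction pipelines emit a
    mixture of properly oriented models and their mirror images. The package
    computes backbone dihedral chirality statistics (the Phi+ ratio), classifies
    residues into Ramachandran favored/allowed/outlier regions, evaluates
    knowledge-based phi/psi scores sensitive to helix handedness, assigns model
    orientation by Kabsch superposition against a reference structure and its
    ideal mirror image, and runs per-energy-term group-significance and
    normalized-mean (NMT) analyses across domains. A synthetic-data module
    generates labeled ensembles of noisy right- or left-handed helical bundles
    spanning distinct, moderate and indistinct RMSD-separation regimes so the
    whole pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
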