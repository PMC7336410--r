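Package: pnhot
Title: Hot-Spot Residue Prediction on Protein-Nucleic-Acid Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies hot-spot residues on protein-DNA and protein-RNA
    interfaces from bound complex structures.  Computes a 97-feature
    structural and sequence characterization of interface residues
    (solvent accessible surface area in bound and unbound states, depth
    and protrusion indices, screened-Coulomb electrostatic potential
    summaries, interface hydrogen-bond counts, secondary structure,
    PSSM-derived conservation, and amino-acid physicochemical
    properties), labels residues from alanine-scanning ddG tables, and
    trains a radial-basis-function support vector machine after a
    two-step feature selection (CART decision tree followed by a beam
    sequential forward search scored by cross-validated F1).  Includes
    leave-one-residue-out and leave-one-complex-out cross-validation,
    a full classification metric suite with ROC and precision-recall
    curves, and deterministic generators of synthetic complexes, PSSM
    profiles and planted benchmark datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    e1071,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
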