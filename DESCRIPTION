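Package: relmol
Title: Relational Molecule Model and AMBER-Style System Preparation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A foundational molecular-modelling toolkit built on a relational
    (non-hierarchical) molecule data model: a molecule owns its atoms, bonds,
    residues, angles and torsions directly, and all containment is expressed
    as adjacency relations between typed object tables with base-40 hashed
    property keys. On top of the model the package provides readers and
    writers for PDB, MOL2 and MOL/SDF, a SMILES reader and SMARTS
    substructure matcher, an AMBER-style atom-mask selection language,
    solvent shell/box/cap/truncated-octahedron construction with ion
    placement, AMBER force-field parameter parsing with bonded, direct
    nonbonded and Generalized Born energy evaluation, an AMBER prmtop and
    coordinate writer, and a LEaP-like command interpreter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
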