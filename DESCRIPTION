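Package: cyptemplate
Title: Fused Hexagonal-Grid Template Modelling of CYP2J2 Ligand Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An executable model of the CYP2J2 fused hexagonal-grid Template:
    a canonical grid geometry with named regions (Rings, Positions, Shelf,
    Left-end, Entrance, Site of oxidation), a parser for the hyphen-linked
    ring-path placement notation, annotated heavy-atom ligand graphs built
    from SMILES or SDF input, a rule engine for the ligand-interaction
    criteria (Width-gauge, simultaneous plural Rear-wall contact, Ring B
    occupancy, Site-of-oxidation occupancy, lactone restrictions,
    Trigger-residue fastening), a constrained graph-to-lattice placement
    search with a brute-force oracle, and bi-molecule (pro-metabolized plus
    trigger molecule) co-placement evaluation.  Worked ligand placements are
    shipped as machine-readable fixtures and replayed as a concordance suite
    so substrate, poor-substrate and inhibitor verdicts and predicted sites
    of oxidation can be reproduced.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    ChemmineR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
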