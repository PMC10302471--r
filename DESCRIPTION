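Package: polyforge
Title: Automated Construction of Polymer Molecular Models from Decorated Monomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds molecular models of linear, ring, branched, diblock,
    random and pattern-specified polymers from monomers decorated with
    placeholder atoms that mark the polymerization sites. Monomers are read
    from SMILES strings or MOL/SDF, PDB and XYZ files; built polymers are
    relaxed with the MMFF94 or UFF classical force fields through Open
    Babel. Inter-ring torsional angles of conjugated polymers are detected
    automatically from the molecular graph and exported as 2D sketches.
    High-throughput helpers create uniquely named folders, relocate files
    by extension, dispatch independent tasks in parallel and assemble
    external-calculator command lines (GFN2-xTB, GFN-FF, SCF engines)
    without running them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    parallel,
    igraph,
    S4Vectors,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: Open Babel (obabel, obenergy on the PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
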