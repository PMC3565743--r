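Package: rsfcd
Title: Fold-Change Detection in Rhodobacter sphaeroides Chemotaxis Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamical models of the Rhodobacter sphaeroides chemotaxis
    pathway built from Monod-Wyman-Changeux (MWC) allosteric receptor
    clusters, a CheA/CheB/CheY mass-action phosphotransfer network and a
    Hill-type flagellar output. Provides three pathway variants differing
    in how external ligand is conveyed to the cytoplasmic receptor
    cluster, an experiment harness for testing exact adaptation and
    fold-change detection (scale invariance) of transient responses,
    in-silico gene-deletion protocols, a synthetic tethered-cell assay
    generator, and simulated-annealing parameter fitting with
    identifiability diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
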