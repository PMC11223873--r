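Package: pathsense
Title: Retrobiosynthetic Design of Biosensor-Detectable Pathways
Version: 0.1.0
Authors@R: person("Pathsense", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Finds, enumerates, ranks and exports enzymatic "detectable
    pathways" that convert a target bio-based compound into an effector of
    an allosteric transcription factor, so that the target can be sensed
    indirectly through a biosensor circuit. Implements Tanimoto-guided
    Monte Carlo tree search over retro reaction rules (RetroRules-style
    SMARTS with diameter and penalty score), scope-graph construction,
    shortest-branch pathway enumeration, worst-step penalty ranking, and
    classification of pathway compounds against a chassis metabolome into
    precursors, intermediates and supplements. Ships readers for effector,
    producible and chassis metabolome tables (delimited or SBML), a
    seeded toy-chemistry fixture generator, SBML Level 3 and Cytoscape-style
    JSON exporters, and a command-line interface. Chemical identity,
    fingerprints and SMARTS rule application are delegated to an RDKit
    helper process invoked in batches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    xml2,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with rdkit available on the PATH as
    'python'; optionally python-libsbml for strict SBML validation.
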