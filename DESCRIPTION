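Package: xenonet
Title: Cross-Sectional Drug-Metabolite Elucidation by Molecular Networking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for elucidating xenobiotic metabolism from LC-HRMS/MS data in a
    cross-sectional in silico / in vitro / in vivo design. Provides exact elemental
    formula arithmetic, rule-based phase I/II metabolite candidate generation from a
    parent SMILES, MS/MS molecular networking with modified-cosine spectral
    similarity, biotransformation mass-shift annotation propagated from the parent
    node, multi-matrix semi-quantitative kinetics, integration of all evidence into a
    metabolite report with canonical isomer naming, and one-compartment
    pharmacokinetic simulation with non-compartmental analysis. Includes a synthetic
    study generator emulating hepatocyte-supernatant and rodent-plasma experiments so
    the whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
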