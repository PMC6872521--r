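Package: proteasplice
Title: Discovery of Proteasome-Generated Spliced Epitope Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in silico pipeline for identifying tumor-specific,
    proteasome-generated spliced and non-spliced epitope candidates.
    Ranks candidate antigens by a Bayesian feature-sum model over protein
    physicochemical characteristics (length, hydropathy, isoelectric
    point, instability) fitted by Markov chain Monte Carlo; exhaustively
    enumerates theoretical non-spliced and cis-spliced peptide products
    of a substrate and maps observed peptides to splice-reactant
    decompositions (non-spliced, cis, trans); filters candidates by
    mutation coverage, length and predicted HLA class I binding
    affinity; and quantifies in vitro proteasome digestion products
    (PSM and kinetic filtering, titration-based absolute quantification,
    site-specific cleavage-strength SCS-P1 and splicing-site PSP-P1
    profiles). Includes synthetic-data generators for closed-loop
    validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
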