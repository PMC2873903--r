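Package: dmiminer
Title: Structure-Based Discovery of Domain-Motif Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate domain-motif interactions (DMIs) in
    three-dimensional protein structures. Peptide windows outside annotated
    sequence domains are scored for motif-like geometry (linearity,
    elongation, secondary structure, accessibility) with a cost-weighted
    linear support vector machine, filtered by domain contact, interface
    area and stoichiometry rules, clustered by interface topology and by
    combined domain/peptide sequence identity, and summarised as consensus
    motif patterns whose significance is assessed against a background
    amino-acid model. Derived motifs can be cross-validated by enrichment
    among interaction partners in protein-protein interaction networks
    using one-sided Fisher's exact tests. Includes deterministic synthetic
    generators (ideal peptide geometries, toy domain-peptide complexes,
    planted-motif sequence sets, planted-enrichment networks) so that
    every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
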