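Package: silacint
Title: SILAC Proteome-Secretome-Transcriptome Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative integration of 3-plex SILAC proteome and secretome
    fold changes with matched transcriptome profiles, as used in time-course
    studies of TLR-stimulated macrophages. Provides MaxQuant-style
    protein-groups ingestion, median-ratio normalization, reliability
    filtering, empirical fold-change thresholds derived from an unstimulated
    basal time course, cross-condition comparison (overlap matrices,
    principal component analysis, hierarchical clustering, strong-changer
    selection), gene-symbol-level merging with transcript fold changes,
    Pearson correlation grids, and classification of discordant
    (post-transcriptionally regulated) proteins. A synthetic-data module
    emulates the triple-label, four-replicate design with planted effects so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
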