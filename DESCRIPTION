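Package: mirsite
Title: miRNA Binding-Site Scanning, Localization and Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans mRNA sequences for miRNA binding sites scored by a
    hydrogen-bond hybridization free-energy model and the dG/dGm
    complementarity ratio, localizes hits to the 5'UTR, CDS and 3'UTR,
    translates CDS-overlapping sites in all three reading frames to
    detect encoded oligopeptides and stop codons, and quantifies site
    conservation across orthologous transcripts with per-position
    substitution profiles and frequency matrices. Includes a seedable
    synthetic-data generator that plants sites with a known manifest so
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
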