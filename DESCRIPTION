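Package: refstab
Title: Cross-Species Reference-Gene Stability Screening for Expression Microarrays
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether two related species share organ-specific
    reference (housekeeping) genes from paired microarray log-ratio datasets.
    Implements cross-dataset Z-score normalization, per-probe coefficient-of-
    variation ranking with lowest-decile selection, a model-based stability
    index (intragroup variance plus shrunken intergroup deviation, in the
    NormFinder family), a bootstrap null for the overlap of two candidate
    probe lists, Fisher-z significance tests for Spearman rank correlations,
    and a Welch-test comparison of the transcriptome correlation of invariant
    versus randomly chosen probes. Includes a reader/writer for the GEO
    series-matrix dialect and a seeded generator of paired two-species
    synthetic datasets so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
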