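Package: lightscreen
Title: Protein-Domain Abundance Screening of High-Light and Low-Light
    Adapted Cyanobacterial Ecotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for contrasting protein-domain
    (Pfam) content between high-light and low-light adapted Prochlorococcus
    ecotypes. Parses HMMER3 per-domain tables into normalized genome-by-domain
    sum-bit-score matrices; screens every domain family with FDR- and
    outlier-corrected robust tests including practical-difference and
    two-one-sided-test (TOST) equivalence calls; orders genomes and domains by
    hierarchical bi-clustering and partial least squares; classifies ecotype
    membership with a boosted ensemble of small TanH neural networks and
    reports variance-based variable importance; counts endogenous viral-family
    (VFam) signatures co-occurring with discriminant Pfams; performs
    domain-centric GO enrichment; and designs Gateway attL-flanked ORFeome
    constructs. A synthetic-data generator reproduces the statistical
    structure of the real inputs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
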