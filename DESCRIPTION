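Package: fungiqpcr
Title: In Silico Primer Screening and Real-Time qPCR Quantification of Soil Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen degenerate PCR primer sets against taxonomically
    annotated 18S rRNA sequence collections and to quantify fungal abundance in
    soil from real-time quantitative PCR plates. The screening side provides
    IUPAC/inosine-aware mismatch-tolerant primer matching, in-silico amplicon
    prediction, per-group specificity and coverage profiling, k2/k0 ratio and
    amplicon-length filters, and hierarchical clustering of hit profiles
    against a theoretical optimal primer set. The qPCR side provides standard
    curves, amplification efficiency, detection limits, replicate variability,
    conversion to gene copies per gram of dry soil, Kruskal-Wallis tests with
    Dunn post-hoc letters, and Pearson correlation screens against soil
    physico-chemical variables. Seeded synthetic-data generators plant primer
    binding sites at controlled mismatch counts and simulate qPCR plates from a
    known standard curve, giving exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    seqinr,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
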