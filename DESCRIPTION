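Package: retroscape
Title: Structural Annotation, Dating and Marker Analysis of LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of long-terminal-repeat (LTR)
    retrotransposons in plant genome assemblies: de novo structural
    detection of full-length elements (both LTRs present), protein-domain
    and homology-based classification into the Copia and Gypsy
    superfamilies and their lineages, insertion-time estimation from
    LTR-pair and read-pair divergence under the Kimura two-parameter
    model, genome-proportion estimation by read mapping, in-silico
    inter-retrotransposon amplified polymorphism (IRAP) fingerprinting
    with admixture-based population-structure inference and Evanno delta-K
    model selection, and enrichment testing of primer occurrences near
    focal gene sets.  A synthetic-genome and marker-population simulator
    with known truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
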