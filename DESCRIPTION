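Package: ablayers
Title: Depth-Resolved Proteome Analysis of Serially Ablated Tissue Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spatially resolved proteomics of serially
    ablated tissue layers, as produced by nanosecond-infrared-laser depth
    profiling of the embryonic mouse cortex. Provides median normalization and
    reference-class batch correction of log2 abundance matrices, resampling
    consensus clustering of ablated layers, moderated per-layer differential
    abundance with unique top-10 layer signatures, correlation-based mapping of
    layer identity across genotypes, single-sample gene-set z-scoring with
    linear depth-gradient filtering, Best-Match/DiffScore deconvolution of
    gene-ontology term representation, ANCOVA screening for genotype-specific
    depth profiles, and histomorphometry statistics (distance binning,
    proliferation rates, cell-cycle re-entry tests). A synthetic-data module
    generates manifests, abundance matrices with planted ground truth, gene
    sets, and cell tables emulating the four-genotype, two-timepoint study
    design, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    fgsea,
    emmeans,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
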