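Package: matriomics
Title: Matrisome Annotation, Tabulation and Composition Charts for Omics Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates tabular omics datasets (proteomics, transcriptomics,
    genomics) with extracellular-matrix matrisome divisions and categories
    across five model organisms (human, mouse, zebrafish, fruit fly,
    nematode), resolving identifiers across namespaces (gene symbol, NCBI
    gene, UniProt, Ensembl, ZFIN, FlyBase, WormBase, common gene name).
    Tabulates numeric columns by matrisome annotation, extracts protein
    identifiers from minimal Skyline XML documents, and renders the four
    matrisome composition chart types: bar (matribar), donut (matriring),
    polar bar (matristar) and alluvial (matriflow). Includes a deterministic
    synthetic-fixture generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
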