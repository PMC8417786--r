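Package: cytolit
Title: Literature-Mined Cytokine Networks in Lysosomal Storage Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative text-mining and network analysis of cytokine
    signaling in lysosomal storage diseases (Gaucher disease, acid
    sphingomyelinase deficiency, Fabry disease). Builds concept
    dictionaries with linguistic variant expansion, extracts directional
    disease-cytokine relations from sentence-segmented literature
    corpora, tests immune cell-type specificity of mined cytokines by
    overrepresentation analysis against a blood expression atlas,
    reconstructs transcription factor to cytokine regulatory networks
    filtered by cell-type expression with co-expression testing, and
    scores directed cell-cell communication networks from ligand-receptor
    pair counts with percentile thresholding. Includes a synthetic-data
    generator that plants ground-truth associations so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    fgsea,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
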