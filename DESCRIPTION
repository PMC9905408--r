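Package: scarscape
Title: Spatiotemporal Architecture of the Spinal Cord Glial Scar from Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spot-based spatial transcriptomics of central
    nervous system lesions. Provides a synthetic Visium-like lesion generator
    (hexagonal spot lattices, concentric time-varying scar domains, negative
    binomial counts with cell-type marker programs, planted ligand-receptor
    pairs and co-expression blocks), readers and writers for the standard file
    formats (Matrix Market counts, tissue positions, GMT gene sets), spot QC
    and log normalization, highly-variable-gene selection, PCA plus k-means
    domain labeling, scar geometry (neighbor graphs, scar center and radius,
    layer bands, two-spot-wide cluster interface extraction, cell-type
    fraction time courses), per-spot gene-set scoring (bin-matched module
    scores and rank-based pathway activity with layer profiles), a
    boundary-restricted ligand-receptor permutation test, and k-means
    co-expression module detection with hierarchical submodules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
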