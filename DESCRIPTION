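Package: tecage
Title: Simulation and Statistical Toolkit for Thymic Epithelial Cell Ageing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational methods for studying age-dependent changes in the
    thymic stroma and T cell selection. Provides a T cell receptor V(D)J
    rearrangement simulator with repertoire saturation and clonotype diversity
    statistics; quality control, size-factor normalisation and highly variable
    gene selection for plate- and droplet-based single-cell RNA-seq counts; a
    gene frequency-inverse cell frequency (GF-ICF) transform with shared
    nearest neighbour graph construction, Walktrap community detection,
    consensus robustness scoring and k-nearest-neighbour label transfer;
    a hashtag-oligonucleotide demultiplexer based on per-tag negative binomial
    background thresholds; the tau index of tissue-restricted antigen
    expression with per-cell tissue representation counting; diffusion map
    pseudotime with Gaussian mixture meta-stable state assignment; and
    negative binomial and Poisson regression models of age-dependent cell
    abundance, thymocyte selection and gene expression trends. Synthetic data
    generators emulating each input type make the full pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    mclust,
    edgeR,
    limma,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    scran,
    SingleCellExperiment,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
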