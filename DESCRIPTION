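Package: spadom
Title: Spatial Domain Detection for Spatial Transcriptomics via Graph
    Variational Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies spatial domains in spatial transcriptomics data by
    augmenting each spot's expression with spatially and morphologically
    weighted neighbour expression, embedding the augmented matrix with a
    joint denoising autoencoder and variational graph autoencoder, optionally
    aligning multiple batches with a domain-adversarial head trained through
    a gradient-reversal layer, and clustering the latent embedding with
    Leiden community detection. Includes Visium-style and generic table
    readers, a negative-binomial synthetic data generator with planted
    domains, clustering evaluation metrics (adjusted Rand index, silhouette,
    Davies-Bouldin, Calinski-Harabasz), and per-domain Wilcoxon marker
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    optparse,
    png,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
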