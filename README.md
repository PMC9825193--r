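# spadom

Spatial domain detection for spatial transcriptomics in R.

## The problem

Spot-based spatial transcriptomics (10x Visium, Stereo-seq, Slide-seq) and
imaging-based spatial omics (MERFISH, 4i, MIBI-TOF) measure expression at
known tissue positions. The analysis task is to partition the spots into
*spatial domains* — contiguous regions coherent in expression and, where an
H&E image is available, in morphology. Clustering expression alone ignores
the spatial dependency and fragments tissue; `spadom` is for analysts who
want domain calls that use expression, position and histology together, and
who need to integrate multiple slides or platforms into one domain map.

## The method

1. **Neighbour-weighted augmentation.** For spot pairs within a
   data-derived radius γ (mean + variance of pooled 4-nearest-neighbour
   distances), expression is smoothed as

   GE&#771;_i = GE_i + (1/n_i) Σ_j GE_j · MS_ij · GC_ij · SW_ij

   where GC is the expression correlation of the pair, MS the cosine
   similarity of image-tile features (50 PCs of a pluggable extractor;
   dropped when there is no image), and SW the binary in-radius indicator.

2. **Joint embedding.** The augmented, PCA-reduced matrix X is embedded by
   a denoising autoencoder (gene latent Z_g) coupled with a variational
   graph autoencoder on the spatial kNN graph (k = 12, symmetrically
   normalized adjacency Ã = D^{-1/2} A D^{-1/2}; posterior μ, log σ²;
   inner-product edge decoder). The decoder reconstructs X from the
   concatenation [Z_g, Z], and training minimizes
   w_rec·L_rec + w_graph·(BCE + KL) (+ w_domain·L_domain for integration)
   with full-graph Adam, deterministically under one seed.

3. **Batch integration.** For multiple slides, a linear batch classifier is
   attached to the joint latent through a gradient-reversal layer: its
   gradient is flipped (×−λ) on the way into the embedding, training the
   features to defeat the classifier and so removing linearly decodable
   batch signal. Spatial graphs are combined block-diagonally and
   cross-slide pairs are excluded from the edge reconstruction.

4. **Domain calling.** Leiden community detection on a kNN graph of the
   joint latent, scanning resolutions 0.1–2.5 (step 0.01): either the
   lowest resolution with exactly the requested number of domains, or the
   partition maximizing the Calinski–Harabasz score. Evaluation: ARI
   against truth, silhouette, Davies–Bouldin, CH; per-domain markers by
   Wilcoxon rank-sum at 1% FDR.

## Worked example

```r
library(spadom)

sim <- simulate_spots(grid_shape = c(30, 30), n_domains = 7, n_genes = 200,
                      marker_fold = 3, seed = 11)
fit <- spadom(sim$dataset, n_domains = 7, true_labels = sim$labels,
              morphology = sim$morphology, seed = 11)
fit
#> spadom fit
#>   900 spots embedded (z_joint 96-d), 7 domains at resolution 0.54 (fixed_k)
#>   silhouette 0.068 | Davies-Bouldin 3.213 | Calinski-Harabasz 28.1
#>   ARI vs truth: 0.995
plot(fit)   # spatial domain map
```

The fixture plants 7 horizontal expression bands (a layered-cortex-like
geometry) with 10 three-fold marker genes each under negative-binomial
noise; the fit recovers them near-perfectly (ARI 0.99; 1.0 would be an
exact match to the planted labels). `cluster_embedding()` re-clusters an
existing embedding at another domain count or adaptively;
`deg_wilcoxon()` returns the marker table; `read_visium()` /
`read_generic()` load real datasets; `spadom_integrate()` runs the
multi-slide workflow. A thin command-line wrapper is in
`inst/scripts/spadom-cli.R` (subcommands `simulate`, `run`, `integrate`).

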