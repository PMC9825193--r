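#' Simulate a spatial transcriptomics dataset with planted domains
#'
#' Spots are laid out on a rectangular grid (or uniformly at random), split
#' into spatially contiguous domains (horizontal bands, Gaussian blobs, or a
#' Voronoi tessellation of random centers), and counts are drawn from a
#' negative binomial whose mean is boosted by \code{marker_fold} for each
#' domain's marker genes. This emulates the layered-cortex geometry used for
#' benchmarking spatial domain detection: the default is 7 bands (six layers
#' plus a background band). Optional batch structure multiplies each gene in
#' batches 2..B by a log-normal scale factor; optional surrogate morphology
#' features are domain one-hot signal plus Gaussian noise, mimicking
#' histology that correlates with domain identity.
#'
#' @param grid_shape integer (rows, cols) for grid layouts; a single integer
#'   gives that many uniformly random 2D positions.
#' @param n_domains number of planted domains (default 7).
#' @param layout one of \code{"bands"}, \code{"blobs"}, \code{"voronoi"}.
#' @param n_genes number of genes (default 200).
#' @param nb_mean_base baseline negative-binomial mean scale (default 5).
#'   Each gene's base mean is \code{nb_mean_base} times a log-normal factor
#'   (sd \code{gene_mean_sd}), reproducing the orders-of-magnitude spread of
#'   per-gene means in UMI data; this spread is what makes expression
#'   correlation between neighbouring spots informative.
#' @param gene_mean_sd sd of the log-normal per-gene mean factors
#'   (default 1; 0 gives identical means for all genes).
#' @param nb_dispersion dispersion; counts have variance
#'   \code{mu + dispersion * mu^2} (default 0.3).
#' @param marker_genes_per_domain markers per domain (default 10).
#' @param marker_fold mean multiplier of a marker inside its domain
#'   (default 3).
#' @param n_batches number of batches (default 1).
#' @param batch_shift_sd sd of the per-gene log-normal batch scale factors
#'   applied to batches >= 2 (default 0; 0 makes all batches identically
#'   distributed). Batches are replicate slides of the same layout, stacked
#'   spot-wise.
#' @param batch_as_z add a z coordinate equal to the batch index, giving a
#'   3D consecutive-section stack (default FALSE).
#' @param morphology_dim width of the surrogate morphology features
#'   (default 16; 0 disables them).
#' @param morphology_noise_sd Gaussian noise sd on the morphology signal
#'   (default 0.3).
#' @param with_image also paint a synthetic image of coloured domain blocks
#'   and register per-spot pixel coordinates (default FALSE).
#' @param seed RNG seed; the generator is fully deterministic under it.
#' @return list with \code{dataset} (a [spot_dataset]), \code{labels} (factor
#'   of true domains), \code{morphology} (a \code{morphology_features}-shaped
#'   list or NULL), and \code{marker_genes} (character matrix domains x
#'   markers).
#' @export
simulate_spots <- function(grid_shape = c(30, 30), n_domains = 7,
                           layout = c("bands", "blobs", "voronoi"),
                           n_genes = 200, nb_mean_base = 5,
                           gene_mean_sd = 1, nb_dispersion = 0.3,
                           marker_genes_per_domain = 10, marker_fold = 3,
                           n_batches = 1, batch_shift_sd = 0,
                           batch_as_z = FALSE,
                           morphology_dim = 16, morphology_noise_sd = 0.3,
                           with_image = FALSE, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(n_domains >= 1, marker_fold >= 1, nb_dispersion > 0)
  if (marker_genes_per_domain * n_domains > n_genes)
    stop("spec error: marker_genes_per_domain * n_domains exceeds n_genes")
  set.seed(seed)

  if (length(grid_shape) == 2L) {
    rows <- grid_shape[1L]; cols <- grid_shape[2L]
    coords <- cbind(rep(seq_len(rows), each = cols),
                    rep(seq_len(cols), times = rows))
  } else {
    n <- grid_shape
    coords <- cbind(stats::runif(n, 0, sqrt(n)), stats::runif(n, 0, sqrt(n)))
  }
  n <- nrow(coords)

  labels <- switch(layout,
    bands = {
      # n_domains horizontal bands of (nearly) equal height -> contiguous
      rng <- range(coords[, 1L])
      band <- findInterval(coords[, 1L],
                           seq(rng[1L], rng[2L],
                               length.out = n_domains + 1L)[-c(1L, n_domains + 1L)]) + 1L
      band
    },
    blobs = {
      centers <- cbind(stats::runif(n_domains, min(coords[, 1]), max(coords[, 1])),
                       stats::runif(n_domains, min(coords[, 2]), max(coords[, 2])))
      d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
        2 * coords %*% t(centers)
      max.col(-d2)
    },
    voronoi = {
      centers <- coords[sample.int(n, n_domains), , drop = FALSE]
      d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
        2 * coords %*% t(centers)
      max.col(-d2)
    })
  labels <- factor(labels, levels = sort(unique(labels)))

  gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
  marker_idx <- matrix(seq_len(marker_genes_per_domain * n_domains),
                       nrow = n_domains, byrow = TRUE)
  gene_base_means <- nb_mean_base *
    exp(stats::rnorm(n_genes, 0, gene_mean_sd))
  mu <- matrix(gene_base_means, n, n_genes, byrow = TRUE)
  for (d in seq_len(n_domains)) {
    rows_d <- labels == levels(labels)[d]
    mu[rows_d, marker_idx[d, ]] <-
      mu[rows_d, marker_idx[d, ], drop = FALSE] * marker_fold
  }

  # batches are replicate slides of the same layout, stacked spot-wise
  batch <- NULL
  if (n_batches > 1L) {
    coords <- coords[rep(seq_len(n), n_batches), , drop = FALSE]
    if (batch_as_z)
      coords <- cbind(coords, z = rep(seq_len(n_batches), each = n))
    labels <- factor(rep(as.integer(labels), n_batches),
                     levels = seq_len(n_domains))
    mu <- mu[rep(seq_len(n), n_batches), , drop = FALSE]
    batch <- factor(rep(seq_len(n_batches), each = n))
    if (batch_shift_sd > 0) {
      for (b in 2L:n_batches) {
        fac <- exp(stats::rnorm(n_genes, 0, batch_shift_sd))
        mu[batch == b, ] <- sweep(mu[batch == b, , drop = FALSE], 2L, fac, "*")
      }
    }
    n <- n * n_batches
  }

  counts <- matrix(stats::rnbinom(n * n_genes, mu = mu,
                                  size = 1 / nb_dispersion), n, n_genes)
  spot_ids <- sprintf("spot_%04d", seq_len(n))

  morph <- NULL
  if (morphology_dim > 0) {
    signal <- matrix(stats::rnorm(n_domains * morphology_dim), n_domains)
    raw <- signal[as.integer(labels), , drop = FALSE] +
      matrix(stats::rnorm(n * morphology_dim, 0, morphology_noise_sd), n)
    morph <- structure(list(raw_features = raw,
                            reduced = pca_fit(raw, min(morphology_dim, n,
                                                       50))$scores,
                            extractor_name = "synthetic_onehot",
                            tile_size_px = NA_integer_),
                       class = "morphology_features")
  }

  img <- NULL; pix <- NULL
  if (with_image && length(grid_shape) == 2L) {
    px_per <- 8L
    img <- array(0, dim = c(grid_shape[1L] * px_per, grid_shape[2L] * px_per,
                            3L))
    pal <- grDevices::hcl.colors(n_domains, "Dark 3")
    for (i in seq_len(n)) {
      rgbv <- grDevices::col2rgb(pal[as.integer(labels[i])]) / 255
      rr <- (coords[i, 1L] - 1L) * px_per + seq_len(px_per)
      cc <- (coords[i, 2L] - 1L) * px_per + seq_len(px_per)
      for (c3 in 1:3) img[rr, cc, c3] <- rgbv[c3]
    }
    pix <- cbind((coords[, 2L] - 0.5) * px_per, (coords[, 1L] - 0.5) * px_per)
  }

  ds <- spot_dataset(counts, coords, spot_ids = spot_ids,
                     gene_ids = gene_ids, batch = batch,
                     pixel_coords = pix, image = img,
                     platform = if (with_image) "visium" else "generic")
  list(dataset = ds, labels = labels, morphology = morph,
       marker_genes = matrix(gene_ids[t(marker_idx)], nrow = n_domains,
                             byrow = TRUE),
       gene_base_means = stats::setNames(gene_base_means, gene_ids))
}
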