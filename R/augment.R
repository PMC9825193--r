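#' Pairwise gene-expression correlation weights
#'
#' For each requested spot pair computes the Pearson correlation of the two
#' spots' normalized expression vectors. In the default \code{"similarity"}
#' mode the correlation is clipped to [0, 1] so that dissimilar neighbours do
#' not contribute; \code{"paper_literal"} returns \code{1 - r} (a correlation
#' distance in [0, 2]).
#'
#' @param expr an \code{expr_matrix} at stage \code{normalized} (or a plain
#'   spots x genes matrix).
#' @param pairs two-column integer matrix of spot index pairs.
#' @param mode \code{"similarity"} (default) or \code{"paper_literal"}.
#' @return numeric vector of weights, one per pair.
#' @export
gene_correlation <- function(expr, pairs,
                             mode = c("similarity", "paper_literal")) {
  mode <- match.arg(mode)
  vals <- if (inherits(expr, "expr_matrix")) {
    if (expr$stage != "normalized")
      stop("gene_correlation expects stage 'normalized'")
    expr$values
  } else as.matrix(expr)
  if (ncol(vals) < 2L) stop("need at least 2 genes per spot")
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  xc <- vals - rowMeans(vals)
  nrm <- sqrt(rowSums(xc^2))
  zero <- nrm == 0
  if (any(zero[unique(as.vector(pairs))]))
    warning("zero-variance spot expression vector; weight set to 0")
  nrm[zero] <- 1
  r <- rowSums(xc[pairs[, 1L], , drop = FALSE] *
               xc[pairs[, 2L], , drop = FALSE]) /
       (nrm[pairs[, 1L]] * nrm[pairs[, 2L]])
  r[zero[pairs[, 1L]] | zero[pairs[, 2L]]] <- if (mode == "similarity") 0 else 1
  unname(if (mode == "similarity") pmin(pmax(r, 0), 1) else 1 - r)
}

#' Neighbourhood radius from nearest-neighbour distances
#'
#' Pools, over all spots, the distances to each spot's \code{k_gamma} nearest
#' neighbours (self excluded) and returns \code{mean + variance} of the pooled
#' list (the default), or \code{mean + sd} when \code{method = "mean_sd"}.
#'
#' @param coords spots x d coordinate matrix.
#' @param k_gamma neighbours per spot entering the pool (default 4).
#' @param method \code{"mean_var"} (default) or \code{"mean_sd"}.
#' @return the radius gamma (scalar).
#' @export
spatial_radius <- function(coords, k_gamma = 4,
                           method = c("mean_var", "mean_sd")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < k_gamma + 1L)
    stop("need at least k_gamma + 1 = ", k_gamma + 1L, " spots")
  nn <- knn_distances(coords, k_gamma)
  pooled <- as.vector(nn)
  v <- if (method == "mean_var") stats::var(pooled) * (length(pooled) - 1) /
         length(pooled) else stats::sd(pooled)
  if (length(pooled) < 2L || !is.finite(v)) v <- 0
  mean(pooled) + v
}

# internal: n x k matrix of distances to the k nearest neighbours (self
# excluded); exhaustive, fine for full-graph problem sizes
knn_distances <- function(coords, k) {
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  t(apply(d, 1L, function(r) sort(r, partial = k)[seq_len(k)]))
}

# internal: n x k index matrix of k nearest neighbours, distance ties broken
# by lower spot index
knn_indices <- function(coords, k) {
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  n <- nrow(d)
  t(vapply(seq_len(n),
           function(i) order(d[i, ], seq_len(n))[seq_len(k)],
           integer(k)))
}

#' Spatial neighbour mask from a radius
#'
#' A spot j is a neighbour of spot i iff \code{dist(i, j) <= gamma} and
#' \code{i != j}.
#'
#' @param coords spots x d coordinate matrix.
#' @param gamma radius, typically from [spatial_radius()].
#' @return list with \code{pairs} (two-column index matrix, both directions),
#'   \code{neighbor_lists} (per-spot integer vectors) and \code{n_per_spot}.
#' @export
spatial_weights <- function(coords, gamma) {
  if (gamma <= 0) stop("gamma must be positive")
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  adj <- d <= gamma
  dimnames(adj) <- NULL
  neighbor_lists <- apply(adj, 1L, which, simplify = FALSE)
  n_per_spot <- unname(lengths(neighbor_lists))
  pairs <- which(adj, arr.ind = TRUE)
  dimnames(pairs) <- NULL
  list(pairs = pairs, neighbor_lists = neighbor_lists,
       n_per_spot = n_per_spot, gamma = gamma)
}

#' Compute the full augmentation weight set for a dataset
#'
#' Convenience wrapper: derives gamma, the spatial mask, expression
#' correlation weights, and (when morphology features are supplied)
#' morphological similarity weights for every in-radius pair.
#'
#' @param expr normalized \code{expr_matrix}.
#' @param coords spot coordinates.
#' @param morphology optional \code{morphology_features}.
#' @param k_gamma neighbours defining the radius (default 4).
#' @param mode weight mode passed to [gene_correlation()] and
#'   [morph_similarity()].
#' @param radius_method passed to [spatial_radius()].
#' @return an \code{augmentation_weights} list with fields \code{pairs},
#'   \code{neighbor_lists}, \code{n_per_spot}, \code{GC}, \code{MS} (or NULL),
#'   \code{gamma}.
#' @export
augmentation_weights <- function(expr, coords, morphology = NULL,
                                 k_gamma = 4,
                                 mode = c("similarity", "paper_literal"),
                                 radius_method = "mean_var") {
  mode <- match.arg(mode)
  gamma <- spatial_radius(coords, k_gamma, radius_method)
  sw <- spatial_weights(coords, gamma)
  gc <- if (nrow(sw$pairs)) gene_correlation(expr, sw$pairs, mode)
        else numeric()
  ms <- NULL
  if (!is.null(morphology) && nrow(sw$pairs))
    ms <- morph_similarity(morphology, sw$pairs, mode)
  structure(c(sw, list(GC = gc, MS = ms, mode = mode)),
            class = "augmentation_weights")
}

#' Augment expression with weighted neighbour expression
#'
#' Each spot's expression is incremented by the mean over its spatial
#' neighbours of the neighbour expression scaled by the pairwise weights:
#' with morphology, \code{GE_i + sum_j(GE_j * MS_ij * GC_ij) / n_i}; without,
#' \code{GE_i + sum_j(GE_j * GC_ij) / n_i}, the sum running over the
#' \code{n_i} spots inside the radius. Spots with no neighbours are left
#' unchanged.
#'
#' @param expr normalized \code{expr_matrix}.
#' @param weights an \code{augmentation_weights} object.
#' @param use_morphology include the MS factor (requires \code{weights$MS}).
#' @return an \code{expr_matrix} at stage \code{augmented}.
#' @export
augment_expression <- function(expr, weights, use_morphology = !is.null(weights$MS)) {
  vals <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (inherits(expr, "expr_matrix") && expr$stage != "normalized")
    stop("augment_expression expects stage 'normalized'")
  if (length(weights$n_per_spot) != nrow(vals))
    stop("consistency error: weights built for ", length(weights$n_per_spot),
         " spots, expression has ", nrow(vals))
  if (use_morphology && is.null(weights$MS))
    stop("use_morphology = TRUE but weights carry no MS values")
  w <- weights$GC
  if (use_morphology) w <- w * weights$MS
  out <- vals
  if (nrow(weights$pairs)) {
    # sparse accumulation: contribution of j to i is GE_j * w_ij / n_i
    wn <- w / weights$n_per_spot[weights$pairs[, 1L]]
    n <- nrow(vals)
    wmat <- Matrix::sparseMatrix(i = weights$pairs[, 1L],
                                 j = weights$pairs[, 2L],
                                 x = wn, dims = c(n, n))
    out <- vals + as.matrix(wmat %*% vals)
  }
  expr_matrix(out, "augmented",
              c(if (inherits(expr, "expr_matrix")) expr$transform_log,
                sprintf("neighbour augmentation (gamma=%.4g, morphology=%s)",
                        weights$gamma, use_morphology)),
              kept_spots = if (inherits(expr, "expr_matrix")) expr$kept_spots
                           else seq_len(nrow(vals)))
}
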