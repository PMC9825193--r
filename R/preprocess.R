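#' Filter, library-size normalize and log-transform counts
#'
#' Genes expressed in fewer than \code{min_spots_gene} spots are removed,
#' spots with total counts below \code{min_counts_spot} (and spots with zero
#' totals) are dropped, each remaining spot is scaled to \code{target_sum}
#' total counts, and \code{log1p} is applied.
#'
#' @param dataset a [spot_dataset] (or a raw numeric count matrix).
#' @param min_counts_spot drop spots with fewer total counts (default 0, off;
#'   zero-total spots are always dropped, with a warning).
#' @param min_spots_gene keep genes detected in at least this many spots
#'   (default 3).
#' @param target_sum per-spot total after scaling, before log1p
#'   (default 1e4).
#' @param scale_genes if TRUE additionally z-scale each gene after log1p
#'   (off by default).
#' @return an \code{expr_matrix}: list with \code{values} (spots x genes),
#'   \code{stage = "normalized"}, \code{transform_log}, and \code{kept_spots}
#'   (indices into the input rows).
#' @export
filter_and_normalize <- function(dataset, min_counts_spot = 0,
                                 min_spots_gene = 3, target_sum = 1e4,
                                 scale_genes = FALSE) {
  m <- if (inherits(dataset, "spot_dataset")) dense_counts(dataset)
       else as.matrix(dataset)
  if (any(m < 0) || any(m != round(m)))
    stop("filter_and_normalize expects raw non-negative integer counts")
  log <- character()
  keep_g <- colSums(m > 0) >= min_spots_gene
  if (any(!keep_g)) {
    m <- m[, keep_g, drop = FALSE]
    log <- c(log, sprintf("filtered %d genes detected in < %d spots",
                          sum(!keep_g), min_spots_gene))
  }
  tot <- rowSums(m)
  keep_s <- tot >= max(min_counts_spot, .Machine$double.eps)
  kept_spots <- unname(which(keep_s))
  if (any(!keep_s)) {
    warning(sum(!keep_s), " spot(s) dropped (total counts below threshold)")
    m <- m[keep_s, , drop = FALSE]
    tot <- tot[keep_s]
    log <- c(log, sprintf("dropped %d low-count spots", sum(!keep_s)))
  }
  m <- m / tot * target_sum
  log <- c(log, sprintf("library-size normalized to %g", target_sum))
  m <- log1p(m)
  log <- c(log, "log1p")
  if (scale_genes) {
    m <- scale(m)
    m[is.na(m)] <- 0
    log <- c(log, "per-gene z-scale")
  }
  expr_matrix(m, "normalized", log, kept_spots = kept_spots)
}

# internal constructor for staged expression matrices
expr_matrix <- function(values, stage, transform_log = character(),
                        kept_spots = seq_len(nrow(values))) {
  stopifnot(stage %in% c("raw", "normalized", "augmented", "reduced"))
  structure(list(values = values, stage = stage,
                 transform_log = transform_log, kept_spots = kept_spots),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix (%s): %d x %d\n", x$stage, nrow(x$values),
              ncol(x$values)))
  for (s in x$transform_log) cat("  -", s, "\n")
  invisible(x)
}

#' Principal-component reduction of an expression matrix
#'
#' Centers the matrix and projects it on the leading eigenvectors of the
#' sample covariance. Components are ordered by decreasing explained
#' variance. To make the result reproducible across linear-algebra backends,
#' the sign of each component is fixed so that its largest-magnitude loading
#' is positive.
#'
#' @param expr an \code{expr_matrix} at stage \code{normalized} or
#'   \code{augmented} (a plain matrix is accepted).
#' @param n_components number of components (default 200, capped at
#'   \code{min(spots, genes)} is an error, not silent truncation).
#' @param seed unused by the deterministic exact solver; accepted for
#'   interface stability.
#' @return an \code{expr_matrix} at stage \code{reduced}; attributes
#'   \code{explained_variance_ratio} and \code{rotation} carry the spectrum
#'   and loadings.
#' @export
pca_reduce <- function(expr, n_components = 200, seed = 0L) {
  vals <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (inherits(expr, "expr_matrix") &&
      !expr$stage %in% c("normalized", "augmented"))
    stop("pca_reduce expects stage 'normalized' or 'augmented', got '",
         expr$stage, "'")
  bound <- min(dim(vals))
  if (n_components > bound)
    stop("parameter error: n_components must be <= min(spots, genes) = ",
         bound)
  pc <- pca_fit(vals, n_components)
  out <- expr_matrix(pc$scores, "reduced",
                     c(if (inherits(expr, "expr_matrix")) expr$transform_log,
                       sprintf("PCA to %d components", n_components)),
                     kept_spots = if (inherits(expr, "expr_matrix"))
                       expr$kept_spots else seq_len(nrow(vals)))
  attr(out, "explained_variance_ratio") <- pc$evr
  attr(out, "rotation") <- pc$rotation
  out
}

# internal: exact PCA via eigendecomposition of the covariance with a fixed
# sign convention (largest-|loading| entry positive per component)
pca_fit <- function(x, k) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) {
    # small-n shortcut through the Gram matrix
    g <- tcrossprod(xc) / (n - 1)
    eg <- eigen(g, symmetric = TRUE)
    pos <- pmax(eg$values, 0)
    keep <- seq_len(k)
    v <- crossprod(xc, eg$vectors[, keep, drop = FALSE])
    nrm <- sqrt(colSums(v^2))
    nrm[nrm == 0] <- 1
    rot <- sweep(v, 2L, nrm, "/")
    vals <- pos
  } else {
    cv <- crossprod(xc) / (n - 1)
    ec <- eigen(cv, symmetric = TRUE)
    rot <- ec$vectors[, seq_len(k), drop = FALSE]
    vals <- pmax(ec$values, 0)
  }
  # sign convention
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- xc %*% rot
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  tot <- sum(vals)
  list(scores = scores, rotation = rot,
       evr = if (tot > 0) vals[seq_len(k)] / tot else rep(0, k))
}
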