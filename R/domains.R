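#' Cluster the latent embedding into spatial domains
#'
#' Builds a k-nearest-neighbour graph on the joint latent and runs Leiden
#' community detection across a resolution grid from 0.1 to 2.5 in steps of
#' 0.01. With \code{target_k} given (\code{fixed_k} mode) the scan stops at
#' the first (lowest) resolution yielding exactly \code{target_k} clusters;
#' without it (\code{adaptive} mode) the partition maximizing the
#' Calinski-Harabasz score over the grid is returned.
#'
#' @param embedding a \code{latent_embedding} (or a plain spots x d matrix).
#' @param target_k desired number of domains (NULL for adaptive mode).
#' @param seed RNG seed for the Leiden refinement; fixed before every call,
#'   making the scan deterministic.
#' @param k_latent neighbourhood size of the latent kNN graph (default 15).
#' @param resolution_grid scanned resolutions (default
#'   \code{seq(0.1, 2.5, by = 0.01)}).
#' @return a \code{domain_assignment}: \code{labels} (factor),
#'   \code{resolution}, \code{n_domains}, \code{mode}, \code{metrics} (list
#'   with \code{sc}, \code{db}, \code{ch}; \code{ari} added later when truth
#'   is known).
#' @export
cluster_embedding <- function(embedding, target_k = NULL, seed = 0L,
                              k_latent = 15,
                              resolution_grid = seq(0.1, 2.5, by = 0.01)) {
  z <- if (inherits(embedding, "latent_embedding")) embedding$z_joint
       else as.matrix(embedding)
  n <- nrow(z)
  if (!is.null(target_k) && target_k < 2L)
    stop("target_k must be >= 2")
  k_latent <- min(k_latent, n - 1L)
  nb <- knn_indices(z, k_latent)
  el <- cbind(rep(seq_len(n), each = k_latent), as.vector(t(nb)))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))

  leiden_at <- function(res) {
    set.seed(seed)
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 2L))
  }

  if (!is.null(target_k)) {
    achieved <- integer(0)
    for (res in resolution_grid) {
      mem <- leiden_at(res)
      kk <- length(unique(mem))
      achieved <- c(achieved, kk)
      if (kk == target_k)
        return(new_domain_assignment(mem, res, "fixed_k", z))
    }
    stop("search error: no resolution in [",
         min(resolution_grid), ", ", max(resolution_grid),
         "] yields ", target_k, " clusters; nearest achieved: ",
         paste(sort(unique(achieved[order(abs(achieved - target_k))]))[1:2],
               collapse = ", "))
  }

  best <- NULL
  for (res in resolution_grid) {
    mem <- leiden_at(res)
    if (length(unique(mem)) < 2L) next
    ch <- cluster_metrics(z, mem, which = "ch")$ch
    if (is.null(best) || ch > best$ch)
      best <- list(mem = mem, res = res, ch = ch)
  }
  if (is.null(best))
    stop("search error: no resolution produced >= 2 clusters")
  new_domain_assignment(best$mem, best$res, "adaptive", z)
}

new_domain_assignment <- function(mem, resolution, mode, z) {
  labels <- factor(as.integer(factor(mem)))
  met <- if (nlevels(labels) >= 2L) cluster_metrics(z, labels)
         else list(sc = NA_real_, db = NA_real_, ch = NA_real_)
  structure(list(labels = labels, resolution = resolution,
                 n_domains = nlevels(labels), mode = mode, metrics = met),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat(sprintf("domain_assignment: %d domains at resolution %.2f (%s mode)\n",
              x$n_domains, x$resolution, x$mode))
  m <- x$metrics
  cat(sprintf("  silhouette %.3f, Davies-Bouldin %.3f, Calinski-Harabasz %.1f%s\n",
              m$sc, m$db, m$ch,
              if (!is.null(m$ari)) sprintf(", ARI %.3f", m$ari) else ""))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table
#' \code{N_ij} and its marginals: \code{(sum_ij C(N_ij,2) - E) / (max - E)}
#' with \code{E = sum_i C(N_i,2) * sum_j C(N_j,2) / C(N,2)} and
#' \code{max = (sum_i C(N_i,2) + sum_j C(N_j,2)) / 2}. Symmetric in its
#' arguments, invariant under relabeling, 1 for identical partitions.
#'
#' @param p_star,p label vectors of equal length (any type coercible to
#'   factor).
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(p_star, p) {
  if (length(p_star) != length(p))
    stop("input error: partitions differ in length (", length(p_star),
         " vs ", length(p), ")")
  tab <- table(p_star, p)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(p))
  expected <- a * b / n2
  maximum <- (a + b) / 2
  if (maximum == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maximum - expected)
}

#' Label-free clustering quality metrics
#'
#' Silhouette coefficient (mean over samples of \code{(b - a) / max(a, b)}
#' with \code{a} the mean intra-cluster and \code{b} the mean
#' nearest-cluster distance), Davies-Bouldin index (mean over clusters of the
#' largest \code{(s_i + s_j) / d_ij} similarity ratio, with \code{s} the mean
#' distance to the centroid and \code{d} the centroid distance), and the
#' Calinski-Harabasz variance-ratio criterion.
#'
#' @param x samples x features matrix.
#' @param labels cluster labels (>= 2 non-empty clusters; all-singleton
#'   clusterings are an error).
#' @param which subset of \code{c("sc", "db", "ch")} to compute.
#' @return list with elements \code{sc}, \code{db}, \code{ch} (requested ones
#'   filled).
#' @export
cluster_metrics <- function(x, labels, which = c("sc", "db", "ch")) {
  x <- as.matrix(x)
  labels <- factor(labels)
  k <- nlevels(labels)
  n <- nrow(x)
  if (k < 2L) stop("metric error: need >= 2 clusters")
  sizes <- table(labels)
  if (all(sizes == 1L)) stop("metric error: all clusters are singletons")
  idx <- split(seq_len(n), labels)
  cent <- t(vapply(idx, function(ii) colMeans(x[ii, , drop = FALSE]),
                   numeric(ncol(x))))
  out <- list(sc = NULL, db = NULL, ch = NULL)

  if ("sc" %in% which) {
    d <- as.matrix(stats::dist(x))
    s <- numeric(n)
    for (i in seq_len(n)) {
      own <- idx[[as.integer(labels[i])]]
      if (length(own) == 1L) { s[i] <- 0; next }
      a <- sum(d[i, own]) / (length(own) - 1L)
      b <- min(vapply(seq_len(k)[-as.integer(labels[i])],
                      function(j) mean(d[i, idx[[j]]]), numeric(1)))
      s[i] <- (b - a) / max(a, b)
    }
    out$sc <- mean(s)
  }
  if ("db" %in% which) {
    s_c <- vapply(seq_len(k), function(j)
      mean(sqrt(rowSums((x[idx[[j]], , drop = FALSE] -
                           rep(cent[j, ], each = length(idx[[j]])))^2))),
      numeric(1))
    dc <- as.matrix(stats::dist(cent))
    rmax <- vapply(seq_len(k), function(i)
      max(vapply(seq_len(k)[-i], function(j) (s_c[i] + s_c[j]) / dc[i, j],
                 numeric(1))), numeric(1))
    out$db <- mean(rmax)
  }
  if ("ch" %in% which) {
    mu <- colMeans(x)
    ssb <- sum(vapply(seq_len(k), function(j)
      length(idx[[j]]) * sum((cent[j, ] - mu)^2), numeric(1)))
    ssw <- sum(vapply(seq_len(k), function(j)
      sum((x[idx[[j]], , drop = FALSE] -
             rep(cent[j, ], each = length(idx[[j]])))^2), numeric(1)))
    out$ch <- if (ssw > 0) (ssb / (k - 1)) / (ssw / (n - k)) else Inf
  }
  out
}

#' Per-domain differential expression by Wilcoxon rank-sum test
#'
#' For every domain and gene, tests the in-domain expression values against
#' all other spots (two-sided rank-sum), adjusts p-values by
#' Benjamini-Hochberg across all tests, and reports log2 fold changes
#' computed on the de-logged normalized values.
#'
#' @param expr normalized \code{expr_matrix} (or spots x genes matrix of
#'   log1p-normalized values).
#' @param labels domain labels.
#' @param fdr significance threshold on the adjusted p-value (default 0.01).
#' @return data.frame with columns \code{gene}, \code{domain},
#'   \code{log_fold_change}, \code{p}, \code{q}, \code{significant}.
#' @export
deg_wilcoxon <- function(expr, labels, fdr = 0.01) {
  vals <- if (inherits(expr, "expr_matrix")) {
    if (expr$stage != "normalized")
      stop("deg_wilcoxon expects stage 'normalized'")
    expr$values
  } else as.matrix(expr)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 domains")
  if (is.null(colnames(vals)))
    colnames(vals) <- paste0("gene_", seq_len(ncol(vals)))
  res <- list()
  for (dom in levels(labels)) {
    inside <- labels == dom
    if (sum(inside) < 3L) {
      warning("domain '", dom, "' has fewer than 3 spots; skipped")
      next
    }
    pv <- vapply(seq_len(ncol(vals)), function(j) {
      x1 <- vals[inside, j]; x2 <- vals[!inside, j]
      if (all(x1 == x1[1L]) && all(x2 == x1[1L])) return(1)
      stats::wilcox.test(x1, x2, exact = FALSE)$p.value
    }, numeric(1))
    m1 <- colMeans(expm1(vals[inside, , drop = FALSE]))
    m2 <- colMeans(expm1(vals[!inside, , drop = FALSE]))
    lfc <- log2((m1 + 1e-9) / (m2 + 1e-9))
    res[[dom]] <- data.frame(gene = colnames(vals), domain = dom,
                             log_fold_change = lfc, p = pv,
                             row.names = NULL)
  }
  tab <- do.call(rbind, res)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < fdr
  rownames(tab) <- NULL
  tab[order(tab$domain, tab$q, tab$gene), ]
}
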