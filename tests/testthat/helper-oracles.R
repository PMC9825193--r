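# Independent brute-force oracles, deliberately written as naive loops /
# direct formulas so they share no code with the package implementation.

oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

oracle_cosine <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

# ARI by explicit pair counting over all C(n,2) pairs
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected) return(ifelse(n11 == expected, 1, 0))
  (n11 - expected) / (maximum - expected)
}

# exhaustive kNN edge set (directed), ties by lower index
oracle_knn_edges <- function(coords, k) {
  n <- nrow(coords)
  edges <- matrix(0L, 0L, 2L)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    edges <- rbind(edges, cbind(i, ord[seq_len(k)]))
  }
  edges
}

# textbook silhouette (per-sample loop)
oracle_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (l in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == l]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_davies_bouldin <- function(x, labels) {
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  cent <- t(sapply(ks, function(l) colMeans(x[labels == l, , drop = FALSE])))
  sdisp <- sapply(ks, function(l) {
    xs <- x[labels == l, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, colMeans(xs))^2)))
  })
  db <- 0
  for (i in seq_along(ks)) {
    best <- -Inf
    for (j in seq_along(ks)) {
      if (i == j) next
      best <- max(best, (sdisp[i] + sdisp[j]) /
                    sqrt(sum((cent[i, ] - cent[j, ])^2)))
    }
    db <- db + best
  }
  db / length(ks)
}

oracle_calinski_harabasz <- function(x, labels) {
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  n <- nrow(x); k <- length(ks)
  mu <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (l in ks) {
    xs <- x[labels == l, , drop = FALSE]
    cl <- colMeans(xs)
    ssb <- ssb + nrow(xs) * sum((cl - mu)^2)
    ssw <- ssw + sum(sweep(xs, 2, cl)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# KL(N(mu, sigma^2) || N(0,1)) per diagonal Gaussian node, closed form
oracle_kl <- function(mu, logvar) {
  mean(sapply(seq_len(nrow(mu)), function(i)
    sum(0.5 * (mu[i, ]^2 + exp(logvar[i, ]) - logvar[i, ] - 1))))
}

# PCA scores via eigendecomposition of the covariance matrix
oracle_pca_scores <- function(x, k) {
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(cov(x), symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  xc %*% ev
}

# small standard fixture reused across tests
make_bands_fixture <- function(seed = 42, rows = 15, cols = 15,
                               n_domains = 3, n_genes = 60, ...) {
  simulate_spots(grid_shape = c(rows, cols), n_domains = n_domains,
                 n_genes = n_genes, marker_genes_per_domain = 3,
                 seed = seed, ...)
}
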