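test_that("ARI matches the brute-force pair-counting oracle", {
  set.seed(90)
  for (rep in 1:20) {
    a <- sample(1:3, 12, TRUE)
    b <- sample(1:4, 12, TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari_pairs(a, b),
                 tolerance = 1e-12)
    # symmetry and label-permutation invariance
    expect_equal(adjusted_rand_index(b, a), adjusted_rand_index(a, b))
    expect_equal(adjusted_rand_index(a, 5 - b), adjusted_rand_index(a, b))
  }
  if (requireNamespace("mclust", quietly = TRUE)) {
    a <- sample(1:3, 40, TRUE); b <- sample(1:3, 40, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("ARI endpoints: identity, chance, and mismatch", {
  p <- rep(1:3, each = 4)
  expect_equal(adjusted_rand_index(p, p), 1.0)
  q <- sample(p)
  expect_equal(adjusted_rand_index(p, q), adjusted_rand_index(q, p))
  expect_equal(adjusted_rand_index(rep(1, 8), rep(1:2, 4)), 0.0)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("clustering metrics agree with textbook-formula oracles", {
  set.seed(91)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 3), 40)
    labels <- sample(1:3, 40, TRUE)
    m <- cluster_metrics(x, labels)
    expect_equal(m$sc, oracle_silhouette(x, labels), tolerance = 1e-8)
    expect_equal(m$db, oracle_davies_bouldin(x, labels), tolerance = 1e-8)
    expect_equal(m$ch, oracle_calinski_harabasz(x, labels), tolerance = 1e-8)
    expect_true(m$sc >= -1 && m$sc <= 1)
    expect_gte(m$db, 0)
  }
  if (requireNamespace("cluster", quietly = TRUE)) {
    x <- matrix(rnorm(60), 20, 3); labels <- rep(1:2, 10)
    sil <- cluster::silhouette(labels, dist(x))
    expect_equal(cluster_metrics(x, labels, "sc")$sc,
                 mean(sil[, "sil_width"]), tolerance = 1e-10)
  }
})

test_that("unit-square hand geometry gives the hand-computed silhouette", {
  # corners (0,0),(1,0) cluster 1; (0,1),(1,1) cluster 2 (paired by side)
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  labels <- c(1, 1, 2, 2)
  # per point: a = 1, b = (1 + sqrt(2)) / 2
  b <- (1 + sqrt(2)) / 2
  expect_equal(cluster_metrics(x, labels, "sc")$sc, (b - 1) / b,
               tolerance = 1e-10)
})

test_that("well-separated blobs yield near-ideal metric values", {
  set.seed(92)
  x <- rbind(matrix(rnorm(60, 0, 0.05), 30),
             matrix(rnorm(60, 10, 0.05), 30))
  labels <- rep(1:2, each = 30)
  m <- cluster_metrics(x, labels)
  expect_gt(m$sc, 0.9)
  expect_lt(m$db, 0.2)
  expect_error(cluster_metrics(x, seq_len(60)), "singleton")
  expect_error(cluster_metrics(x, rep(1, 60)), ">= 2 clusters")
})

test_that("fixed-k search finds planted blobs and adaptive CH picks their k", {
  set.seed(93)
  z <- rbind(matrix(rnorm(80, 0, 0.3), 40),
             matrix(rnorm(80, 6, 0.3), 40),
             matrix(rnorm(80 , 12, 0.3), 40))
  truth <- rep(1:3, each = 40)
  emb <- structure(list(z_joint = z), class = "latent_embedding")
  fixed <- cluster_embedding(emb, target_k = 3, seed = 1)
  expect_equal(fixed$n_domains, 3L)
  expect_equal(adjusted_rand_index(truth, fixed$labels), 1.0)
  expect_equal(fixed$mode, "fixed_k")
  adaptive <- cluster_embedding(emb, seed = 1)
  expect_equal(adaptive$n_domains, 3L)
  expect_equal(adaptive$mode, "adaptive")
  expect_true(adaptive$resolution >= 0.1 && adaptive$resolution <= 2.5)
})

test_that("clustering is deterministic under a fixed seed and errors clearly", {
  set.seed(94)
  z <- matrix(rnorm(60 * 5), 60)
  emb <- structure(list(z_joint = z), class = "latent_embedding")
  a <- cluster_embedding(emb, target_k = 2, seed = 7)
  b <- cluster_embedding(emb, target_k = 2, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(a$resolution, b$resolution)
  expect_error(cluster_embedding(emb, target_k = 50, seed = 7),
               "search error")
})

test_that("wilcoxon marker calling recovers a planted fold change", {
  set.seed(95)
  n <- 100
  labels <- rep(1:2, each = 50)
  counts <- matrix(rpois(n * 20, 20), n, 20,
                   dimnames = list(NULL, paste0("g", 1:20)))
  counts[labels == 1, 3] <- rpois(50, 80)  # 4x planted marker in domain 1
  norm <- filter_and_normalize(counts, min_spots_gene = 0)
  tab <- deg_wilcoxon(norm, labels, fdr = 0.01)
  hit <- tab[tab$gene == colnames(norm$values)[3] & tab$domain == "1", ]
  expect_true(hit$significant)
  expect_gt(hit$log_fold_change, 1)
  # a gene with identical normalized values everywhere is never significant
  vals2 <- cbind(norm$values, flat = log1p(7))
  tab2 <- deg_wilcoxon(vals2, labels, fdr = 0.01)
  flat <- tab2[tab2$gene == "flat", ]
  expect_true(all(flat$q > 0.99))
  expect_false(any(flat$significant))
  # tiny domains are skipped with a warning
  expect_warning(deg_wilcoxon(norm, c(rep(1, 98), 2, 2), fdr = 0.01),
                 "fewer than 3")
})
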