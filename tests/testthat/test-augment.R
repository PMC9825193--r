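test_that("gene correlation matches the textbook Pearson oracle", {
  set.seed(21)
  x <- matrix(rexp(12 * 10), 12, 10)
  pairs <- cbind(sample(12, 30, TRUE), sample(12, 30, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  lit <- gene_correlation(x, pairs, mode = "paper_literal")
  sim <- gene_correlation(x, pairs, mode = "similarity")
  for (p in seq_len(nrow(pairs))) {
    r <- oracle_pearson(x[pairs[p, 1], ], x[pairs[p, 2], ])
    expect_equal(lit[p], 1 - r, tolerance = 1e-10)
    expect_equal(sim[p], min(max(r, 0), 1), tolerance = 1e-10)
  }
})

test_that("gene correlation endpoints: identical and anticorrelated spots", {
  s <- c(1, 2, 3, 4, 5)
  x <- rbind(s, s, -s + 6)
  expect_equal(gene_correlation(x, cbind(1, 2), "paper_literal"), 0)
  expect_equal(gene_correlation(x, cbind(1, 2), "similarity"), 1)
  expect_equal(gene_correlation(x, cbind(1, 3), "paper_literal"), 2)
  expect_equal(gene_correlation(x, cbind(1, 3), "similarity"), 0)
  flat <- rbind(s, rep(2, 5))
  expect_warning(w <- gene_correlation(flat, cbind(1, 2), "similarity"),
                 "zero-variance")
  expect_equal(w, 0)
})

test_that("radius gamma equals mean + variance of pooled kNN distances", {
  # ring of equally spaced spots: both nearest neighbours at one distance,
  # so the pooled list is constant and gamma = that distance (zero variance)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(cos(th), sin(th))
  spacing <- sqrt(sum((ring[1, ] - ring[2, ])^2))
  expect_equal(spatial_radius(ring, 2), spacing, tolerance = 1e-12)
  # random cloud vs exhaustive O(N^2) oracle
  set.seed(9)
  pts <- matrix(runif(60), 30, 2)
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  pooled <- as.vector(apply(d, 1, function(r) sort(r)[1:4]))
  v_pop <- mean((pooled - mean(pooled))^2)
  expect_equal(spatial_radius(pts, 4), mean(pooled) + v_pop,
               tolerance = 1e-12)
  expect_equal(spatial_radius(pts, 4, method = "mean_sd"),
               mean(pooled) + sd(pooled), tolerance = 1e-12)
})

test_that("spatial mask equals the exhaustive distance-threshold oracle", {
  set.seed(10)
  pts <- matrix(runif(80), 40, 2)
  gamma <- 0.2
  sw <- spatial_weights(pts, gamma)
  d <- as.matrix(dist(pts))
  for (i in 1:40) {
    expected <- unname(which(d[i, ] <= gamma & seq_len(40) != i))
    expect_equal(sw$neighbor_lists[[i]], expected)
  }
  # two-point endpoints
  two <- rbind(c(0, 0), c(0, 0.1))
  expect_equal(spatial_weights(two, 0.2)$n_per_spot, c(1L, 1L))
  expect_equal(spatial_weights(two, 0.05)$n_per_spot, c(0L, 0L))
})

test_that("augmentation reproduces the 3-spot hand computation", {
  # GE = [[1,0],[0,1],[1,1]]; spot 1 neighbours {2,3}; weight products 0.5
  ge <- rbind(c(1, 0), c(0, 1), c(1, 1))
  weights <- list(pairs = rbind(c(1, 2), c(1, 3)),
                  neighbor_lists = list(c(2L, 3L), integer(), integer()),
                  n_per_spot = c(2L, 0L, 0L), gamma = 1,
                  GC = c(0.5, 0.5), MS = c(1, 1))
  aug <- augment_expression(ge, weights, use_morphology = TRUE)
  expect_equal(aug$values[1, ], c(1.25, 0.5))
  # isolated spots are fixed points
  expect_equal(aug$values[2, ], ge[2, ])
  expect_equal(aug$values[3, ], ge[3, ])
  expect_equal(aug$stage, "augmented")
})

test_that("morphology-free path equals the morphology path with MS = 1", {
  sim <- make_bands_fixture(seed = 30, rows = 8, cols = 8, n_genes = 30)
  norm <- filter_and_normalize(sim$dataset)
  w <- augmentation_weights(norm, sim$dataset$coords)
  w_ms1 <- w
  w_ms1$MS <- rep(1, nrow(w$pairs))
  a1 <- augment_expression(norm, w, use_morphology = FALSE)
  a2 <- augment_expression(norm, w_ms1, use_morphology = TRUE)
  expect_equal(a1$values, a2$values, tolerance = 1e-12)
})

test_that("augmentation is linear in expression and identity when isolated", {
  sim <- make_bands_fixture(seed = 31, rows = 6, cols = 6, n_genes = 20)
  norm <- filter_and_normalize(sim$dataset)
  w <- augmentation_weights(norm, sim$dataset$coords)
  a1 <- augment_expression(norm, w)
  doubled <- expr2 <- norm
  doubled$values <- 2 * norm$values
  # weights held fixed: reuse w
  a2 <- augment_expression(doubled, w)
  expect_equal(a2$values, 2 * a1$values, tolerance = 1e-10)
  # all-isolated mask: identity
  w0 <- list(pairs = matrix(integer(), 0, 2),
             neighbor_lists = rep(list(integer()), nrow(norm$values)),
             n_per_spot = rep(0L, nrow(norm$values)), gamma = 1,
             GC = numeric(), MS = NULL)
  expect_equal(augment_expression(norm, w0)$values, norm$values)
})
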