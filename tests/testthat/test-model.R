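small_cfg <- function(...) {
  model_config(fc_encoder_dims = c(16, 8), gnn_dims = c(8, 4), epochs = 30,
               ...)
}

test_that("dae forward preserves shapes and concatenates the latents", {
  cfg <- small_cfg()
  set.seed(1)
  p <- init_model_params(cfg, in_dim = 10)
  x <- matrix(rnorm(50), 5, 10)
  zg <- matrix(0, 5, 4)
  fw <- dae_forward(x, zg, p)
  expect_equal(dim(fw$z_gene), c(5L, 8L))
  expect_equal(dim(fw$z_joint), c(5L, 12L))  # R + R'
  expect_equal(dim(fw$x_reconstructed), dim(x))
  expect_equal(fw$z_joint, cbind(fw$z_gene, zg))
  expect_error(dae_forward(matrix(0, 5, 7), zg, p), "config error")
})

test_that("reconstruction loss matches the hand-computed mean squared norm", {
  x <- rbind(c(1, 2), c(3, 4))
  xr <- rbind(c(0, 2), c(3, 2))
  # per-spot squared norms: 1 and 4 -> mean 2.5
  expect_equal(reconstruction_loss(x, xr), 2.5)
})

test_that("vgae encoder follows the propagation formula and reparameterizes", {
  cfg <- small_cfg()
  set.seed(2)
  p <- init_model_params(cfg, in_dim = 6)
  coords <- matrix(runif(40), 20, 2)
  g <- normalize_adjacency(build_knn_graph(coords, 3))
  x <- matrix(rnorm(120), 20, 6)
  enc0 <- vgae_encode(x, g, p, eps = 0)
  expect_equal(enc0$z_graph, enc0$mu)
  # direct matrix-product oracle for mu
  at <- as.matrix(g$normalized)
  xbar <- (at %*% pmax((at %*% x) %*% p$Wg1, 0)) %*% p$Wg2
  expect_equal(enc0$mu, (at %*% xbar) %*% p$Wmu, tolerance = 1e-10)
  # zero weights give zero posterior parameters
  p0 <- p
  p0$Wg1[] <- 0; p0$Wg2[] <- 0; p0$Wmu[] <- 0; p0$Wsig[] <- 0
  encz <- vgae_encode(x, g, p0, eps = 0)
  expect_true(all(encz$mu == 0) && all(encz$logvar == 0))
})

test_that("reparameterized samples have variance exp(logvar)", {
  mu <- matrix(0, 1, 2)
  logvar <- matrix(c(log(4), log(0.25)), 1, 2)
  set.seed(3)
  draws <- replicate(1e5, {
    eps <- matrix(rnorm(2), 1)
    mu + exp(0.5 * logvar) * eps
  })
  expect_equal(var(draws[1, 1, ]), 4, tolerance = 0.02)
  expect_equal(var(draws[1, 2, ]), 0.25, tolerance = 0.02)
})

test_that("inner-product decoder is symmetric with the scalar oracle", {
  z <- rbind(c(1, 0), c(2, 0))
  p <- vgae_decode(z)
  expect_equal(p[1, 2], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(p[1, 2], p[2, 1])
  expect_equal(vgae_decode(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  set.seed(4)
  zr <- matrix(rnorm(20), 5, 4)
  expect_equal(vgae_decode(zr), t(vgae_decode(zr)), tolerance = 1e-12)
})

test_that("graph loss KL term equals the closed form on random posteriors", {
  set.seed(5)
  g <- normalize_adjacency(build_knn_graph(matrix(runif(20), 10, 2), 2))
  z0 <- matrix(0, 10, 3)
  # mu = 0, logvar = 0 -> KL = 0
  gl0 <- graph_loss(vgae_decode(z0), g, matrix(0, 10, 3), matrix(0, 10, 3))
  expect_equal(gl0$kl, 0)
  # single unit-mean coordinate -> KL = 0.5
  mu1 <- matrix(1, 1, 1)
  gl1 <- graph_loss(matrix(0.5, 1, 1),
                    normalize_adjacency(diag(1)), mu1, matrix(0, 1, 1))
  expect_equal(gl1$kl, 0.5)
  for (rep in 1:20) {
    mu <- matrix(rnorm(30), 10)
    lv <- matrix(rnorm(30, sd = 0.5), 10)
    gl <- graph_loss(vgae_decode(z0), g, mu, lv)
    expect_equal(gl$kl, oracle_kl(mu, lv), tolerance = 1e-8)
  }
})

test_that("perfect edge probabilities drive the reconstruction term to zero", {
  g <- normalize_adjacency(build_knn_graph(matrix(runif(20), 10, 2), 2))
  a <- as.matrix(g$adjacency)
  prob <- a * (1 - 1e-7) + (1 - a) * 1e-7
  gl <- graph_loss(prob, g, matrix(0, 10, 2), matrix(0, 10, 2))
  expect_lt(gl$bce, 1e-5)
})

test_that("gradient reversal: identity forward, -lambda scaled backward", {
  set.seed(6)
  z <- matrix(rnorm(12), 4, 3)
  expect_equal(grl_apply(z, 2), z, ignore_attr = TRUE)
  p <- list(Wc = matrix(rnorm(3), 3, 1), bc = 0.3)
  labels <- factor(c(1, 2, 2, 1))
  for (lambda in c(0, 0.5, 2)) {
    g_analytic <- grl_gradient(z, labels, p, lambda)
    # finite-difference oracle on the unreversed loss
    g_num <- matrix(0, 4, 3)
    h <- 1e-6
    for (i in 1:4) for (j in 1:3) {
      zp <- z; zp[i, j] <- zp[i, j] + h
      zm <- z; zm[i, j] <- zm[i, j] - h
      lp <- domain_loss(zp %*% p$Wc + p$bc, labels)
      lm <- domain_loss(zm %*% p$Wc + p$bc, labels)
      g_num[i, j] <- (lp - lm) / (2 * h)
    }
    expect_equal(g_analytic, -lambda * g_num, tolerance = 1e-5)
  }
  expect_true(all(grl_gradient(z, labels, p, 0) == 0))
})

test_that("domain loss matches hand computations for 2 and 3 classes", {
  # uniform probabilities -> ln M
  expect_equal(domain_loss(matrix(0, 4, 1), factor(c(1, 2, 1, 2))), log(2),
               tolerance = 1e-12)
  expect_equal(domain_loss(matrix(0, 6, 3), factor(rep(1:3, 2))), log(3),
               tolerance = 1e-12)
  # hand-set true-class probabilities 0.8 and 0.4
  logits <- matrix(c(log(0.8 / 0.2), log(0.4 / 0.6)), 2, 1)
  expect_equal(domain_loss(logits, c(2L, 2L)),
               -(log(0.8) + log(0.4)) / 2, tolerance = 1e-10)
  # near-certain correct predictions -> loss ~ 0
  sure <- matrix(c(50, -50), 2, 1)
  expect_lt(domain_loss(sure, factor(c(2, 1))), 1e-10)
  expect_error(domain_loss(matrix(0, 2, 3), c(1, 5)), "input error")
})

test_that("training reduces the loss and is bitwise reproducible by seed", {
  set.seed(7)
  coords <- cbind(cos(seq_len(50) / 50 * 2 * pi), sin(seq_len(50) / 50 * 2 * pi))
  g <- normalize_adjacency(build_knn_graph(coords, 4))
  x <- matrix(rnorm(50 * 10), 50, 10)
  cfg <- model_config(fc_encoder_dims = c(16, 8), gnn_dims = c(8, 4),
                      epochs = 50, seed = 123)
  r1 <- train_embedding(x, g, config = cfg)
  expect_lt(r1$log$epochs$loss_total[50], r1$log$epochs$loss_total[1])
  r2 <- train_embedding(x, g, config = cfg)
  expect_equal(r1$embedding$z_joint, r2$embedding$z_joint, tolerance = 1e-7)
  expect_equal(dim(r1$embedding$z_joint), c(50L, 12L))
  expect_true(all(is.finite(r1$log$epochs$loss_total)))
})
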