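#' Configuration for the joint embedding model
#'
#' The embedding model couples a denoising autoencoder (DAE) over the reduced
#' expression matrix with a variational graph autoencoder (VGAE) over the
#' spatial graph. The DAE decoder reconstructs the expression from the
#' concatenation of the two latents; the VGAE reconstructs the adjacency by
#' inner products. For multi-batch integration a domain-adversarial
#' classifier is attached to the joint latent through a gradient-reversal
#' layer (GRL).
#'
#' @param fc_encoder_dims widths of the DAE encoder layers; the last entry is
#'   the gene latent dimension R (default \code{c(256, 64)}).
#' @param gnn_dims widths of the VGAE trunk; the last entry is the graph
#'   latent dimension R' (default \code{c(64, 32)}).
#' @param loss_weights list with \code{w_rec}, \code{w_graph},
#'   \code{w_domain} (defaults 10, 0.1, 1).
#' @param epochs training epochs (default 500).
#' @param learning_rate Adam step size (default 1e-3).
#' @param weight_decay L2 penalty on weight matrices (default 1e-4).
#' @param seed RNG seed controlling initialization, input corruption and the
#'   reparameterization noise.
#' @param dan_enabled train the domain-adversarial head (requires batch
#'   labels with >= 2 levels).
#' @param grl_lambda gradient-reversal strength (default 1).
#' @param grl_warmup ramp lambda linearly from 0 over the first 20\% of
#'   epochs (default FALSE: constant lambda).
#' @param disc_lr_scale learning-rate multiplier for the domain-classifier
#'   head (default 1).
#' @param disc_steps inner discriminator updates per epoch (default 5).
#'   Keeping the classifier near its optimum is what makes the adversarial
#'   gradient remove decodable batch signal rather than merely defeating a
#'   stale classifier.
#' @param dan_feature_loss objective whose gradient the reversal layer sends
#'   into the embedding. \code{"confusion"} (default): cross-entropy of the
#'   classifier output against the uniform distribution — non-saturating,
#'   so the embedding keeps receiving pressure even when the classifier is
#'   confident. \code{"reverse"}: the literal negated classifier loss; its
#'   gradient vanishes exactly when the classifier wins (the saturation
#'   problem), so it mixes poorly in full-batch training.
#' @param corruption_sd sd of the Gaussian input corruption applied to the
#'   DAE input during training (default 0.1; the denoising part of the DAE).
#' @param reparam \code{"standard"}: \code{z = mu + exp(0.5 logvar) * eps};
#'   \code{"paper_literal"}: \code{z = mu + logvar * eps}.
#' @return a \code{model_config} list.
#' @export
model_config <- function(fc_encoder_dims = c(256, 64),
                         gnn_dims = c(64, 32),
                         loss_weights = list(w_rec = 10, w_graph = 0.1,
                                             w_domain = 1),
                         epochs = 500, learning_rate = 1e-3,
                         weight_decay = 1e-4, seed = 0L,
                         dan_enabled = FALSE, grl_lambda = 1,
                         grl_warmup = FALSE, disc_lr_scale = 1,
                         disc_steps = 5,
                         dan_feature_loss = c("confusion", "reverse"),
                         corruption_sd = 0.1,
                         reparam = c("standard", "paper_literal")) {
  reparam <- match.arg(reparam)
  dan_feature_loss <- match.arg(dan_feature_loss)
  stopifnot(all(fc_encoder_dims >= 1), all(gnn_dims >= 1), epochs >= 1,
            learning_rate > 0, grl_lambda >= 0, disc_lr_scale > 0,
            disc_steps >= 1, all(unlist(loss_weights) >= 0))
  structure(list(fc_encoder_dims = as.integer(fc_encoder_dims),
                 gnn_dims = as.integer(gnn_dims),
                 loss_weights = loss_weights, epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed), dan_enabled = dan_enabled,
                 grl_lambda = grl_lambda, grl_warmup = grl_warmup,
                 disc_lr_scale = disc_lr_scale,
                 disc_steps = as.integer(disc_steps),
                 dan_feature_loss = dan_feature_loss,
                 corruption_sd = corruption_sd, reparam = reparam),
            class = "model_config")
}

# Glorot-uniform weight matrix
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model parameters
#'
#' @param config a [model_config()].
#' @param in_dim width of the reduced expression matrix.
#' @param n_domains number of batch levels for the adversarial head (0 when
#'   disabled).
#' @return named list of weight matrices / bias vectors.
#' @export
init_model_params <- function(config, in_dim, n_domains = 0L) {
  fd <- config$fc_encoder_dims
  gd <- config$gnn_dims
  r <- fd[length(fd)]
  rp <- gd[length(gd)]
  enc_dims <- c(in_dim, fd)
  dec_dims <- c(r + rp, rev(fd)[-1L], in_dim)
  p <- list()
  for (l in seq_len(length(enc_dims) - 1L)) {
    p[[paste0("We", l)]] <- glorot(enc_dims[l], enc_dims[l + 1L])
    p[[paste0("be", l)]] <- numeric(enc_dims[l + 1L])
  }
  for (l in seq_len(length(dec_dims) - 1L)) {
    p[[paste0("Wd", l)]] <- glorot(dec_dims[l], dec_dims[l + 1L])
    p[[paste0("bd", l)]] <- numeric(dec_dims[l + 1L])
  }
  gt_dims <- c(in_dim, gd)
  for (l in seq_len(length(gt_dims) - 1L))
    p[[paste0("Wg", l)]] <- glorot(gt_dims[l], gt_dims[l + 1L])
  p$Wmu <- glorot(gd[length(gd)], rp)
  p$Wsig <- glorot(gd[length(gd)], rp)
  if (n_domains >= 2L) {
    out <- if (n_domains == 2L) 1L else n_domains
    p$Wc <- glorot(r + rp, out)
    p$bc <- numeric(out)
  }
  attr(p, "n_enc") <- length(enc_dims) - 1L
  attr(p, "n_dec") <- length(dec_dims) - 1L
  attr(p, "n_gnn") <- length(gt_dims) - 1L
  p
}

#' Denoising-autoencoder forward pass
#'
#' Encoder maps the reduced expression \code{x} to the gene latent
#' \code{z_gene}; the decoder input is the concatenation
#' \code{cbind(z_gene, z_graph)} and reconstructs \code{x}. Hidden layers use
#' ReLU; latent and output layers are linear.
#'
#' @param x spots x M reduced expression matrix.
#' @param z_graph spots x R' graph latent (zeros give a pure autoencoder).
#' @param params from [init_model_params()].
#' @return list \code{z_gene}, \code{z_joint}, \code{x_reconstructed}, plus
#'   cached activations for backpropagation.
#' @export
dae_forward <- function(x, z_graph, params) {
  n_enc <- attr(params, "n_enc")
  n_dec <- attr(params, "n_dec")
  if (ncol(x) != nrow(params$We1))
    stop("config error: input width ", ncol(x), " does not match encoder (",
         nrow(params$We1), ")")
  hs <- vector("list", n_enc)
  h <- x
  for (l in seq_len(n_enc)) {
    h <- h %*% params[[paste0("We", l)]] +
      rep(params[[paste0("be", l)]], each = nrow(h))
    if (l < n_enc) h <- pmax(h, 0)
    hs[[l]] <- h
  }
  z_gene <- h
  zj <- cbind(z_gene, z_graph)
  ds <- vector("list", n_dec)
  d <- zj
  for (l in seq_len(n_dec)) {
    d <- d %*% params[[paste0("Wd", l)]] +
      rep(params[[paste0("bd", l)]], each = nrow(d))
    if (l < n_dec) d <- pmax(d, 0)
    ds[[l]] <- d
  }
  list(z_gene = z_gene, z_joint = zj, x_reconstructed = d,
       enc_acts = hs, dec_acts = ds)
}

#' Mean reconstruction loss
#'
#' Mean over spots of the squared Euclidean distance between input and
#' reconstruction.
#'
#' @param x input matrix.
#' @param x_rec reconstruction.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(x, x_rec) {
  sum((x - x_rec)^2) / nrow(x)
}

#' Variational graph-autoencoder encoder
#'
#' Two normalized-adjacency propagation layers with a ReLU in between form
#' the trunk; two separate linear heads on a further propagation produce the
#' posterior mean and log-variance, and the latent is drawn by the
#' reparameterization trick.
#'
#' @param x spots x M reduced expression matrix.
#' @param graph a normalized \code{spatial_graph}.
#' @param params from [init_model_params()].
#' @param eps optional noise matrix (spots x R'); NULL draws standard normal
#'   from the current RNG state, 0 may be passed (recycled) to get
#'   \code{z = mu}.
#' @param reparam \code{"standard"} (default) or \code{"paper_literal"} (see
#'   [model_config()]).
#' @return list \code{mu}, \code{logvar}, \code{z_graph} plus cached
#'   activations.
#' @export
vgae_encode <- function(x, graph, params, eps = NULL,
                        reparam = c("standard", "paper_literal")) {
  reparam <- match.arg(reparam)
  if (is.null(graph$normalized)) graph <- normalize_adjacency(graph)
  at <- graph$normalized
  n_gnn <- attr(params, "n_gnn")
  p1 <- as.matrix(at %*% x)
  t1 <- p1 %*% params$Wg1
  h1 <- pmax(t1, 0)
  q <- as.matrix(at %*% h1)
  xbar <- q %*% params$Wg2
  u <- as.matrix(at %*% xbar)
  mu <- u %*% params$Wmu
  logvar <- u %*% params$Wsig
  if (!all(is.finite(mu)) || !all(is.finite(logvar)))
    stop("training error: non-finite activation in the graph encoder")
  if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu)), nrow(mu))
  else if (length(eps) == 1L) eps <- matrix(eps, nrow(mu), ncol(mu))
  z <- if (reparam == "standard") mu + exp(0.5 * logvar) * eps
       else mu + logvar * eps
  list(mu = mu, logvar = logvar, z_graph = z, eps = eps,
       cache = list(p1 = p1, t1 = t1, h1 = h1, q = q, xbar = xbar, u = u))
}

#' Inner-product edge decoder
#'
#' Edge probability \code{p(A_ij = 1 | z_i, z_j) = sigmoid(z_i . z_j)};
#' symmetric by construction.
#'
#' @param z_graph spots x R' latent matrix.
#' @return spots x spots probability matrix.
#' @export
vgae_decode <- function(z_graph) {
  1 / (1 + exp(-tcrossprod(z_graph)))
}

#' Graph reconstruction + KL loss
#'
#' Returns the value whose minimization maximizes the variational objective
#' (expected edge log-likelihood minus KL): a positive-edge-reweighted binary
#' cross-entropy between the decoded probabilities and the adjacency, plus
#' the mean per-node KL divergence of the diagonal Gaussian posterior from
#' N(0, I), \code{-0.5 * sum(1 + logvar - mu^2 - exp(logvar))}.
#'
#' @param prob edge probability matrix from [vgae_decode()].
#' @param graph \code{spatial_graph} providing the target adjacency.
#' @param mu,logvar posterior parameters.
#' @param pos_weight weight on the positive-edge term; default
#'   \code{(P - |E|) / |E|} with \code{P} the number of scored pairs,
#'   countering graph sparsity.
#' @param pair_mask optional binary matrix marking which pairs the
#'   reconstruction is scored on. Cross-batch pairs of a block-diagonal
#'   integration graph are unobserved (inter-slide distances are not
#'   comparable) and must not be scored as true negatives — scoring them
#'   would force the latent to keep batches linearly separable.
#' @return list \code{total}, \code{bce}, \code{kl}.
#' @export
graph_loss <- function(prob, graph, mu, logvar, pos_weight = NULL,
                       pair_mask = NULL) {
  a <- as.matrix(graph$adjacency)
  n <- nrow(a)
  if (is.null(pair_mask)) pair_mask <- 1
  npairs <- if (is.matrix(pair_mask)) sum(pair_mask) else n^2
  ne <- sum(a)
  if (is.null(pos_weight)) pos_weight <- (npairs - ne) / ne
  p <- pmin(pmax(prob, 1e-10), 1 - 1e-10)
  bce <- -sum(pair_mask * (pos_weight * a * log(p) +
                             (1 - a) * log(1 - p))) / npairs
  kl <- mean(-0.5 * rowSums(1 + logvar - mu^2 - exp(logvar)))
  list(total = bce + kl, bce = bce, kl = kl)
}

#' Gradient-reversal layer
#'
#' Forward pass is the identity; during backpropagation the gradient flowing
#' from the attached head into the features is multiplied by
#' \code{-lambda}. The returned matrix carries lambda as attribute
#' \code{"grl_lambda"}, honoured by the training loop.
#'
#' @param features input matrix.
#' @param lambda reversal strength (>= 0).
#' @return \code{features}, tagged.
#' @export
grl_apply <- function(features, lambda) {
  stopifnot(lambda >= 0)
  attr(features, "grl_lambda") <- lambda
  features
}

#' Domain-classifier forward pass
#'
#' Linear head on the (gradient-reversed) joint latent. With two domains a
#' single sigmoid logit is used; with more, softmax over M columns.
#'
#' @param z input features (spots x (R + R')).
#' @param params parameter list containing \code{Wc}, \code{bc}.
#' @return list \code{logits}, \code{prob} (spots x M, two columns for the
#'   binary case).
#' @export
domain_head_forward <- function(z, params) {
  logits <- z %*% params$Wc + rep(params$bc, each = nrow(z))
  if (ncol(logits) == 1L) {
    p1 <- 1 / (1 + exp(-logits))
    prob <- cbind(1 - p1, p1)
  } else {
    m <- apply(logits, 1L, max)
    e <- exp(logits - m)
    prob <- e / rowSums(e)
  }
  list(logits = logits, prob = prob)
}

#' Domain-classification cross-entropy
#'
#' \code{L_d = -(1/N) sum_i sum_d 1[label_i = d] log p_id} with softmax
#' probabilities for M > 2 classes and the sigmoid form for M = 2 (a single
#' logit column is interpreted as the probability of the second level).
#'
#' @param logits spots x M matrix (or spots x 1 for the binary sigmoid form).
#' @param batch_labels factor (or integer codes 1..M) of true domains.
#' @return scalar loss.
#' @export
domain_loss <- function(logits, batch_labels) {
  logits <- as.matrix(logits)
  y <- if (is.factor(batch_labels)) as.integer(batch_labels)
       else as.integer(batch_labels)
  m <- max(ncol(logits), 2L, length(unique(y)))
  if (any(y < 1L) || any(y > m))
    stop("input error: batch label outside [1, ", m, "]")
  if (ncol(logits) == 1L) {
    p1 <- 1 / (1 + exp(-logits[, 1L]))
    p <- cbind(1 - p1, p1)
  } else {
    mx <- apply(logits, 1L, max)
    e <- exp(logits - mx)
    p <- e / rowSums(e)
  }
  p <- pmin(pmax(p, 1e-12), 1)
  -mean(log(p[cbind(seq_along(y), y)]))
}

#' Gradient of the adversarial loss at the GRL input
#'
#' Analytic gradient of [domain_loss()] with respect to the features entering
#' [grl_apply()]: the classifier-input gradient multiplied by \code{-lambda}.
#' Used by the training loop and testable against finite differences.
#'
#' @param z features entering the GRL (spots x (R + R')).
#' @param batch_labels true domains (factor or integer codes).
#' @param params list with \code{Wc}, \code{bc}.
#' @param lambda reversal strength.
#' @return matrix of the same shape as \code{z}.
#' @export
grl_gradient <- function(z, batch_labels, params, lambda) {
  y <- as.integer(if (is.factor(batch_labels)) batch_labels
                  else factor(batch_labels))
  fw <- domain_head_forward(z, params)
  n <- nrow(z)
  if (ncol(fw$logits) == 1L) {
    g_logit <- matrix((fw$prob[, 2L] - (y == 2L)) / n, ncol = 1L)
  } else {
    onehot <- matrix(0, n, ncol(fw$logits))
    onehot[cbind(seq_len(n), y)] <- 1
    g_logit <- (fw$prob - onehot) / n
  }
  -lambda * (g_logit %*% t(params$Wc))
}
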