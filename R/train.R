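#' Train the joint embedding model
#'
#' Full-graph gradient training of the coupled denoising autoencoder and
#' variational graph autoencoder, minimizing
#' \code{w_rec * L_rec + w_graph * L_graph + w_domain * L_domain} with the
#' Adam update. The adversarial term is present only when
#' \code{config$dan_enabled}; its gradient reaches the joint latent through
#' the gradient-reversal layer. Fully deterministic under
#' \code{config$seed}. The returned embedding is recomputed after training
#' from a clean forward pass with the posterior mean (no corruption, no
#' sampling noise).
#'
#' @param x spots x M reduced expression matrix (stage \code{reduced}).
#' @param graph a \code{spatial_graph} over the same spots.
#' @param batch_labels optional factor of batch membership (required with
#'   >= 2 levels when \code{config$dan_enabled}).
#' @param config a [model_config()].
#' @return list with \code{embedding} (a \code{latent_embedding}: fields
#'   \code{z_gene}, \code{z_graph}, \code{z_joint}, \code{mu},
#'   \code{logvar}), \code{log} (per-epoch losses) and \code{params}.
#' @export
train_embedding <- function(x, graph, batch_labels = NULL,
                            config = model_config()) {
  x <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  n <- nrow(x)
  if (nrow(graph$adjacency) != n)
    stop("consistency error: graph has ", nrow(graph$adjacency),
         " spots, expression has ", n)
  if (is.null(graph$normalized)) graph <- normalize_adjacency(graph)
  at <- graph$normalized
  a_dense <- as.matrix(graph$adjacency)
  ne <- sum(a_dense)
  # cross-batch pairs are unobserved in a block-diagonal integration graph:
  # score edge reconstruction within batches only
  pair_mask <- NULL
  npairs <- n^2
  if (!is.null(batch_labels)) {
    bl <- as.integer(factor(batch_labels))
    pair_mask <- outer(bl, bl, "==") * 1
    npairs <- sum(pair_mask)
  }
  pos_weight <- (npairs - ne) / ne
  w <- config$loss_weights
  dan <- isTRUE(config$dan_enabled)
  if (dan) {
    if (is.null(batch_labels)) stop("dan_enabled requires batch_labels")
    batch_labels <- factor(batch_labels)
    if (nlevels(batch_labels) < 2L)
      stop("dan_enabled requires >= 2 batch levels")
  }
  m_dom <- if (dan) nlevels(batch_labels) else 0L
  y <- if (dan) as.integer(batch_labels) else NULL

  set.seed(config$seed)
  params <- init_model_params(config, ncol(x), m_dom)
  n_enc <- attr(params, "n_enc")
  n_dec <- attr(params, "n_dec")
  r <- config$fc_encoder_dims[length(config$fc_encoder_dims)]
  rp <- config$gnn_dims[length(config$gnn_dims)]
  onehot <- NULL
  if (dan && m_dom > 2L) {
    onehot <- matrix(0, n, m_dom)
    onehot[cbind(seq_len(n), y)] <- 1
  }

  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  lr <- config$learning_rate
  wd <- config$weight_decay
  is_weight <- grepl("^W", names(params))
  t_disc <- 0L

  log_df <- data.frame(epoch = seq_len(config$epochs), loss_total = NA_real_,
                       loss_rec = NA_real_, loss_graph = NA_real_,
                       loss_domain = NA_real_)
  t0 <- proc.time()[["elapsed"]]

  for (epoch in seq_len(config$epochs)) {
    lambda_t <- config$grl_lambda
    if (config$grl_warmup) {
      ramp_end <- max(1, floor(0.2 * config$epochs))
      lambda_t <- config$grl_lambda * min(1, epoch / ramp_end)
    }
    # ---- forward ----
    xc <- x + matrix(stats::rnorm(length(x), sd = config$corruption_sd), n)
    enc <- vgae_encode(x, graph, params, reparam = config$reparam)
    fw <- dae_forward(xc, enc$z_graph, params)
    zj <- if (dan) grl_apply(fw$z_joint, lambda_t) else fw$z_joint

    l_rec <- reconstruction_loss(x, fw$x_reconstructed)
    s <- vgae_decode(enc$z_graph)
    gl <- graph_loss(s, graph, enc$mu, enc$logvar, pos_weight, pair_mask)
    l_dom <- 0
    if (dan) {
      # inner loop: keep the discriminator near-optimal on the current
      # features so the reversed gradient removes decodable signal
      for (st in seq_len(config$disc_steps)) {
        dh <- domain_head_forward(fw$z_joint, params)
        if (m_dom == 2L) {
          gl_d <- matrix((dh$prob[, 2L] - (y == 2L)) / n, ncol = 1L)
        } else {
          gl_d <- (dh$prob - onehot) / n
        }
        for (k in c("Wc", "bc")) {
          gk <- if (k == "Wc") crossprod(fw$z_joint, gl_d) + wd * params$Wc
                else colSums(gl_d)
          t_disc <- t_disc + (k == "Wc")
          adam_m[[k]] <- b1 * adam_m[[k]] + (1 - b1) * gk
          adam_v[[k]] <- b2 * adam_v[[k]] + (1 - b2) * gk^2
          mhat <- adam_m[[k]] / (1 - b1^t_disc)
          vhat <- adam_v[[k]] / (1 - b2^t_disc)
          params[[k]] <- params[[k]] -
            lr * config$disc_lr_scale * mhat / (sqrt(vhat) + eps_adam)
        }
      }
      dh <- domain_head_forward(zj, params)
      l_dom <- domain_loss(dh$logits, batch_labels)
    }
    total <- w$w_rec * l_rec + w$w_graph * gl$total +
      (if (dan) w$w_domain * l_dom else 0)
    if (!is.finite(total)) {
      last <- if (epoch > 1L) epoch - 1L else 0L
      stop("training error: non-finite loss at epoch ", epoch,
           " (last finite epoch: ", last, ")")
    }
    log_df[epoch, 2:5] <- c(total, l_rec, gl$total, l_dom)

    # ---- backward ----
    grads <- vector("list", length(params))
    names(grads) <- names(params)

    # reconstruction head
    g <- w$w_rec * (2 / n) * (fw$x_reconstructed - x)
    dec_inputs <- c(list(fw$z_joint), fw$dec_acts[-n_dec])
    for (l in n_dec:1) {
      grads[[paste0("Wd", l)]] <- crossprod(dec_inputs[[l]], g)
      grads[[paste0("bd", l)]] <- colSums(g)
      g <- g %*% t(params[[paste0("Wd", l)]])
      if (l > 1L) g <- g * (fw$dec_acts[[l - 1L]] > 0)
    }
    g_zj <- g

    # adversarial pressure into the latent (discriminator already updated)
    if (dan) {
      if (config$dan_feature_loss == "confusion") {
        # descend on CE(classifier output, uniform): non-saturating
        if (m_dom == 2L) {
          g_logit <- matrix((dh$prob[, 2L] - 0.5) / n, ncol = 1L)
        } else {
          g_logit <- (dh$prob - 1 / m_dom) / n
        }
        g_zj <- g_zj + lambda_t * w$w_domain * (g_logit %*% t(params$Wc))
      } else {
        # literal gradient reversal of the classifier loss
        if (m_dom == 2L) {
          g_logit <- matrix((dh$prob[, 2L] - (y == 2L)) / n, ncol = 1L)
        } else {
          g_logit <- (dh$prob - onehot) / n
        }
        g_zj <- g_zj - lambda_t * w$w_domain * (g_logit %*% t(params$Wc))
      }
    }

    g_zg <- g_zj[, seq_len(r), drop = FALSE]
    g_z <- g_zj[, r + seq_len(rp), drop = FALSE]

    # edge-reconstruction path
    gA <- w$w_graph *
      (pos_weight * a_dense * (s - 1) + (1 - a_dense) * s) / npairs
    if (!is.null(pair_mask)) gA <- gA * pair_mask
    g_z <- g_z + (gA + t(gA)) %*% enc$z_graph

    # reparameterization + KL
    if (config$reparam == "standard") {
      g_mu <- g_z + w$w_graph * enc$mu / n
      g_lv <- g_z * enc$eps * 0.5 * exp(0.5 * enc$logvar) +
        w$w_graph * 0.5 * (exp(enc$logvar) - 1) / n
    } else {
      g_mu <- g_z + w$w_graph * enc$mu / n
      g_lv <- g_z * enc$eps + w$w_graph * 0.5 * (exp(enc$logvar) - 1) / n
    }

    cc <- enc$cache
    grads$Wmu <- crossprod(cc$u, g_mu)
    grads$Wsig <- crossprod(cc$u, g_lv)
    g_u <- g_mu %*% t(params$Wmu) + g_lv %*% t(params$Wsig)
    g_xbar <- as.matrix(at %*% g_u)
    grads$Wg2 <- crossprod(cc$q, g_xbar)
    g_q <- g_xbar %*% t(params$Wg2)
    g_h1 <- as.matrix(at %*% g_q)
    g_t1 <- g_h1 * (cc$t1 > 0)
    grads$Wg1 <- crossprod(cc$p1, g_t1)

    # DAE encoder
    g <- g_zg
    enc_inputs <- c(list(xc), fw$enc_acts[-n_enc])
    for (l in n_enc:1) {
      grads[[paste0("We", l)]] <- crossprod(enc_inputs[[l]], g)
      grads[[paste0("be", l)]] <- colSums(g)
      if (l > 1L) {
        g <- g %*% t(params[[paste0("We", l)]])
        g <- g * (fw$enc_acts[[l - 1L]] > 0)
      }
    }

    # ---- Adam update (discriminator handled in its inner loop) ----
    for (k in setdiff(names(params), c("Wc", "bc"))) {
      gk <- grads[[k]]
      if (is.null(gk)) next
      if (is_weight[match(k, names(params))]) gk <- gk + wd * params[[k]]
      adam_m[[k]] <- b1 * adam_m[[k]] + (1 - b1) * gk
      adam_v[[k]] <- b2 * adam_v[[k]] + (1 - b2) * gk^2
      mhat <- adam_m[[k]] / (1 - b1^epoch)
      vhat <- adam_v[[k]] / (1 - b2^epoch)
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps_adam)
    }
  }

  # ---- inference pass: clean input, posterior mean ----
  enc <- vgae_encode(x, graph, params, eps = 0, reparam = config$reparam)
  fw <- dae_forward(x, enc$mu, params)
  emb <- structure(list(z_gene = fw$z_gene, z_graph = enc$mu,
                        z_joint = fw$z_joint, mu = enc$mu,
                        logvar = enc$logvar),
                   class = "latent_embedding")
  log <- structure(list(epochs = log_df, seed = config$seed,
                        wall_seconds = proc.time()[["elapsed"]] - t0),
                   class = "training_log")
  list(embedding = emb, log = log, params = params, config = config)
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("latent_embedding: %d spots, z_gene %d + z_graph %d = z_joint %d\n",
              nrow(x$z_joint), ncol(x$z_gene), ncol(x$z_graph),
              ncol(x$z_joint)))
  invisible(x)
}

#' @export
print.training_log <- function(x, ...) {
  e <- x$epochs
  cat(sprintf("training_log: %d epochs in %.1fs (seed %d)\n", nrow(e),
              x$wall_seconds, x$seed))
  cat(sprintf("  loss %0.4f -> %0.4f (rec %0.4f, graph %0.4f, domain %0.4f)\n",
              e$loss_total[1L], e$loss_total[nrow(e)],
              e$loss_rec[nrow(e)], e$loss_graph[nrow(e)],
              e$loss_domain[nrow(e)]))
  invisible(x)
}
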