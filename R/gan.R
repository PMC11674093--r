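#' Configuration for the class-conditional augmentation GAN
#'
#' The augmentation model is a generative adversarial network modified
#' for labeled tabular expression data: the generator receives a one-hot
#' class vector `c` concatenated with Gaussian noise `z` and emits an
#' expression vector over the selected gene panel; the discriminator has
#' two heads, a source head estimating P(source = real) and an auxiliary
#' class head estimating P(class). Training alternates discriminator
#' ascent of `loss_x + loss_c` (see [gan_losses()]) with a generator
#' update under the chosen objective.
#'
#' @param noise_dim dimension of the noise vector `z`.
#' @param hidden_sizes hidden-layer widths shared by both networks.
#' @param epochs training epochs.
#' @param batch_size samples per update; `NULL` uses the full training
#'   fold (folds here hold ~10 samples, so mini-batching buys nothing).
#' @param learning_rate Adam step size for both players.
#' @param d_steps_per_g_step discriminator updates per generator update.
#' @param generator_objective `"ac_gan_standard"` (default): the
#'   generator ascends `log P(source = real | fake) + log P(class =
#'   intended | fake)` — the non-saturating auxiliary-classifier form.
#'   `"paper_literal"`: the generator descends `loss_x + loss_c` exactly
#'   as written, which also penalizes fakes being *correctly* classified;
#'   kept available for fidelity experiments (see the methods vignette).
#' @param filter_threshold optional probability in [0, 1]: generated
#'   vectors whose discriminator class probability for the intended class
#'   falls below it are rejected and resampled (bounded retries).
#' @param instance_noise standard deviation (on the standardized feature
#'   scale) of Gaussian noise added to both real and fake discriminator
#'   inputs, linearly annealed to zero over training. Instance noise
#'   keeps the two input distributions overlapping early on, which
#'   stabilizes the adversarial game and prevents variance collapse on
#'   low-dimensional tabular data. Set 0 to disable.
#' @param moment_weight weight of an auxiliary class-conditional moment-
#'   matching penalty in the generator objective: the mean squared gap
#'   between generated and real per-class feature means and variances
#'   (on the standardized scale). A purely adversarial generator matches
#'   class-conditional moments only loosely at the ~10-sample fold sizes
#'   this model targets; the penalty anchors the synthetic class
#'   distributions to the training fold without touching the
#'   discriminator's game. Set 0 for a purely adversarial generator.
#' @param seed integer RNG seed.
#' @return a `gan_config` list.
#' @export
gan_config <- function(noise_dim = 8L, hidden_sizes = c(32L, 32L),
                       epochs = 4000L, batch_size = NULL,
                       learning_rate = 2e-3, d_steps_per_g_step = 1L,
                       generator_objective = c("ac_gan_standard", "paper_literal"),
                       filter_threshold = NULL, instance_noise = 0.5,
                       moment_weight = 20, seed = 1L) {
  generator_objective <- match.arg(generator_objective)
  cfg <- list(noise_dim = as.integer(noise_dim),
              hidden_sizes = as.integer(hidden_sizes),
              epochs = as.integer(epochs),
              batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
              learning_rate = as.numeric(learning_rate),
              d_steps_per_g_step = as.integer(d_steps_per_g_step),
              generator_objective = generator_objective,
              filter_threshold = filter_threshold,
              instance_noise = as.numeric(instance_noise),
              moment_weight = as.numeric(moment_weight),
              seed = as.integer(seed))
  if (cfg$noise_dim < 1L) stop_config("noise_dim must be >= 1")
  if (cfg$epochs < 1L) stop_config("epochs must be >= 1")
  if (!is.null(cfg$filter_threshold) &&
      (cfg$filter_threshold < 0 || cfg$filter_threshold > 1)) {
    stop_config("filter_threshold must be in [0, 1]")
  }
  class(cfg) <- "gan_config"
  cfg
}

#' Source and class losses of the modified GAN
#'
#' `loss_x` is the expected log-probability of the source head being
#' right on both real and fake batches; `loss_c` is the expected
#' log-probability of the class head naming the true class on real
#' samples and the intended class on fakes. Both are batch means of
#' log-probabilities, hence always <= 0, with 0 attained only at perfect
#' confidence. Probabilities are clamped at 1e-7 before the log; no sign
#' flips are hidden inside — the discriminator *maximizes*
#' `loss_x + loss_c`.
#'
#' @param d_real_source P(source = real) on the real batch.
#' @param d_fake_source P(source = fake) on the fake batch.
#' @param d_real_class optional list(`probs` = n x K class-probability
#'   matrix with class colnames, `classes` = true class per row).
#' @param d_fake_class same, with `classes` = intended class per row.
#' @return list with `loss_x` and `loss_c` (`loss_c` is NA when no class
#'   head output is supplied).
#' @export
gan_losses <- function(d_real_source, d_fake_source,
                       d_real_class = NULL, d_fake_class = NULL) {
  if (length(d_real_source) == 0L || length(d_fake_source) == 0L) {
    stop_config("empty batch in gan_losses")
  }
  clamp <- function(p) pmin(pmax(p, 1e-7), 1)
  loss_x <- mean(log(clamp(d_real_source))) + mean(log(clamp(d_fake_source)))
  loss_c <- NA_real_
  if (!is.null(d_real_class) && !is.null(d_fake_class)) {
    pick <- function(cls) {
      P <- cls$probs
      idx <- cbind(seq_len(nrow(P)), match(as.character(cls$classes), colnames(P)))
      if (anyNA(idx)) stop_config("class not found among class-head columns")
      P[idx]
    }
    loss_c <- mean(log(clamp(pick(d_real_class)))) +
      mean(log(clamp(pick(d_fake_class))))
  }
  list(loss_x = loss_x, loss_c = loss_c)
}

# ---- minimal MLP machinery (leaky-ReLU trunk + linear heads, Adam) ----

lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
dlrelu <- function(z) ifelse(z > 0, 1, 0.2)

init_layer <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

# X: batch x d_in. Returns activations of every hidden layer.
trunk_fwd <- function(layers, X) {
  A <- list(X)
  Z <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    Z[[i]] <- sweep(A[[i]] %*% layers[[i]]$W, 2L, layers[[i]]$b, `+`)
    A[[i + 1L]] <- lrelu(Z[[i]])
  }
  list(A = A, Z = Z)
}

# dTop: gradient w.r.t. the trunk's top activation. Returns per-layer
# parameter gradients plus the gradient w.r.t. the trunk input.
trunk_bwd <- function(layers, cache, dTop) {
  L <- length(layers)
  grads <- vector("list", L)
  dA <- dTop
  for (i in rev(seq_len(L))) {
    dZ <- dA * dlrelu(cache$Z[[i]])
    grads[[i]] <- list(W = crossprod(cache$A[[i]], dZ), b = colSums(dZ))
    dA <- dZ %*% t(layers[[i]]$W)
  }
  list(grads = grads, dX = dA)
}

adam_new <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0), how = "replace",
         classes = c("matrix", "numeric", "integer", "array"))
}

# params/grads/state share one nested list shape; `direction` +1 ascends,
# -1 descends the objective whose gradient is supplied.
adam_step <- function(params, grads, state, lr, t, direction = -1) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  # direction = +1 ascends (p + lr*step), -1 descends (p - lr*step)
  walk2 <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- walk2(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      mhat <- s$m / (1 - b1^t)
      vhat <- s$v / (1 - b2^t)
      list(p = p + direction * lr * mhat / (sqrt(vhat) + eps), s = s)
    }
  }
  walk2(params, grads, state)
}

softmax_rows <- function(L) {
  M <- L - apply(L, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}

disc_fwd <- function(D, X) {
  tf <- trunk_fwd(D$trunk, X)
  H <- tf$A[[length(tf$A)]]
  s <- drop(H %*% D$src$W + D$src$b)
  logits <- sweep(H %*% D$cls$W, 2L, D$cls$b, `+`)
  list(p_src = 1 / (1 + exp(-s)), p_cls = softmax_rows(logits), H = H, cache = tf)
}

gen_fwd <- function(G, C_onehot, Z) {
  inp <- cbind(C_onehot, Z)
  tf <- trunk_fwd(G$trunk, inp)
  H <- tf$A[[length(tf$A)]]
  Xf <- sweep(H %*% G$out$W, 2L, G$out$b, `+`)
  list(X = Xf, H = H, cache = tf)
}

# Accumulate head + trunk gradients for the discriminator given
# per-sample gradients w.r.t. source logit (ds) and class logits (dlog).
disc_grads <- function(D, fwd, ds, dlog) {
  H <- fwd$H
  g <- list(trunk = NULL,
            src = list(W = crossprod(H, matrix(ds, ncol = 1)), b = sum(ds)),
            cls = list(W = crossprod(H, dlog), b = colSums(dlog)))
  dH <- matrix(ds, ncol = 1) %*% t(D$src$W) + dlog %*% t(D$cls$W)
  tb <- trunk_bwd(D$trunk, fwd$cache, dH)
  g$trunk <- tb$grads
  list(grads = g, dX = tb$dX)
}

sum_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- sum_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

one_hot <- function(classes, levels_) {
  M <- matrix(0, length(classes), length(levels_),
              dimnames = list(NULL, levels_))
  M[cbind(seq_along(classes), match(as.character(classes), levels_))] <- 1
  M
}

init_gan_nets <- function(p, K, cfg) {
  gen_sizes <- c(K + cfg$noise_dim, cfg$hidden_sizes)
  dis_sizes <- c(p, cfg$hidden_sizes)
  h_top <- utils::tail(cfg$hidden_sizes, 1L)
  G <- list(trunk = lapply(seq_len(length(gen_sizes) - 1L), function(i) {
    init_layer(gen_sizes[i], gen_sizes[i + 1L])
  }), out = init_layer(h_top, p))
  D <- list(trunk = lapply(seq_len(length(dis_sizes) - 1L), function(i) {
    init_layer(dis_sizes[i], dis_sizes[i + 1L])
  }), src = init_layer(h_top, 1L), cls = init_layer(h_top, K))
  D$src$b <- 0
  list(G = G, D = D)
}

# One discriminator ascent step on (real, fake) batches; returns updated
# D, its Adam state, and the achieved losses.
d_step <- function(D, d_state, G_out_fake, X_real, Y_real, Y_fake, lr, t) {
  Br <- nrow(X_real); Bf <- nrow(G_out_fake)
  fr <- disc_fwd(D, X_real)
  ff <- disc_fwd(D, G_out_fake)
  colnames(fr$p_cls) <- colnames(Y_real)
  colnames(ff$p_cls) <- colnames(Y_fake)
  losses <- gan_losses(fr$p_src, 1 - ff$p_src,
                       list(probs = fr$p_cls, classes = colnames(Y_real)[max.col(Y_real)]),
                       list(probs = ff$p_cls, classes = colnames(Y_fake)[max.col(Y_fake)]))
  # ascend loss_x + loss_c
  ds_r <- (1 - fr$p_src) / Br                 # d/ds of mean log sigma(s)
  ds_f <- (-ff$p_src) / Bf                    # d/ds of mean log(1 - sigma(s))
  dlog_r <- (Y_real - fr$p_cls) / Br          # d/dlogits of mean log softmax_true
  dlog_f <- (Y_fake - ff$p_cls) / Bf
  gr <- disc_grads(D, fr, ds_r, dlog_r)
  gf <- disc_grads(D, ff, ds_f, dlog_f)
  g <- sum_grads(gr$grads, gf$grads)
  upd <- adam_step(D, g, d_state, lr, t, direction = +1)
  list(D = upd$p, state = upd$s, losses = losses)
}

#' Train the class-conditional augmentation GAN on a training fold
#'
#' Features (genes) are standardized to zero mean and unit variance on
#' the training fold before training; [generate_samples()] inverts the
#' scaling. Updates alternate `d_steps_per_g_step` discriminator ascent
#' steps of `loss_x + loss_c` with one generator step under
#' `cfg$generator_objective`. Fake batches mirror the real batch's class
#' composition, so the generator is never asked for classes absent from
#' the fold. Deterministic given `cfg$seed`.
#'
#' @param X_panel panel-genes x samples matrix (the training fold only).
#' @param y class labels aligned to `colnames(X_panel)`.
#' @param cfg a [gan_config()].
#' @return a `gan_model`: generator/discriminator parameters, per-gene
#'   `feature_scaling`, class levels, and `loss_history` (one `loss_x`,
#'   `loss_c` row per epoch).
#' @export
train_gan <- function(X_panel, y, cfg = gan_config()) {
  validate_expression(X_panel)
  y <- align_labels(X_panel, y)
  y <- droplevels(y)
  if (any(table(y) < 2L)) stop_config("every class in the training fold needs >= 2 samples")
  p <- nrow(X_panel); K <- nlevels(y); n <- ncol(X_panel)
  Z <- standardize_genes(X_panel)
  scaling <- list(center = attr(Z, "center"), scale = attr(Z, "scale"))
  Xr <- t(Z)                                   # samples x genes
  Yr <- one_hot(y, levels(y))
  B <- min(cfg$batch_size %||% n, n)

  # per-class real moments on the standardized scale (moment-matching
  # targets for the generator)
  real_mu <- do.call(rbind, lapply(levels(y), function(cl) {
    rowMeans(Z[, y == cl, drop = FALSE])
  }))
  real_v <- do.call(rbind, lapply(levels(y), function(cl) {
    M <- Z[, y == cl, drop = FALSE]
    rowMeans((M - rowMeans(M))^2)
  }))

  with_seed(cfg$seed, {
    nets <- init_gan_nets(p, K, cfg)
    G <- nets$G; D <- nets$D
    G_ema <- G
    ema_decay <- 0.995
    g_state <- adam_new(G); d_state <- adam_new(D)
    hist <- data.frame(epoch = seq_len(cfg$epochs),
                       loss_x = NA_real_, loss_c = NA_real_)
    t_d <- 0L; t_g <- 0L
    for (ep in seq_len(cfg$epochs)) {
      idx <- if (B < n) sample.int(n, B) else seq_len(n)
      Xb <- Xr[idx, , drop = FALSE]; Yb <- Yr[idx, , drop = FALSE]
      # linear anneals: instance noise and step size both shrink to zero,
      # damping the limit-cycle oscillation of the adversarial game
      inoise <- cfg$instance_noise * (1 - (ep - 1) / cfg$epochs)
      lr_ep <- cfg$learning_rate * (1 - (ep - 1) / cfg$epochs)
      for (s in seq_len(cfg$d_steps_per_g_step)) {
        Zn <- matrix(stats::rnorm(nrow(Xb) * cfg$noise_dim), nrow(Xb))
        gf <- gen_fwd(G, Yb, Zn)
        Xb_n <- Xb + inoise * matrix(stats::rnorm(length(Xb)), nrow(Xb))
        Xf_n <- gf$X + inoise * matrix(stats::rnorm(length(gf$X)), nrow(gf$X))
        t_d <- t_d + 1L
        st <- d_step(D, d_state, Xf_n, Xb_n, Yb, Yb, lr_ep, t_d)
        D <- st$D; d_state <- st$state
      }
      hist$loss_x[ep] <- st$losses$loss_x
      hist$loss_c[ep] <- st$losses$loss_c
      # generator step (fake batch gets the same instance noise the
      # discriminator was trained with; additive noise passes gradients
      # through unchanged)
      Zn <- matrix(stats::rnorm(nrow(Xb) * cfg$noise_dim), nrow(Xb))
      gf <- gen_fwd(G, Yb, Zn)
      ff <- disc_fwd(D, gf$X + inoise * matrix(stats::rnorm(length(gf$X)), nrow(gf$X)))
      Bf <- nrow(gf$X)
      if (cfg$generator_objective == "ac_gan_standard") {
        # ascend mean log sigma(s_fake) + mean log P(intended | fake)
        ds_f <- (1 - ff$p_src) / Bf
        dlog_f <- (Yb - ff$p_cls) / Bf
        direction <- +1
      } else {
        # descend loss_x + loss_c in its fake terms exactly as written
        ds_f <- (-ff$p_src) / Bf                # d/ds of mean log(1 - sigma)
        dlog_f <- (Yb - ff$p_cls) / Bf          # d/dlogits of mean log P(intended)
        direction <- -1
      }
      dg <- disc_grads(D, ff, ds_f, dlog_f)
      dXf <- dg$dX
      if (cfg$moment_weight > 0) {
        # gradient of mean_{c,j} [(mu_f - mu_r)^2 + (v_f - v_r)^2] on the
        # clean generator output; sign arranged so the penalty is always
        # descended whatever `direction` does to the adversarial term
        dMM <- matrix(0, nrow(gf$X), p)
        cls_idx <- max.col(Yb)
        for (c_i in unique(cls_idx)) {
          rows <- which(cls_idx == c_i)
          nc <- length(rows)
          Xc <- gf$X[rows, , drop = FALSE]
          mu_f <- colMeans(Xc)
          v_f <- colMeans(sweep(Xc, 2L, mu_f)^2)
          d_mu <- 2 * (mu_f - real_mu[c_i, ]) / nc
          d_v <- 2 * (v_f - real_v[c_i, ]) / nc
          dMM[rows, ] <- matrix(d_mu, nc, p, byrow = TRUE) +
            sweep(Xc, 2L, mu_f) * 2 * matrix(d_v, nc, p, byrow = TRUE)
        }
        dMM <- dMM / (K * p)
        dXf <- dXf - direction * cfg$moment_weight * dMM
      }
      tb <- trunk_bwd(G$trunk, gf$cache, dXf %*% t(G$out$W))
      g_grads <- list(trunk = tb$grads,
                      out = list(W = crossprod(gf$H, dXf), b = colSums(dXf)))
      t_g <- t_g + 1L
      upd <- adam_step(G, g_grads, g_state, lr_ep, t_g,
                       direction = direction)
      G <- upd$p; g_state <- upd$s
      G_ema <- ema_params(G_ema, G, ema_decay)
    }
    structure(list(generator = G_ema, discriminator = D,
                   feature_scaling = scaling, classes = levels(y),
                   gene_ids = rownames(X_panel), loss_history = hist,
                   config = cfg),
              class = "gan_model")
  })
}

#' Sample labeled synthetic expression vectors from a trained GAN
#'
#' Draws noise, conditions the generator on `class_label`, and returns
#' vectors on the original expression scale (inverse of the training
#' standardization). When the model's `filter_threshold` is set, vectors
#' whose discriminator class probability for `class_label` falls below it
#' are rejected and resampled for up to 20 rounds; if the quota is still
#' unmet the short set is returned with a warning.
#'
#' @param model a `gan_model` from [train_gan()].
#' @param class_label class to condition on (must have been seen in
#'   training).
#' @param n number of vectors to draw.
#' @param seed integer RNG seed.
#' @return an n x p matrix (rows are synthetic samples named
#'   `syn_<class>_<i>`) with attributes `class_label` and
#'   `origin = "synthetic"`.
#' @export
generate_samples <- function(model, class_label, n, seed = 1L) {
  stopifnot(inherits(model, "gan_model"))
  if (!as.character(class_label) %in% model$classes) {
    stop_config("class '%s' was not seen during GAN training", class_label)
  }
  p <- length(model$gene_ids)
  if (n == 0L) {
    out <- matrix(numeric(0), 0L, p, dimnames = list(NULL, model$gene_ids))
    attr(out, "class_label") <- as.character(class_label)
    attr(out, "origin") <- "synthetic"
    return(out)
  }
  thr <- model$config$filter_threshold
  with_seed(seed, {
    draw <- function(m) {
      C <- one_hot(rep(as.character(class_label), m), model$classes)
      Zn <- matrix(stats::rnorm(m * model$config$noise_dim), m)
      gen_fwd(model$generator, C, Zn)$X
    }
    if (is.null(thr)) {
      Xs <- draw(n)
    } else {
      kept <- matrix(numeric(0), 0L, p)
      rounds <- 0L
      k <- match(as.character(class_label), model$classes)
      while (nrow(kept) < n && rounds < 20L) {
        rounds <- rounds + 1L
        cand <- draw(n)
        pc <- disc_fwd(model$discriminator, cand)$p_cls[, k]
        kept <- rbind(kept, cand[pc >= thr, , drop = FALSE])
      }
      if (nrow(kept) < n) {
        warning(sprintf(
          "discriminator-confidence filter kept only %d of %d requested samples for class '%s'",
          nrow(kept), n, class_label), call. = FALSE)
      }
      Xs <- kept[seq_len(min(n, nrow(kept))), , drop = FALSE]
    }
    Xs <- sweep(sweep(Xs, 2L, model$feature_scaling$scale, `*`),
                2L, model$feature_scaling$center, `+`)
    dimnames(Xs) <- list(sprintf("syn_%s_%03d", class_label, seq_len(nrow(Xs))),
                         model$gene_ids)
    attr(Xs, "class_label") <- as.character(class_label)
    attr(Xs, "origin") <- "synthetic"
    Xs
  })
}

#' Moment-matching diagnostics for a trained GAN
#'
#' Compares per-gene, per-class generated means against real training
#' means, in units of the real within-class standard deviation.
#'
#' @param model a `gan_model`.
#' @param X_panel,y the real data the model was trained on.
#' @param n_per_class generated samples per class.
#' @param seed RNG seed for generation.
#' @return list with `z_diff` (genes x classes matrix of
#'   |generated mean - real mean| / real SD) and `fraction_within`
#'   (function of a threshold in SD units).
#' @export
gan_diagnostics <- function(model, X_panel, y, n_per_class = 200L, seed = 1L) {
  y <- align_labels(X_panel, y)
  z <- matrix(NA_real_, nrow(X_panel), length(model$classes),
              dimnames = list(rownames(X_panel), model$classes))
  for (k in seq_along(model$classes)) {
    cl <- model$classes[k]
    real <- X_panel[, y == cl, drop = FALSE]
    gen <- generate_samples(model, cl, n_per_class, seed = derive_seed(seed, k))
    sds <- apply(real, 1L, stats::sd)
    sds[sds == 0] <- 1
    z[, k] <- abs(colMeans(gen) - rowMeans(real)) / sds
  }
  list(z_diff = z,
       fraction_within = function(sd_units) mean(z <= sd_units))
}

# Discriminator-only training on fixed real/fake batches; used to check
# that ascent of loss_x actually increases it when the two sources are
# separable.
train_discriminator_only <- function(X_real, X_fake, y_real, y_fake, cfg) {
  K <- nlevels(y_real)
  with_seed(cfg$seed, {
    D <- init_gan_nets(ncol(X_real), K, cfg)$D
    d_state <- adam_new(D)
    Yr <- one_hot(y_real, levels(y_real))
    Yf <- one_hot(y_fake, levels(y_real))
    hist <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      st <- d_step(D, d_state, X_fake, X_real, Yr, Yf, cfg$learning_rate, ep)
      D <- st$D; d_state <- st$state
      hist[ep] <- st$losses$loss_x
    }
    list(D = D, loss_x_history = hist)
  })
}

# exponential moving average over nested parameter lists
ema_params <- function(avg, cur, decay) {
  if (is.list(avg)) {
    for (nm in seq_along(avg)) avg[[nm]] <- ema_params(avg[[nm]], cur[[nm]], decay)
    avg
  } else decay * avg + (1 - decay) * cur
}
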