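# Conditional masked autoregressive flow (MAF).
#
# A stack of MADE blocks (Germain et al. masks) models the conditional
# density q(theta | x): each block shifts and scales one coordinate given
# the preceding coordinates (autoregressive) and the conditioning
# features (fully connected), with a standard-normal base distribution.
# Training minimizes the negative log-likelihood with Adam; gradients are
# computed by hand-written backpropagation through the masked layers, so
# no external autodiff framework is needed.  Scales are soft-clamped with
# a tanh to keep the transform well-conditioned.

ALPHA_MAX <- 4  # soft clamp on log-scales

maf_masks <- function(d, hidden, rng) {
  deg_in <- seq_len(d)
  deg_h <- if (d == 1) rep(0L, hidden) else {
    1L + (seq_len(hidden) - 1L) %% (d - 1L)
  }
  m1 <- outer(deg_h, deg_in, ">=") * 1     # hidden x d
  m2 <- outer(c(deg_in, deg_in), deg_h, ">") * 1  # 2d x hidden
  list(m1 = m1, m2 = m2)
}

maf_init <- function(d_theta, d_context, n_transforms = 5, hidden = 50,
                     seed = 1) {
  set.seed(seed)
  transforms <- vector("list", n_transforms)
  perm <- seq_len(d_theta)
  for (k in seq_len(n_transforms)) {
    msk <- maf_masks(d_theta, hidden, NULL)
    sc1 <- sqrt(1 / max(1, d_theta + d_context))
    sc2 <- sqrt(1 / max(1, hidden + d_context))
    transforms[[k]] <- list(
      perm = perm,
      m1 = msk$m1, m2 = msk$m2,
      W1 = matrix(stats::rnorm(hidden * d_theta, 0, sc1), hidden, d_theta) *
        msk$m1,
      A1 = matrix(stats::rnorm(hidden * d_context, 0, sc1), hidden,
                  d_context),
      b1 = rep(0, hidden),
      W2 = matrix(stats::rnorm(2 * d_theta * hidden, 0, 0.01 * sc2),
                  2 * d_theta, hidden) * msk$m2,
      A2 = matrix(stats::rnorm(2 * d_theta * d_context, 0, 0.01 * sc2),
                  2 * d_theta, d_context),
      b2 = rep(0, 2 * d_theta)
    )
    perm <- rev(perm)
  }
  list(d_theta = d_theta, d_context = d_context, hidden = hidden,
       n_transforms = n_transforms, transforms = transforms)
}

# forward pass through one MADE block; returns intermediates for backprop
made_forward <- function(tr, u, ctx) {
  d <- ncol(u)
  h <- tanh(u %*% t(tr$W1 * tr$m1) + ctx %*% t(tr$A1) +
              matrix(tr$b1, nrow(u), length(tr$b1), byrow = TRUE))
  out <- h %*% t(tr$W2 * tr$m2) + ctx %*% t(tr$A2) +
    matrix(tr$b2, nrow(u), length(tr$b2), byrow = TRUE)
  mu <- out[, seq_len(d), drop = FALSE]
  raw <- out[, d + seq_len(d), drop = FALSE]
  alpha <- ALPHA_MAX * tanh(raw / ALPHA_MAX)
  list(h = h, mu = mu, alpha = alpha)
}

# log q(theta | ctx) for a batch; returns vector, optionally with cache
maf_log_prob <- function(flow, theta, ctx, cache = FALSE) {
  n <- nrow(theta)
  u <- theta
  logdet <- numeric(n)
  caches <- if (cache) vector("list", flow$n_transforms) else NULL
  for (k in seq_len(flow$n_transforms)) {
    tr <- flow$transforms[[k]]
    v <- u[, tr$perm, drop = FALSE]
    f <- made_forward(tr, v, ctx)
    z <- (v - f$mu) * exp(-f$alpha)
    logdet <- logdet - rowSums(f$alpha)
    if (cache) caches[[k]] <- list(v = v, h = f$h, mu = f$mu,
                                   alpha = f$alpha, z = z)
    u <- z
  }
  lp <- -0.5 * rowSums(u^2) - 0.5 * flow$d_theta * log(2 * pi) + logdet
  if (cache) list(lp = lp, z = u, caches = caches) else lp
}

# gradient of mean NLL wrt all weights (list mirroring transforms)
maf_backward <- function(flow, theta, ctx) {
  fw <- maf_log_prob(flow, theta, ctx, cache = TRUE)
  n <- nrow(theta)
  g <- fw$z / n   # d(meanNLL)/dz for the 0.5 z^2 term
  grads <- vector("list", flow$n_transforms)
  for (k in rev(seq_len(flow$n_transforms))) {
    tr <- flow$transforms[[k]]
    cc <- fw$caches[[k]]
    ea <- exp(-cc$alpha)
    dmu <- -g * ea
    dalpha <- -g * cc$z + 1 / n              # + direct logdet term
    draw <- dalpha * (1 - (cc$alpha / ALPHA_MAX)^2)
    dout <- cbind(dmu, draw)
    W2m <- tr$W2 * tr$m2
    dh <- dout %*% W2m
    dpre <- dh * (1 - cc$h^2)
    grads[[k]] <- list(
      W2 = (t(dout) %*% cc$h) * tr$m2,
      A2 = t(dout) %*% ctx,
      b2 = colSums(dout),
      W1 = (t(dpre) %*% cc$v) * tr$m1,
      A1 = t(dpre) %*% ctx,
      b1 = colSums(dpre)
    )
    du_perm <- g * ea + dpre %*% (tr$W1 * tr$m1)
    g_prev <- matrix(0, n, flow$d_theta)
    g_prev[, tr$perm] <- du_perm
    g <- g_prev
  }
  list(grads = grads, nll = -mean(fw$lp))
}

# draw n samples from q(. | ctx) by sequential inversion
maf_sample <- function(flow, n, ctx_row) {
  ctx <- matrix(ctx_row, n, length(ctx_row), byrow = TRUE)
  d <- flow$d_theta
  u <- matrix(stats::rnorm(n * d), n, d)
  for (k in rev(seq_len(flow$n_transforms))) {
    tr <- flow$transforms[[k]]
    z <- u
    v <- matrix(0, n, d)
    for (i in seq_len(d)) {
      f <- made_forward(tr, v, ctx)
      v[, i] <- z[, i] * exp(f$alpha[, i]) + f$mu[, i]
    }
    u <- matrix(0, n, d)
    u[, tr$perm] <- v
  }
  u
}

adam_state <- function(flow) {
  lapply(flow$transforms, function(tr) {
    lapply(tr[c("W1", "A1", "b1", "W2", "A2", "b2")], function(w) {
      list(m = w * 0, v = w * 0)
    })
  })
}

adam_update <- function(flow, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (k in seq_along(flow$transforms)) {
    for (nm in c("W1", "A1", "b1", "W2", "A2", "b2")) {
      gk <- grads[[k]][[nm]]
      st <- state[[k]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * gk
      st$v <- beta2 * st$v + (1 - beta2) * gk^2
      state[[k]][[nm]] <- st
      flow$transforms[[k]][[nm]] <- flow$transforms[[k]][[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(flow = flow, state = state)
}

# train the flow by maximum likelihood with early stopping
maf_fit <- function(theta, ctx, n_transforms = 5, hidden = 50,
                    batch_size = 200, lr = 1e-3, max_epochs = 400,
                    patience = 25, val_frac = 0.1, seed = 1,
                    verbose = FALSE) {
  n <- nrow(theta)
  set.seed(seed)
  flow <- maf_init(ncol(theta), ncol(ctx), n_transforms, hidden,
                   seed = seed + 1L)
  idx <- sample.int(n)
  n_val <- max(1L, round(val_frac * n))
  val <- idx[seq_len(n_val)]
  trn <- idx[-seq_len(n_val)]
  state <- adam_state(flow)
  best <- list(flow = flow, val = Inf, epoch = 0L)
  t_adam <- 0
  history <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(trn)
    nb <- ceiling(length(ord) / batch_size)
    for (b in seq_len(nb)) {
      ix <- ord[((b - 1) * batch_size + 1):min(b * batch_size, length(ord))]
      bk <- maf_backward(flow, theta[ix, , drop = FALSE],
                         ctx[ix, , drop = FALSE])
      t_adam <- t_adam + 1
      up <- adam_update(flow, bk$grads, state, lr, t_adam)
      flow <- up$flow
      state <- up$state
    }
    vl <- -mean(maf_log_prob(flow, theta[val, , drop = FALSE],
                             ctx[val, , drop = FALSE]))
    history <- c(history, vl)
    if (is.finite(vl) && vl < best$val - 1e-5) {
      best <- list(flow = flow, val = vl, epoch = epoch)
    }
    if (verbose && epoch %% 20 == 0) {
      message(sprintf("epoch %d: val NLL %.4f (best %.4f @ %d)",
                      epoch, vl, best$val, best$epoch))
    }
    if (epoch - best$epoch >= patience) break
  }
  list(flow = best$flow, val_nll = best$val, epochs = length(history),
       best_epoch = best$epoch, history = history)
}
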