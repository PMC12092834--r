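#' Assemble a training set for the neural density estimator
#'
#' Pairs parameter vectors with the MEA features of their simulations
#' and fits the feature standardizer (per-feature mean/sd, training set
#' only). Silent or degenerate simulations are retained with their
#' convention-imputed features so the prior predictive is not truncated.
#'
#' @param params Tibble of parameter vectors (rows aligned with
#'   `features`/`rasters`), e.g. from [sample_prior()].
#' @param features Tibble of feature rows, or `NULL` to compute them
#'   from `rasters` via [compute_features_batch()].
#' @param rasters Optional list of rasters/simulations, used when
#'   `features` is `NULL`.
#' @param ranges Prior ranges for the columns of `params` (subset of
#'   [prior_ranges()] for reduced models).
#' @param provenance Free-form list stored with the set (seeds,
#'   duration, simulator settings).
#' @return An object of class `mea_training_set`.
#' @export
build_training_set <- function(params, features = NULL, rasters = NULL,
                               ranges = NULL,
                               provenance = list()) {
  if (is.null(features)) {
    if (is.null(rasters)) stop("supply `features` or `rasters`")
    features <- compute_features_batch(rasters)
  }
  if (nrow(params) != nrow(features)) {
    stop("`params` and `features` must have the same number of rows")
  }
  if (is.null(ranges)) {
    ranges <- prior_ranges()[prior_ranges()$parameter %in% names(params), ]
  }
  theta <- as.matrix(params[, ranges$parameter, drop = FALSE])
  x <- as.matrix(features)
  if (any(!is.finite(theta)) || any(!is.finite(x))) {
    stop("training set contains non-finite entries")
  }
  std <- list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
  structure(list(theta = theta, x = x, ranges = ranges,
                 standardizer = std, feature_names = colnames(x),
                 provenance = provenance),
            class = "mea_training_set")
}

#' @export
print.mea_training_set <- function(x, ...) {
  cat(sprintf("<mea_training_set> %d simulations, %d parameters, %d features\n",
              nrow(x$theta), ncol(x$theta), ncol(x$x)))
  invisible(x)
}

# map parameters between the prior box and the flow's unbounded space
box_to_unbounded <- function(theta, ranges, eps = 1e-6) {
  lo <- matrix(ranges$lower, nrow(theta), nrow(ranges), byrow = TRUE)
  hi <- matrix(ranges$upper, nrow(theta), nrow(ranges), byrow = TRUE)
  p <- pmin(pmax((theta - lo) / (hi - lo), eps), 1 - eps)
  stats::qlogis(p)
}

unbounded_to_box <- function(u, ranges) {
  lo <- matrix(ranges$lower, nrow(u), nrow(ranges), byrow = TRUE)
  hi <- matrix(ranges$upper, nrow(u), nrow(ranges), byrow = TRUE)
  lo + (hi - lo) * stats::plogis(u)
}

# log |d theta_tilde / d theta| summed over parameters
box_log_jacobian <- function(theta, ranges, eps = 1e-6) {
  lo <- matrix(ranges$lower, nrow(theta), nrow(ranges), byrow = TRUE)
  hi <- matrix(ranges$upper, nrow(theta), nrow(ranges), byrow = TRUE)
  p <- pmin(pmax((theta - lo) / (hi - lo), eps), 1 - eps)
  -rowSums(log((hi - lo) * p * (1 - p)))
}

standardize_features <- function(x, std) {
  sweep(sweep(x, 2, std$mean), 2, std$sd, "/")
}

#' Train the neural density estimator
#'
#' Fits the conditional masked autoregressive flow q(theta | features)
#' by maximum likelihood on the training set (amortized single-round
#' neural posterior estimation: with a uniform prior the conditional
#' density trained on prior simulations is the posterior). Parameters
#' are logit-mapped to the prior box, so posterior samples always lie
#' inside it; features are z-scored by the training standardizer.
#'
#' @param ts A `mea_training_set`.
#' @param seed Integer seed (training is reproducible given the seed).
#' @param n_transforms,hidden Flow architecture (MADE blocks, hidden
#'   units per block).
#' @param max_epochs,patience,batch_size,lr,val_frac Optimizer settings;
#'   early stopping monitors a validation split.
#' @param min_n Minimum admissible training-set size.
#' @return An object of class `mea_posterior_model`.
#' @export
train_nde <- function(ts, seed = 1, n_transforms = 5, hidden = 50,
                      max_epochs = 300, patience = 25, batch_size = 200,
                      lr = 1e-3, val_frac = 0.1, min_n = 500) {
  stopifnot(inherits(ts, "mea_training_set"))
  if (nrow(ts$theta) < min_n) {
    stop(sprintf("training set has %d rows; at least %d required",
                 nrow(ts$theta), min_n))
  }
  const <- which(ts$standardizer$sd == 0)
  if (length(const)) {
    stop("degenerate (constant) feature column(s): ",
         paste(ts$feature_names[const], collapse = ", "))
  }
  theta_u <- box_to_unbounded(ts$theta, ts$ranges)
  x_std <- standardize_features(ts$x, ts$standardizer)
  fit <- maf_fit(theta_u, x_std, n_transforms = n_transforms,
                 hidden = hidden, batch_size = batch_size, lr = lr,
                 max_epochs = max_epochs, patience = patience,
                 val_frac = val_frac, seed = seed)
  structure(list(flow = fit$flow, ranges = ts$ranges,
                 standardizer = ts$standardizer,
                 feature_names = ts$feature_names,
                 provenance = ts$provenance,
                 training = list(n = nrow(ts$theta), seed = seed,
                                 val_nll = fit$val_nll,
                                 epochs = fit$epochs,
                                 best_epoch = fit$best_epoch)),
            class = "mea_posterior_model")
}

#' @export
print.mea_posterior_model <- function(x, ...) {
  cat(sprintf(
    "<mea_posterior_model> %d parameters | %d features | trained on %d sims (val NLL %.3f)\n",
    nrow(x$ranges), length(x$feature_names), x$training$n,
    x$training$val_nll))
  invisible(x)
}

#' Condition the trained estimator on an observation
#'
#' Evaluating the amortized model on a new feature vector requires no
#' retraining; the returned handle supports [posterior_sample()],
#' [posterior_log_prob()], [posterior_mode()] and the posterior-analysis
#' functions. Features further than 10 training standard deviations
#' from the training mean trigger a misspecification warning.
#'
#' @param observation One-row tibble (or named vector) of MEA features
#'   matching the training features.
#' @param model A `mea_posterior_model`.
#' @param id Optional observation identifier.
#' @param batch Optional MEA batch label (used by the comparison layer's
#'   same-batch guard).
#' @return An object of class `mea_posterior`.
#' @export
posterior_for <- function(observation, model, id = NULL, batch = NULL) {
  stopifnot(inherits(model, "mea_posterior_model"))
  if (is.data.frame(observation)) {
    stopifnot(nrow(observation) == 1)
    observation <- unlist(observation[1, ])
  }
  miss <- setdiff(model$feature_names, names(observation))
  if (length(miss)) {
    stop("observation lacks feature(s): ", paste(miss, collapse = ", "))
  }
  xv <- as.numeric(observation[model$feature_names])
  if (any(!is.finite(xv))) stop("observation features must be finite")
  z <- (xv - model$standardizer$mean) / model$standardizer$sd
  far <- abs(z) > 10
  if (any(far)) {
    warning("feature(s) more than 10 training sd from the training mean ",
            "(possible model misspecification): ",
            paste(model$feature_names[far], collapse = ", "))
  }
  structure(list(model = model, x_std = as.numeric(z),
                 observation = xv, id = id, batch = batch),
            class = "mea_posterior")
}

#' @export
print.mea_posterior <- function(x, ...) {
  cat(sprintf("<mea_posterior> over %d parameters%s\n",
              nrow(x$model$ranges),
              if (is.null(x$id)) "" else paste0(" (obs ", x$id, ")")))
  invisible(x)
}

#' Draw samples from a conditioned posterior
#'
#' @param posterior A `mea_posterior` handle.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Tibble of `n` rows, one column per parameter; all values lie
#'   inside the prior box.
#' @export
posterior_sample <- function(posterior, n = 1000, seed = NULL) {
  stopifnot(inherits(posterior, "mea_posterior"))
  if (!is.null(seed)) set.seed(seed)
  u <- maf_sample(posterior$model$flow, n, posterior$x_std)
  th <- unbounded_to_box(u, posterior$model$ranges)
  colnames(th) <- posterior$model$ranges$parameter
  tibble::as_tibble(th)
}

#' Posterior log-density at given parameter values
#'
#' @param posterior A `mea_posterior`.
#' @param theta Tibble/matrix of parameter rows (natural units).
#' @return Numeric vector of log-densities (natural-parameter scale).
#' @export
posterior_log_prob <- function(posterior, theta) {
  stopifnot(inherits(posterior, "mea_posterior"))
  ranges <- posterior$model$ranges
  if (is.data.frame(theta)) {
    theta <- as.matrix(theta[, ranges$parameter, drop = FALSE])
  }
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  ctx <- matrix(posterior$x_std, nrow(theta), length(posterior$x_std),
                byrow = TRUE)
  u <- box_to_unbounded(theta, ranges)
  maf_log_prob(posterior$model$flow, u, ctx) +
    box_log_jacobian(theta, ranges)
}

#' Joint posterior mode
#'
#' Best-of-N posterior samples followed by local refinement of the
#' log-density (BFGS in the unbounded parameterization, so the result
#' stays inside the prior box).
#'
#' @param posterior A `mea_posterior`.
#' @param n_samples Number of candidate samples (default 10000).
#' @param seed Integer seed.
#' @return One-row tibble of parameter values.
#' @export
posterior_mode <- function(posterior, n_samples = 10000, seed = 1) {
  ranges <- posterior$model$ranges
  s <- as.matrix(posterior_sample(posterior, n_samples, seed = seed))
  lp <- posterior_log_prob(posterior, s)
  u0 <- box_to_unbounded(s[which.max(lp), , drop = FALSE], ranges)
  ctx <- matrix(posterior$x_std, 1, length(posterior$x_std))
  obj <- function(u) {
    th <- unbounded_to_box(matrix(u, nrow = 1), ranges)
    -(maf_log_prob(posterior$model$flow, matrix(u, nrow = 1), ctx) +
        box_log_jacobian(th, ranges))
  }
  opt <- stats::optim(as.numeric(u0), obj, method = "BFGS",
                      control = list(maxit = 200))
  th <- unbounded_to_box(matrix(opt$par, nrow = 1), ranges)
  colnames(th) <- ranges$parameter
  tibble::as_tibble(th)
}

#' Conditional posterior over one or two parameters
#'
#' Clamps all other parameters at given values and evaluates the joint
#' log-density on a grid over the free parameters' prior ranges,
#' renormalizing on the grid. Sampling uses the discrete grid
#' probabilities (inverse-CDF).
#'
#' @param posterior A `mea_posterior`.
#' @param fixed Named numeric vector of clamped parameter values (inside
#'   the prior box); must cover all parameters except `free`.
#' @param free Character vector of 1 or 2 free parameter names.
#' @param n_grid Grid points per axis (default 100).
#' @return List of class `mea_conditional`: `free`, `grid` (list of
#'   axes), `density` (vector or matrix, normalized to sum x cell = 1),
#'   `log_density`.
#' @export
conditional_posterior <- function(posterior, fixed, free, n_grid = 100) {
  ranges <- posterior$model$ranges
  free <- as.character(free)
  if (!length(free) || length(free) > 2) {
    stop("`free` must name 1 or 2 parameters")
  }
  if (!all(free %in% ranges$parameter)) stop("unknown free parameter")
  clamp <- setdiff(ranges$parameter, free)
  if (!all(clamp %in% names(fixed))) {
    stop("`fixed` must provide values for all non-free parameters")
  }
  ri <- match(free, ranges$parameter)
  axes <- lapply(ri, function(i) {
    seq(ranges$lower[i], ranges$upper[i], length.out = n_grid + 2)[
      2:(n_grid + 1)]
  })
  grid <- if (length(free) == 1) {
    matrix(axes[[1]], ncol = 1)
  } else {
    as.matrix(expand.grid(axes[[1]], axes[[2]]))
  }
  theta <- matrix(NA_real_, nrow(grid), nrow(ranges))
  colnames(theta) <- ranges$parameter
  for (nm in clamp) theta[, nm] <- fixed[[nm]]
  for (j in seq_along(free)) theta[, free[j]] <- grid[, j]
  lp <- posterior_log_prob(posterior, theta)
  lp <- lp - max(lp)
  w <- exp(lp)
  dens <- w / sum(w)
  if (length(free) == 2) {
    dens <- matrix(dens, n_grid, n_grid)  # rows: axis 1, cols: axis 2
    lp <- matrix(lp, n_grid, n_grid)
  }
  structure(list(free = free, grid = axes, density = dens,
                 log_density = lp),
            class = "mea_conditional")
}

#' Sample from a gridded conditional posterior
#'
#' @param cond A `mea_conditional`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param jitter Add uniform within-cell jitter (default `TRUE`).
#' @return Tibble with one column per free parameter.
#' @export
conditional_sample <- function(cond, n, seed = NULL, jitter = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  p <- as.numeric(cond$density)
  ix <- sample.int(length(p), n, replace = TRUE, prob = p)
  if (length(cond$free) == 1) {
    g <- cond$grid[[1]]
    dx <- g[2] - g[1]
    v <- g[ix] + if (jitter) stats::runif(n, -dx / 2, dx / 2) else 0
    out <- tibble::tibble(v)
    names(out) <- cond$free
  } else {
    n1 <- length(cond$grid[[1]])
    i1 <- (ix - 1) %% n1 + 1
    i2 <- (ix - 1) %/% n1 + 1
    d1 <- cond$grid[[1]][2] - cond$grid[[1]][1]
    d2 <- cond$grid[[2]][2] - cond$grid[[2]][1]
    out <- tibble::tibble(
      a = cond$grid[[1]][i1] +
        if (jitter) stats::runif(n, -d1 / 2, d1 / 2) else 0,
      b = cond$grid[[2]][i2] +
        if (jitter) stats::runif(n, -d2 / 2, d2 / 2) else 0
    )
    names(out) <- cond$free
  }
  out
}

#' Conditional correlation structure of the posterior
#'
#' For every parameter pair, draws `n_conditionals` conditioning vectors
#' from the posterior, forms the 2-D conditional with the pair free,
#' samples `n_points` points from each conditional, and records the
#' Pearson correlation. Reports the mean correlation matrix and, per
#' pair, the one-sample t-test of the correlations against zero.
#'
#' @param posterior A `mea_posterior`.
#' @param n_conditionals Conditioning draws per pair (default 50).
#' @param n_points Points sampled per conditional (default 50).
#' @param n_grid Grid points per axis for each 2-D conditional.
#' @param seed Integer seed.
#' @return List of class `mea_cond_corr`: `mean_r` (symmetric matrix,
#'   unit diagonal), `pairs` (tibble: param_a, param_b, mean_r, p_value,
#'   shapiro_p), `r_values` (list-column source tibble).
#' @export
conditional_corr_matrix <- function(posterior, n_conditionals = 50,
                                    n_points = 50, n_grid = 50,
                                    seed = 1) {
  ranges <- posterior$model$ranges
  d <- nrow(ranges)
  set.seed(seed)
  cond_draws <- posterior_sample(posterior, n_conditionals)
  mean_r <- diag(1, d)
  dimnames(mean_r) <- list(ranges$parameter, ranges$parameter)
  rows <- list()
  for (i in seq_len(d - 1)) {
    for (j in seq((i + 1), d)) {
      free <- ranges$parameter[c(i, j)]
      rs <- numeric(n_conditionals)
      for (k in seq_len(n_conditionals)) {
        fx <- unlist(cond_draws[k, ])
        cond <- conditional_posterior(posterior, fx, free,
                                      n_grid = n_grid)
        pts <- conditional_sample(cond, n_points)
        rs[k] <- stats::cor(pts[[1]], pts[[2]])
      }
      rs <- rs[is.finite(rs)]
      tt <- corr_vs_zero(rs)
      mean_r[i, j] <- mean_r[j, i] <- mean(rs)
      rows[[length(rows) + 1]] <- tibble::tibble(
        param_a = free[1], param_b = free[2], mean_r = mean(rs),
        p_value = tt$p_value, shapiro_p = tt$shapiro_p,
        r_values = list(rs))
    }
  }
  structure(list(mean_r = mean_r, pairs = dplyr::bind_rows(rows)),
            class = "mea_cond_corr")
}

#' Posterior sensitivity scores (active-subspace style)
#'
#' Estimates the matrix `E[g g^T]` of outer products of the posterior
#' log-density gradient (finite differences, parameters scaled by their
#' prior range) over posterior samples, eigen-decomposes it, and scores
#' each parameter by its weighted loading on the eigenvectors,
#' normalized to `[0, 1]`. Directions along which the log-density
#' changes fastest (narrow, informed parameters) score high; flat
#' parameters score near 0.
#'
#' @param posterior A `mea_posterior`.
#' @param n_samples Posterior samples to average over.
#' @param seed Integer seed.
#' @param rel_step Finite-difference step as a fraction of prior range.
#' @return Tibble: `parameter`, `score`.
#' @export
sensitivity_scores <- function(posterior, n_samples = 200, seed = 1,
                               rel_step = 1e-3) {
  ranges <- posterior$model$ranges
  d <- nrow(ranges)
  s <- as.matrix(posterior_sample(posterior, n_samples, seed = seed))
  span <- ranges$upper - ranges$lower
  G <- matrix(0, n_samples, d)
  for (i in seq_len(d)) {
    h <- rel_step * span[i]
    up <- s; up[, i] <- pmin(up[, i] + h, ranges$upper[i] - 1e-9 * span[i])
    dn <- s; dn[, i] <- pmax(dn[, i] - h, ranges$lower[i] + 1e-9 * span[i])
    G[, i] <- (posterior_log_prob(posterior, up) -
                 posterior_log_prob(posterior, dn)) /
      (up[, i] - dn[, i]) * span[i]   # gradient in range-scaled units
  }
  M <- crossprod(G) / n_samples
  eg <- eigen(M, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  score <- sqrt((eg$vectors^2) %*% lam)[, 1]
  score <- as.numeric(score / max(score))
  tibble::tibble(parameter = ranges$parameter, score = score)
}

#' Sensitivity of a simulated MEA feature to the model parameters
#'
#' Central finite differences of one feature of the simulated activity
#' with respect to each free parameter (step expressed as a fraction of
#' the prior range), averaged over simulation seeds, with Monte Carlo
#' standard errors.
#'
#' @param params0 Baseline parameter vector (inside the prior box).
#' @param feature Feature name (column of [compute_features()]).
#' @param step_frac Step size as a fraction of each prior range.
#' @param n_seeds Seeds to average over.
#' @param ranges Prior ranges (subset for reduced models).
#' @param fixed,duration,n_neurons Simulator settings.
#' @param seed Base seed.
#' @return Tibble: `parameter`, `sensitivity` (feature units per full
#'   prior range), `mc_se`, `n_seeds`.
#' @export
feature_sensitivity <- function(params0, feature, step_frac = 0.05,
                                n_seeds = 3, ranges = prior_ranges(),
                                fixed = fixed_params(), duration = 30,
                                n_neurons = 100, seed = 1) {
  v0 <- validate_params(params0, ranges)
  span <- ranges$upper - ranges$lower
  rows <- list()
  for (i in seq_len(nrow(ranges))) {
    h <- step_frac * span[i]
    up <- v0; up[i] <- min(v0[i] + h, ranges$upper[i])
    dn <- v0; dn[i] <- max(v0[i] - h, ranges$lower[i])
    diffs <- vapply(seq_len(n_seeds), function(s) {
      fu <- compute_features(simulate_network(
        as.list(up), fixed, duration, seed = seed + s,
        n_neurons = n_neurons))[[feature]]
      fd <- compute_features(simulate_network(
        as.list(dn), fixed, duration, seed = seed + s,
        n_neurons = n_neurons))[[feature]]
      (fu - fd) / (up[i] - dn[i]) * span[i]
    }, numeric(1))
    rows[[i]] <- tibble::tibble(
      parameter = ranges$parameter[i],
      sensitivity = mean(diffs),
      mc_se = if (n_seeds > 1) stats::sd(diffs) / sqrt(n_seeds) else NA_real_,
      n_seeds = n_seeds)
  }
  dplyr::bind_rows(rows)
}

#' Posterior-predictive check for a ground-truth parameter vector
#'
#' Simulates the network at `theta_star`, computes its features,
#' conditions the posterior on them, and checks — for every univariate
#' and pairwise marginal, by kernel density estimation on posterior
#' samples — that the density at the ground truth is at least half the
#' marginal's maximum density.
#'
#' @param model A `mea_posterior_model`.
#' @param theta_star Ground-truth parameter vector (inside the prior).
#' @param seed Integer seed for the check simulation and sampling.
#' @param features Optional precomputed feature row for `theta_star`
#'   (skips the simulation).
#' @param fixed,duration,n_neurons Simulator settings used when
#'   `features` is `NULL`.
#' @param n_samples Posterior samples for the KDEs (default 1000).
#' @param level Density-ratio criterion (default 0.5).
#' @return List of class `mea_ppc`: `pass` (all marginals pass),
#'   `univariate` (tibble: parameter, ratio, pass), `pairwise` (tibble:
#'   param_a, param_b, ratio, pass), `posterior` (the handle).
#' @export
ppc_check <- function(model, theta_star, seed = 1, features = NULL,
                      fixed = fixed_params(), duration = 30,
                      n_neurons = 100, n_samples = 1000, level = 0.5) {
  ranges <- model$ranges
  v <- validate_params(theta_star, ranges, check_box = TRUE)
  if (is.null(features)) {
    # reduced models clamp the remaining parameters at prior midpoints
    sim <- simulate_network(complete_params(as.list(v)), fixed, duration,
                            seed = seed, n_neurons = n_neurons)
    features <- compute_features(sim$raster)
    features <- features[, model$feature_names, drop = FALSE]
  }
  post <- posterior_for(features, model)
  s <- posterior_sample(post, n_samples, seed = seed + 1L)
  d <- nrow(ranges)

  # reflect samples at the prior boundaries before kernel density
  # estimation: the marginals live on a box, and an uncorrected KDE
  # underestimates the density near the edges by up to a factor 2.
  # density ratios are unaffected by the constant renormalization.
  reflect <- function(x, lo, hi) c(x, 2 * lo - x, 2 * hi - x)

  uni <- purrr::map_dfr(seq_len(d), function(i) {
    xs <- s[[i]]
    bw <- stats::bw.nrd(xs) + 1e-12
    xr <- reflect(xs, ranges$lower[i], ranges$upper[i])
    de <- stats::density(xr, bw = bw, from = ranges$lower[i],
                         to = ranges$upper[i])
    at <- stats::approx(de$x, de$y, xout = v[i], rule = 2)$y
    tibble::tibble(parameter = ranges$parameter[i],
                   ratio = at / max(de$y))
  })
  uni$pass <- uni$ratio >= level

  pairs <- list()
  for (i in seq_len(d - 1)) {
    for (j in seq((i + 1), d)) {
      hx <- MASS::bandwidth.nrd(s[[i]])
      hy <- MASS::bandwidth.nrd(s[[j]])
      xr <- reflect(s[[i]], ranges$lower[i], ranges$upper[i])
      # all 9 image combinations so both axes are reflected
      xi <- rep(xr, times = 3)
      yj <- c(rep(s[[j]], 3), rep(2 * ranges$lower[j] - s[[j]], 3),
              rep(2 * ranges$upper[j] - s[[j]], 3))
      kd <- MASS::kde2d(xi, yj, h = c(hx, hy) + 1e-12, n = 50,
                        lims = c(ranges$lower[i], ranges$upper[i],
                                 ranges$lower[j], ranges$upper[j]))
      ii <- findInterval(v[i], kd$x, all.inside = TRUE)
      jj <- findInterval(v[j], kd$y, all.inside = TRUE)
      at <- kd$z[ii, jj]
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        param_a = ranges$parameter[i], param_b = ranges$parameter[j],
        ratio = at / max(kd$z))
    }
  }
  pairwise <- if (length(pairs)) {
    dplyr::bind_rows(pairs)
  } else {
    tibble::tibble(param_a = character(0), param_b = character(0),
                   ratio = numeric(0))
  }
  pairwise$pass <- pairwise$ratio >= level
  structure(list(pass = all(uni$pass) && all(pairwise$pass),
                 univariate = uni, pairwise = pairwise,
                 posterior = post, theta_star = v),
            class = "mea_ppc")
}

#' @export
print.mea_ppc <- function(x, ...) {
  cat(sprintf("<mea_ppc> %s (%d/%d univariate, %d/%d pairwise marginals pass)\n",
              if (x$pass) "PASS" else "FAIL",
              sum(x$univariate$pass), nrow(x$univariate),
              sum(x$pairwise$pass), nrow(x$pairwise)))
  invisible(x)
}

#' Parameter recovery error
#'
#' For each parameter, the mean absolute deviation of the posterior
#' marginal samples from the ground truth, normalized by the prior
#' range: 0 for a point mass at the truth, 0.25 for a prior-wide
#' uniform marginal with the truth at the range midpoint, 0.5 with the
#' truth at an edge.
#'
#' @param posterior A `mea_posterior` handle, or a tibble/matrix of
#'   posterior samples.
#' @param theta_star Ground-truth parameter vector.
#' @param ranges Prior ranges (taken from the handle when available).
#' @param n_samples,seed Sampling settings when a handle is given.
#' @return Tibble: `parameter`, `pre`.
#' @export
parameter_recovery_error <- function(posterior, theta_star,
                                     ranges = NULL, n_samples = 1000,
                                     seed = 1) {
  if (inherits(posterior, "mea_posterior")) {
    ranges <- posterior$model$ranges
    s <- posterior_sample(posterior, n_samples, seed = seed)
  } else {
    if (is.null(ranges)) stop("`ranges` required when passing samples")
    s <- tibble::as_tibble(posterior)
  }
  v <- validate_params(theta_star, ranges)
  pre <- vapply(seq_len(nrow(ranges)), function(i) {
    mean(abs(s[[ranges$parameter[i]]] - v[i])) /
      (ranges$upper[i] - ranges$lower[i])
  }, numeric(1))
  tibble::tibble(parameter = ranges$parameter, pre = pre)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summarize a posterior's marginals
#'
#' @param x A `mea_posterior`.
#' @param n_samples,seed Sampling settings.
#' @param ... Unused.
#' @return Tibble: `parameter`, `mean`, `median`, `sd`, `q05`, `q95`.
#' @export
tidy.mea_posterior <- function(x, n_samples = 1000, seed = 1, ...) {
  s <- posterior_sample(x, n_samples, seed = seed)
  purrr::map_dfr(names(s), function(nm) {
    tibble::tibble(parameter = nm, mean = mean(s[[nm]]),
                   median = stats::median(s[[nm]]), sd = stats::sd(s[[nm]]),
                   q05 = stats::quantile(s[[nm]], 0.05, names = FALSE),
                   q95 = stats::quantile(s[[nm]], 0.95, names = FALSE))
  })
}

#' One-line training summary of a posterior model
#'
#' @param x A `mea_posterior_model`.
#' @param ... Unused.
#' @return One-row tibble: `n_train`, `n_parameters`, `n_features`,
#'   `val_nll`, `epochs`.
#' @export
glance.mea_posterior_model <- function(x, ...) {
  tibble::tibble(n_train = x$training$n, n_parameters = nrow(x$ranges),
                 n_features = length(x$feature_names),
                 val_nll = x$training$val_nll, epochs = x$training$epochs)
}
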