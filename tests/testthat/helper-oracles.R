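# Independent oracles and shared fixtures for the test suite.
#
# Expensive fixtures (the reduced-model training run, trained density
# estimators) are built once per session and memoised here so every test
# file can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# brute-force ISI-distance: explicit loops on a dense grid, written
# independently of the package implementation
oracle_isi_distance <- function(a, b, dt = 5e-4) {
  lo <- max(a[1], b[1])
  hi <- min(a[length(a)], b[length(b)])
  tt <- seq(lo, hi - dt, by = dt)
  vals <- vapply(tt, function(t) {
    ia <- a[which(a > t)[1]] - rev(a[a <= t])[1]
    ib <- b[which(b > t)[1]] - rev(b[b <= t])[1]
    if (ia <= ib) abs(ia / ib - 1) else abs(ib / ia - 1)
  }, numeric(1))
  mean(vals)
}

# analytic posterior for the toy simulator x = theta + eps,
# theta ~ U(0,1), eps ~ N(0, noise^2): Gaussian truncated to [0,1]
toy_true_posterior <- function(x_o, noise = 0.1) {
  z0 <- (0 - x_o) / noise
  z1 <- (1 - x_o) / noise
  zc <- pnorm(z1) - pnorm(z0)
  mean <- x_o + noise * (dnorm(z0) - dnorm(z1)) / zc
  var <- noise^2 * (1 + (z0 * dnorm(z0) - z1 * dnorm(z1)) / zc -
                      ((dnorm(z0) - dnorm(z1)) / zc)^2)
  list(mean = mean, sd = sqrt(var))
}

# toy model trained once: theta ~ U(0,1), x = theta + N(0, 0.1^2), n = 5000
toy_model <- function() {
  cached("toy_model", function() {
    ts <- make_fixture("toy-simulator", n = 5000, noise = 0.1, seed = 11)
    train_nde(ts, seed = 3, n_transforms = 3, hidden = 24,
              max_epochs = 150, patience = 15)
  })
}

# independent 2-D toy model: x = theta + noise in both coordinates
toy2d_model <- function() {
  cached("toy2d_model", function() {
    ts <- make_fixture("toy-simulator", n = 5000, d = 2, noise = 0.1,
                       seed = 19)
    train_nde(ts, seed = 4, n_transforms = 3, hidden = 24,
              max_epochs = 150, patience = 15)
  })
}

# reduced-model study: 600 prior simulations of the 5-parameter network
# (30 neurons, 30 s, dt 0.1 ms) and the density estimator trained on them
reduced_study <- function() {
  cached("reduced_study", function() {
    ts <- make_fixture("reduced-model", n = 600, n_neurons = 30,
                       duration = 30, dt = 0.1, seed = 101)
    model <- train_nde(ts, seed = 7, n_transforms = 5, hidden = 50,
                       max_epochs = 200, patience = 20,
                       batch_size = 100, min_n = 400)
    list(ts = ts, model = model)
  })
}

# held-out ground truths for posterior-predictive checks on the reduced
# model, with their check results (simulated once, reused by tests)
reduced_ppc_runs <- function() {
  cached("reduced_ppc", function() {
    study <- reduced_study()
    truths <- sample_prior(10, seed = 202, ranges = reduced_ranges())
    lapply(seq_len(10), function(i) {
      ppc_check(study$model, truths[i, ], seed = 300 + i,
                fixed = fixed_params(dt = 0.1), duration = 30,
                n_neurons = 30)
    })
  })
}

# flow trained on an unconditional correlated 2-D Gaussian (constant
# context), used for conditional-narrowing and correlation tests
gaussian_posterior <- function(rho = 0.9, sd = 0.08, n = 4000,
                               seed = 21) {
  key <- sprintf("gauss_%g_%g", rho, sd)
  cached(key, function() {
    set.seed(seed)
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    theta <- tibble::tibble(theta1 = 0.5 + sd * z1,
                            theta2 = 0.5 + sd * z2)
    stopifnot(all(theta >= 0 & theta <= 1))
    ranges <- tibble::tibble(parameter = c("theta1", "theta2"),
                             lower = 0, upper = 1, unit = "-",
                             description = "gaussian toy")
    feats <- tibble::tibble(x1 = rnorm(n, 0, 1))  # uninformative context
    ts <- build_training_set(theta, features = feats, ranges = ranges)
    model <- train_nde(ts, seed = 5, n_transforms = 3, hidden = 24,
                       max_epochs = 150, patience = 15)
    posterior_for(tibble::tibble(x1 = 0), model)
  })
}

# crafted two-burst raster of the hand-evaluated kind: all electrodes
# at 100 Hz during [1.0, 1.3] and [5.0, 5.3] s, sparse background
two_burst_raster <- function(participating2 = 0:11, background = TRUE,
                             seed = 5) {
  spikes <- list()
  for (e in 0:11) {
    st <- seq(1.0, 1.3, by = 0.01) + (e %% 5) * 1e-3
    if (e %in% participating2) {
      st <- c(st, seq(5.0, 5.3, by = 0.01) + (e %% 5) * 1e-3)
    }
    spikes[[e + 1]] <- tibble::tibble(electrode = e, time_s = st)
  }
  if (background) {
    set.seed(seed)
    spikes <- c(spikes, list(tibble::tibble(
      electrode = rep(0:11, each = 6),
      time_s = runif(72, 0, 60))))  # 0.1 Hz background
  }
  as_spike_raster(dplyr::bind_rows(spikes),
                  n_electrodes = 12, duration = 60)
}
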