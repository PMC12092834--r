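#' Deterministic fixtures for every stage of the pipeline
#'
#' Generates the crafted inputs used to exercise each stage without any
#' recording: rasters with known burst structure (`"crafted-raster"`),
#' synthetic extracellular traces for the detection path
#' (`"synthetic-trace"`), the linear-Gaussian toy simulator with an
#' analytically known posterior (`"toy-simulator"`), and a reduced
#' 5-parameter network training set for full-loop recovery experiments
#' (`"reduced-model"`). Everything is deterministic given `seed`.
#'
#' @param kind One of `"crafted-raster"`, `"synthetic-trace"`,
#'   `"toy-simulator"`, `"reduced-model"`.
#' @param ... Kind-specific settings, see Details.
#' @param seed Integer seed.
#'
#' @details
#' `"crafted-raster"`: `n_bursts`, `period_s`, `burst_len_s`,
#' `rate_hz` (per electrode, in burst), `background_hz`,
#' `n_electrodes`, `participating` (electrode ids spiking in bursts),
#' `duration`. Spikes are regular within bursts with small
#' per-electrode phase offsets; background spikes are Poisson.
#'
#' `"synthetic-trace"`: a crafted raster (same settings) rendered to a
#' raw trace via [synth_extracellular()] with `noise_sd`, `amplitude`,
#' `fs`.
#'
#' `"toy-simulator"`: `n`, `d` (default 1), `noise` (default 0.1);
#' `theta ~ U(0,1)^d`, `x = theta + Normal(0, noise^2)`; returns a
#' `mea_training_set` whose true posterior given `x_o` is a Gaussian
#' truncated to the unit box.
#'
#' `"reduced-model"`: `n`, plus `n_neurons` (30), `duration` (30 s),
#' `dt` (0.1 ms): samples a sub-prior over `noise_sd`, `g_AMPA`,
#' `conn_p`, `tau_D`, `U_std` with the other parameters clamped at
#' their prior midpoints, simulates each draw and computes features;
#' returns a `mea_training_set`.
#'
#' @return See Details; rasters are `mea_raster`, traces `mea_trace`,
#'   the others `mea_training_set`.
#' @export
make_fixture <- function(kind, ..., seed = 1) {
  opts <- list(...)
  switch(
    kind,
    "crafted-raster" = do.call(crafted_raster, c(opts, list(seed = seed))),
    "synthetic-trace" = {
      raster_args <- opts[setdiff(names(opts),
                                  c("noise_sd", "amplitude", "fs"))]
      raster <- do.call(crafted_raster, c(raster_args, list(seed = seed)))
      synth_extracellular(
        raster,
        noise_sd = opts$noise_sd %||% 1,
        amplitude = opts$amplitude %||% 10,
        fs = opts$fs %||% 10000, seed = seed + 1L)
    },
    "toy-simulator" = do.call(toy_training_set,
                              c(opts, list(seed = seed))),
    "reduced-model" = do.call(reduced_training_set,
                              c(opts, list(seed = seed))),
    stop("unknown fixture kind: ", kind)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

crafted_raster <- function(n_bursts = 3, period_s = 10, burst_len_s = 0.3,
                           rate_hz = 100, background_hz = 0.2,
                           n_electrodes = 12,
                           participating = NULL, duration = NULL,
                           first_burst_s = 1, seed = 1) {
  set.seed(seed)
  if (is.null(duration)) duration <- first_burst_s + n_bursts * period_s
  if (is.null(participating)) participating <- seq_len(n_electrodes) - 1L
  spikes <- list()
  for (e in seq_len(n_electrodes) - 1L) {
    st <- numeric(0)
    if (e %in% participating && n_bursts > 0) {
      phase <- (e %% 5) * 1e-3   # deterministic per-electrode offset
      for (b in seq_len(n_bursts)) {
        t0 <- first_burst_s + (b - 1) * period_s
        st <- c(st, seq(t0, t0 + burst_len_s, by = 1 / rate_hz) + phase)
      }
    }
    if (background_hz > 0) {
      n_bg <- stats::rpois(1, background_hz * duration)
      st <- c(st, stats::runif(n_bg, 0, duration))
    }
    st <- sort(st[st >= 0 & st <= duration])
    spikes[[e + 1L]] <- tibble::tibble(electrode = e, time_s = st)
  }
  as_spike_raster(dplyr::bind_rows(spikes), n_electrodes, duration)
}

toy_training_set <- function(n = 5000, d = 1, noise = 0.1, seed = 1) {
  set.seed(seed)
  theta <- matrix(stats::runif(n * d), n, d)
  x <- theta + matrix(stats::rnorm(n * d, 0, noise), n, d)
  ranges <- tibble::tibble(
    parameter = paste0("theta", seq_len(d)),
    lower = 0, upper = 1,
    unit = "-", description = "toy parameter")
  colnames(theta) <- ranges$parameter
  colnames(x) <- paste0("x", seq_len(d))
  build_training_set(tibble::as_tibble(theta),
                     features = tibble::as_tibble(x),
                     ranges = ranges,
                     provenance = list(kind = "toy-simulator",
                                       noise = noise, seed = seed))
}

#' Sub-prior of the reduced 5-parameter model
#'
#' The five parameters with the clearest pathways to network activity
#' (noise drive, AMPA strength, connectivity, and the two short-term
#' depression constants); the remaining parameters are clamped at their
#' prior midpoints.
#'
#' @return Prior-ranges tibble with 5 rows.
#' @export
reduced_ranges <- function() {
  pr <- prior_ranges()
  pr[pr$parameter %in% c("noise_sd", "g_AMPA", "conn_p", "tau_D",
                         "U_std"), ]
}

#' Fill a reduced parameter vector up to the full parameter set
#'
#' @param params Named values for a subset of parameters.
#' @return Named list over all 10 parameters, others at prior midpoints.
#' @export
complete_params <- function(params) {
  pr <- prior_ranges()
  full <- as.list((pr$lower + pr$upper) / 2)
  names(full) <- pr$parameter
  if (is.data.frame(params)) params <- as.list(params)
  full[names(params)] <- params
  full
}

reduced_training_set <- function(n = 600, n_neurons = 30, duration = 30,
                                 dt = 0.1, seed = 1,
                                 progress = FALSE) {
  ranges <- reduced_ranges()
  params <- sample_prior(n, seed = seed, ranges = ranges)
  fixed <- fixed_params(dt = dt)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_network(complete_params(params[i, ]), fixed,
                            duration, seed = seed + i,
                            n_neurons = n_neurons)
    feats[[i]] <- compute_features(sim$raster)
    if (progress && i %% 50 == 0) message("simulated ", i, "/", n)
  }
  build_training_set(params, features = dplyr::bind_rows(feats),
                     ranges = ranges,
                     provenance = list(kind = "reduced-model", n = n,
                                       n_neurons = n_neurons,
                                       duration = duration, dt = dt,
                                       seed = seed))
}

#' Simulate features for one reduced-model parameter vector
#'
#' Companion to the `"reduced-model"` fixture: simulates the reduced
#' network at `params` with the same settings recorded in a training
#' set's provenance and returns the feature row.
#'
#' @param params Named values for the reduced parameters.
#' @param provenance Provenance list of a reduced-model training set.
#' @param seed Integer seed.
#' @return One-row feature tibble.
#' @export
reduced_model_features <- function(params, provenance, seed = 1) {
  fixed <- fixed_params(dt = provenance$dt %||% 0.1)
  sim <- simulate_network(complete_params(params), fixed,
                          provenance$duration %||% 30, seed = seed,
                          n_neurons = provenance$n_neurons %||% 30)
  compute_features(sim$raster)
}
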