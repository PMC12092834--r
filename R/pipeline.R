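#' Run the inference pipeline end to end
#'
#' Executes the full chain on one machine: sample the prior, simulate
#' every draw, extract MEA features, train the density estimator,
#' condition it on an observation, and summarize the posterior
#' (samples, marginal summary, joint mode). Stage artifacts are written
#' as plain CSV/JSON files carrying the configuration hash and seeds;
#' stages whose artifact already exists with the same hash are skipped,
#' so an interrupted run resumes where it stopped.
#'
#' @param config Named list:
#'   \describe{
#'     \item{n_sims}{number of prior simulations}
#'     \item{duration}{simulated seconds per draw}
#'     \item{n_neurons}{network size}
#'     \item{dt}{integration step, ms}
#'     \item{parameters}{free-parameter names (default: all ten;
#'       a subset clamps the rest at prior midpoints)}
#'     \item{seed}{base seed}
#'     \item{out_dir}{artifact directory}
#'     \item{observation}{optional feature row to condition on;
#'       default: a held-out simulation from the last prior draw's
#'       parameters with a fresh seed}
#'     \item{flow}{optional list of [train_nde()] settings}
#'   }
#' @param quiet Suppress per-stage messages.
#' @return List: `training_set`, `model`, `posterior`, `summary`
#'   (tidy marginals), `mode`, `paths` (artifact files).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  defaults <- list(n_sims = 100, duration = 30, n_neurons = 30, dt = 0.1,
                   parameters = param_names(), seed = 1,
                   out_dir = tempfile("mea_run_"), observation = NULL,
                   flow = list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  say <- function(...) if (!quiet) message(...)

  pr <- prior_ranges()
  ranges <- pr[pr$parameter %in% cfg$parameters, ]
  fixed <- fixed_params(dt = cfg$dt)
  pth <- function(nm) file.path(cfg$out_dir, paste0(nm, "-", hash, ".csv"))

  # stage 1-3: prior draws, simulations, features
  if (file.exists(pth("features")) && file.exists(pth("params"))) {
    say("stage simulate: artifacts found, skipping")
    params <- tibble::as_tibble(utils::read.csv(pth("params")))
    feats <- tibble::as_tibble(utils::read.csv(pth("features")))
  } else {
    say("stage simulate: ", cfg$n_sims, " prior simulations")
    params <- sample_prior(cfg$n_sims, seed = cfg$seed, ranges = ranges)
    feats <- dplyr::bind_rows(lapply(seq_len(cfg$n_sims), function(i) {
      sim <- simulate_network(complete_params(params[i, ]), fixed,
                              cfg$duration, seed = cfg$seed + i,
                              n_neurons = cfg$n_neurons)
      compute_features(sim$raster)
    }))
    utils::write.csv(params, pth("params"), row.names = FALSE)
    utils::write.csv(feats, pth("features"), row.names = FALSE)
  }

  ts <- build_training_set(params, features = feats, ranges = ranges,
                           provenance = list(kind = "pipeline",
                                             config = cfg[c(
                                               "n_sims", "duration",
                                               "n_neurons", "dt", "seed")],
                                             hash = hash))
  say("stage train: fitting density estimator")
  model <- do.call(train_nde,
                   c(list(ts = ts, seed = cfg$seed,
                          min_n = min(500, cfg$n_sims)), cfg$flow))

  obs <- cfg$observation
  if (is.null(obs)) {
    say("stage observe: simulating a held-out observation")
    sim <- simulate_network(complete_params(params[nrow(params), ]),
                            fixed, cfg$duration,
                            seed = cfg$seed + cfg$n_sims + 1L,
                            n_neurons = cfg$n_neurons)
    obs <- compute_features(sim$raster)
  }
  post <- posterior_for(obs, model, id = "pipeline-observation")
  smry <- tidy(post, seed = cfg$seed)
  mode <- posterior_mode(post, seed = cfg$seed)
  utils::write.csv(smry, pth("posterior_summary"), row.names = FALSE)
  utils::write.csv(mode, pth("posterior_mode"), row.names = FALSE)
  jsonlite::write_json(
    list(hash = hash,
         config = cfg[setdiff(names(cfg), c("observation", "out_dir"))]),
    file.path(cfg$out_dir, paste0("config-", hash, ".json")),
    auto_unbox = TRUE, digits = NA)
  list(training_set = ts, model = model, posterior = post,
       summary = smry, mode = mode,
       paths = c(params = pth("params"), features = pth("features"),
                 summary = pth("posterior_summary"),
                 mode = pth("posterior_mode")))
}

config_hash <- function(cfg) {
  key <- cfg[c("n_sims", "duration", "n_neurons", "dt", "seed",
               "parameters")]
  txt <- paste(vapply(key, function(x) paste(x, collapse = ","),
                      character(1)), collapse = "|")
  # small deterministic string hash (djb2)
  h <- 5381
  for (ch in utf8ToInt(txt)) h <- (h * 33 + ch) %% 2^28
  sprintf("%07x", h)
}

#' Simulate with the posterior mode and compare features
#'
#' Runs `n` simulations at the joint mode of a posterior and quantifies
#' their MEA features; when a group of observed feature rows is given,
#' each feature is compared between mode simulations and observations
#' with a Mann-Whitney test via [compare_features()].
#'
#' @param posterior A `mea_posterior`.
#' @param n Number of mode simulations (default 10).
#' @param seed Base seed (simulation i uses `seed + i`).
#' @param fixed,duration,n_neurons Simulator settings.
#' @param observed Optional feature tibble of observed recordings (>= 3
#'   rows) for the comparison.
#' @return List: `mode` (one-row tibble), `features` (n-row tibble),
#'   `comparison` (tibble or `NULL`).
#' @export
simulate_from_mode <- function(posterior, n = 10, seed = 1,
                               fixed = fixed_params(), duration = 30,
                               n_neurons = 100, observed = NULL) {
  if (n == 0) {
    return(list(mode = posterior_mode(posterior, seed = seed),
                features = compute_features(
                  as_spike_raster(tibble::tibble(electrode = integer(0),
                                                 time_s = numeric(0)),
                                  duration = duration))[0, ],
                comparison = NULL))
  }
  mode <- posterior_mode(posterior, seed = seed)
  feats <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    sim <- simulate_network(complete_params(mode), fixed, duration,
                            seed = seed + i, n_neurons = n_neurons)
    compute_features(sim$raster)
  }))
  comparison <- if (!is.null(observed)) {
    compare_features(feats, observed)
  }
  list(mode = mode, features = feats, comparison = comparison)
}
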