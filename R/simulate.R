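#' Simulate a network of Hodgkin-Huxley neurons
#'
#' Integrates the coupled stochastic system: single-compartment
#' Hodgkin-Huxley neurons (Traub-Miles kinetics shifted by `V_T`) with a
#' slow AHP conductance incremented at every spike, conductance-based
#' AMPA and NMDA synapses (Jahr-Stevens magnesium block on NMDA),
#' Tsodyks-Markram short-term depression, Wang-style asynchronous
#' release, Ornstein-Uhlenbeck membrane-potential noise, heterogeneous
#' constant input currents and distance-dependent conduction delays.
#' Spikes are upward crossings of 0 mV with a 2 ms dead time; each
#' neuron's spikes are pooled onto its nearest virtual electrode to form
#' the MEA raster.
#'
#' The result is bit-reproducible for fixed `(params, seed, dt,
#' duration)`: topology, initial conditions, membrane noise and
#' asynchronous events use separate named random streams derived from
#' `seed`.
#'
#' @param params Free parameters: one row of [sample_prior()] or a named
#'   list (see [prior_ranges()]).
#' @param fixed Fixed parameters, see [fixed_params()]. `fixed$dt` (ms)
#'   is the integration step.
#' @param duration Simulated time in seconds (default 180, i.e. the
#'   3-minute protocol).
#' @param seed Integer seed.
#' @param n_neurons Network size (default 100).
#' @param topology Optional pre-built [build_topology()] object; when
#'   `NULL` the topology is built from `params$conn_p` with a seed
#'   derived from `seed`. Passing a fixed topology while varying `seed`
#'   varies only noise/initial conditions.
#' @return An object of class `mea_sim`: list with `raster` (tibble
#'   `electrode`, `time_s`), `neuron_spikes` (tibble `neuron`,
#'   `time_s`), `duration`, `dt`, `seed`, `params`, `n_electrodes`.
#' @export
simulate_network <- function(params, fixed = fixed_params(),
                             duration = 180, seed = 1,
                             n_neurons = 100, topology = NULL) {
  v <- validate_params(params)
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be a positive number of seconds")
  }
  if (is.null(topology)) {
    topology <- build_topology(as.list(v), fixed, n_neurons = n_neurons,
                               seed = seed + 1000003L)
  }
  res <- .simulate_network_cpp(
    topology$n_neurons,
    as.integer(topology$edges$from), as.integer(topology$edges$to),
    as.numeric(topology$edges$weight), as.numeric(topology$edges$delay_ms),
    as.numeric(topology$input_current),
    as.list(v), fixed, duration, as.numeric(seed)
  )
  neuron_spikes <- tibble::tibble(neuron = res$neuron, time_s = res$time_s)
  raster <- tibble::tibble(
    electrode = topology$electrode_map[res$neuron + 1L],
    time_s = res$time_s
  )
  raster <- dplyr::arrange(raster, .data$electrode, .data$time_s)
  structure(
    list(raster = new_spike_raster(raster, topology$n_electrodes, duration),
         neuron_spikes = neuron_spikes,
         duration = duration, dt = fixed$dt, seed = seed,
         params = as.list(v), n_electrodes = topology$n_electrodes),
    class = "mea_sim"
  )
}

#' @export
print.mea_sim <- function(x, ...) {
  cat(sprintf(
    "<mea_sim> %.0f s, %d spikes on %d electrodes (seed %s)\n",
    x$duration, nrow(x$raster), x$n_electrodes, format(x$seed)))
  invisible(x)
}

#' Construct a spike raster table
#'
#' A spike raster is a tibble with columns `electrode` (0-based id) and
#' `time_s`, sorted within electrode, plus attributes `n_electrodes` and
#' `duration`. All feature extraction operates on this one
#' representation, whether the spikes come from simulation or from
#' recordings.
#'
#' @param spikes Data frame with columns `electrode` and `time_s`.
#' @param n_electrodes Number of recording sites (default 12).
#' @param duration Recording length in seconds.
#' @return A `mea_raster` tibble.
#' @export
as_spike_raster <- function(spikes, n_electrodes = 12, duration = NULL) {
  stopifnot(all(c("electrode", "time_s") %in% names(spikes)))
  if (is.null(duration)) {
    duration <- if (nrow(spikes)) max(spikes$time_s) else 0
  }
  if (nrow(spikes) && (min(spikes$time_s) < 0 ||
                       max(spikes$time_s) > duration + 1e-9)) {
    stop("spike times must lie within [0, duration]")
  }
  out <- dplyr::arrange(
    tibble::tibble(electrode = as.integer(spikes$electrode),
                   time_s = as.numeric(spikes$time_s)),
    .data$electrode, .data$time_s)
  new_spike_raster(out, n_electrodes, duration)
}

new_spike_raster <- function(tbl, n_electrodes, duration) {
  structure(tbl,
            n_electrodes = as.integer(n_electrodes),
            duration = as.numeric(duration),
            class = c("mea_raster", class(tibble::tibble())))
}

raster_duration <- function(raster) attr(raster, "duration")
raster_n_electrodes <- function(raster) {
  n <- attr(raster, "n_electrodes")
  if (is.null(n)) n <- 12L
  n
}

#' Read / write a spike raster as CSV
#'
#' The on-disk format is a plain CSV with header `electrode,time_s`
#' (0-based electrode ids, seconds, sorted).
#'
#' @param raster A `mea_raster`.
#' @param path File path.
#' @param n_electrodes,duration Metadata for [read_raster()] (duration
#'   defaults to the last spike time rounded up to a second).
#' @return `write_raster()` returns `path` invisibly; `read_raster()`
#'   returns a `mea_raster`.
#' @export
write_raster <- function(raster, path) {
  df <- data.frame(electrode = raster$electrode,
                   time_s = sprintf("%.17g", raster$time_s))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, n_electrodes = 12, duration = NULL) {
  df <- utils::read.csv(path)
  if (is.null(duration) && nrow(df)) duration <- ceiling(max(df$time_s))
  as_spike_raster(df, n_electrodes, duration)
}
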