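#' One step of the Tsodyks-Markram short-term-depression synapse
#'
#' Between presynaptic spikes the synaptic resource recovers towards 1
#' with timescale `tau_D`; when a spike arrives, a fraction `U_std` of
#' the current resource is released and subtracted.
#'
#' @param x Current resource fraction in `[0, 1]`.
#' @param dt_since_spike Time since the previous presynaptic spike (ms).
#' @param params List with `U_std` and `tau_D` (ms).
#' @return A list with `released` (fraction released by the arriving
#'   spike) and `x` (post-spike resource).
#' @export
#' @examples
#' synapse_step(1, 100, list(U_std = 0.2, tau_D = 500))
synapse_step <- function(x, dt_since_spike, params) {
  if (!is.finite(x) || x < 0 || x > 1) {
    stop("resource `x` must lie in [0, 1]")
  }
  if (params$tau_D <= 0) stop("`tau_D` must be positive")
  x_rec <- 1 - (1 - x) * exp(-dt_since_spike / params$tau_D)
  released <- params$U_std * x_rec
  list(released = released, x = x_rec - released)
}

#' Pre-spike steady state of the depressing synapse under periodic drive
#'
#' For presynaptic spikes at fixed interval `T`, the resource seen by
#' each spike converges to
#' \deqn{x^* = \frac{1 - e^{-T/\tau_D}}{1 - (1-U)\,e^{-T/\tau_D}}.}
#'
#' @param U_std Release strength.
#' @param tau_D Recovery timescale (ms).
#' @param interval Inter-spike interval `T` (ms).
#' @return The fixed-point resource fraction.
#' @export
std_steady_state <- function(U_std, tau_D, interval) {
  e <- exp(-interval / tau_D)
  (1 - e) / (1 - (1 - U_std) * e)
}

#' Iterate the depressing synapse over a presynaptic spike train
#'
#' @param spike_times Sorted presynaptic spike times (ms).
#' @param params List with `U_std`, `tau_D`.
#' @param x0 Initial resource (default 1, rested).
#' @return Tibble with one row per spike: `time_ms`, `x_pre` (resource
#'   seen by the spike, after recovery), `released`, `x_post`.
#' @export
std_train <- function(spike_times, params, x0 = 1) {
  x <- x0
  last <- -Inf
  out <- matrix(NA_real_, nrow = length(spike_times), ncol = 3)
  for (k in seq_along(spike_times)) {
    dt <- spike_times[k] - last
    x_rec <- if (is.finite(dt)) 1 - (1 - x) * exp(-dt / params$tau_D) else x
    rel <- params$U_std * x_rec
    x <- x_rec - rel
    out[k, ] <- c(x_rec, rel, x)
    last <- spike_times[k]
  }
  tibble::tibble(time_ms = spike_times, x_pre = out[, 1],
                 released = out[, 2], x_post = out[, 3])
}

#' Asynchronous-release rate trajectory for a presynaptic spike history
#'
#' A residual release variable increments by `U_asyn` at every
#' presynaptic spike (saturating at `U_max`) and decays exponentially
#' with timescale `tau_asyn`; asynchronous release events occur as an
#' inhomogeneous point process with this rate.
#'
#' @param spike_times Sorted presynaptic spike times (ms).
#' @param params List with `U_asyn`.
#' @param fixed Fixed parameters (uses `tau_asyn`, `U_max`).
#' @param t_grid Times (ms) at which to evaluate the rate.
#' @return Tibble with `time_ms` and `rate` (events per ms).
#' @export
asynchronous_release_rate <- function(spike_times, params,
                                      fixed = fixed_params(),
                                      t_grid) {
  if (params$U_asyn < 0) stop("`U_asyn` must be non-negative")
  a <- 0
  t_last <- -Inf
  # residual immediately after each spike
  a_post <- numeric(length(spike_times))
  for (k in seq_along(spike_times)) {
    if (is.finite(t_last)) {
      a <- a * exp(-(spike_times[k] - t_last) / fixed$tau_asyn)
    }
    a <- min(a + params$U_asyn, fixed$U_max)
    a_post[k] <- a
    t_last <- spike_times[k]
  }
  rate <- vapply(t_grid, function(t) {
    k <- findInterval(t, spike_times)
    if (k == 0) return(0)
    a_post[k] * exp(-(t - spike_times[k]) / fixed$tau_asyn)
  }, numeric(1))
  tibble::tibble(time_ms = t_grid, rate = rate)
}
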