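#' Build the synaptic topology of a model network
#'
#' Neurons are placed on a square grid. Each ordered pair of distinct
#' neurons is connected independently with probability `conn_p`. Synaptic
#' weights are lognormal with mean 1 and coefficient of variation `sd_w`
#' (guaranteeing positivity); conduction delays grow linearly with
#' Euclidean grid distance, scaled so the largest possible distance maps
#' to `max_delay`. Twelve virtual electrodes are placed as a 4 x 3
#' interior grid (mimicking an MEA well in which the four corner sites
#' are absent) and every neuron is assigned to its nearest electrode.
#'
#' @param params Free parameters (only `conn_p` is used here); a named
#'   list/one-row data frame, or a single numeric connection probability.
#' @param fixed Fixed parameters from [fixed_params()].
#' @param n_neurons Number of neurons (>= 2).
#' @param seed Integer seed for the topology stream.
#' @param n_electrodes Number of virtual electrodes (default 12).
#' @return An object of class `mea_topology`: a list with
#'   `positions` (tibble: neuron, x, y), `edges` (tibble: from, to,
#'   weight, delay_ms), `electrode_map` (integer vector, one electrode id
#'   in `0:(n_electrodes-1)` per neuron), `input_current` (pA per
#'   neuron), and `n_neurons`.
#' @export
build_topology <- function(params, fixed = fixed_params(), n_neurons = 100,
                           seed = 1, n_electrodes = 12) {
  if (is.numeric(params) && length(params) == 1) {
    conn_p <- params
  } else {
    if (is.data.frame(params)) params <- as.list(params)
    conn_p <- as.numeric(params$conn_p)
  }
  if (!is.finite(conn_p) || conn_p < 0 || conn_p > 1) {
    stop("`conn_p` must lie in [0, 1]")
  }
  if (n_neurons < 2) stop("`n_neurons` must be at least 2")
  n_neurons <- as.integer(n_neurons)
  set.seed(seed)

  side <- ceiling(sqrt(n_neurons))
  idx <- seq_len(n_neurons) - 1L
  pos <- tibble::tibble(
    neuron = idx,
    x = as.numeric(idx %% side),
    y = as.numeric(idx %/% side)
  )

  # directed Bernoulli adjacency, self-connections excluded
  from <- rep(idx, each = n_neurons)
  to <- rep(idx, times = n_neurons)
  keep <- from != to & stats::runif(length(from)) < conn_p
  from <- from[keep]; to <- to[keep]

  # lognormal weights: mean 1, cv = sd_w
  sdlog <- sqrt(log(1 + fixed$sd_w^2))
  w <- stats::rlnorm(length(from), meanlog = -sdlog^2 / 2, sdlog = sdlog)

  dx <- pos$x[from + 1L] - pos$x[to + 1L]
  dy <- pos$y[from + 1L] - pos$y[to + 1L]
  dist <- sqrt(dx^2 + dy^2)
  max_dist <- sqrt(2) * (side - 1)
  delay <- fixed$max_delay * dist / max_dist
  delay <- pmax(delay, 1e-3)   # delays strictly positive

  elec <- electrode_positions(n_electrodes, side)
  d2 <- outer(pos$x, elec$x, "-")^2 + outer(pos$y, elec$y, "-")^2
  electrode_map <- max.col(-d2, ties.method = "first") - 1L

  input_current <- stats::rnorm(n_neurons, fixed$input_mean, fixed$input_sd)

  structure(
    list(
      positions = pos,
      edges = tibble::tibble(from = from, to = to, weight = w,
                             delay_ms = delay),
      electrode_map = electrode_map,
      input_current = input_current,
      n_neurons = n_neurons,
      n_electrodes = as.integer(n_electrodes),
      conn_p = conn_p,
      seed = seed
    ),
    class = "mea_topology"
  )
}

# interior grid of electrode coordinates covering the neuron grid
electrode_positions <- function(n_electrodes, side) {
  nc <- ceiling(sqrt(n_electrodes))
  nr <- ceiling(n_electrodes / nc)
  # interior placement: electrodes at fractional positions, away from edges
  xs <- (seq_len(nc) - 0.5) / nc * (side - 1)
  ys <- (seq_len(nr) - 0.5) / nr * (side - 1)
  g <- expand.grid(x = xs, y = ys)[seq_len(n_electrodes), ]
  tibble::tibble(x = g$x, y = g$y)
}

#' @export
print.mea_topology <- function(x, ...) {
  cat(sprintf(
    "<mea_topology> %d neurons, %d connections (conn_p = %.3g), %d electrodes\n",
    x$n_neurons, nrow(x$edges), x$conn_p, x$n_electrodes))
  invisible(x)
}
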