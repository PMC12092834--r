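#' Prior ranges of the ten free biophysical parameters
#'
#' The box prior over the free parameters of the network model: membrane
#' noise, delayed-rectifier K and voltage-gated Na conductance densities,
#' sAHP conductance, AMPA and NMDA synaptic conductances, connection
#' probability, and the short-term-depression / asynchronous-release
#' parameters. Each parameter is uniform and independent within its range.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`, `unit`,
#'   `description`, one row per free parameter, in canonical order.
#' @export
#' @examples
#' prior_ranges()
prior_ranges <- function() {
  tibble::tibble(
    parameter = c("noise_sd", "g_K", "g_Na", "g_AHP", "g_AMPA",
                  "g_NMDA", "conn_p", "tau_D", "U_std", "U_asyn"),
    lower = c(1.5, 0.5, 25, 0.5, 0.05, 0, 0.1, 150, 0.005, 0),
    upper = c(7, 50, 100, 10, 1, 1, 0.6, 1200, 0.3, 0.005),
    unit = c("mV", "mS/cm^2", "mS/cm^2", "nS", "nS", "nS", "-", "ms",
             "-", "-"),
    description = c(
      "sd of membrane-potential fluctuations",
      "max delayed-rectifier K conductance density",
      "max voltage-gated Na conductance density",
      "max slow-AHP conductance",
      "max AMPA receptor conductance",
      "max NMDA receptor conductance",
      "probability that an ordered neuron pair is connected",
      "recovery timescale of short-term depression",
      "release strength of short-term depression",
      "strength of asynchronous release"
    )
  )
}

#' Names of the free parameters in canonical order
#' @return Character vector of length 10.
#' @export
param_names <- function() prior_ranges()$parameter

#' Fixed parameters of the network model
#'
#' Defaults for the quantities held fixed during inference: passive
#' membrane properties, Nernst potentials, synaptic and sAHP time
#' constants, conduction-delay cap, synaptic-weight spread, and the
#' asynchronous-release constants. Any value can be overridden, e.g. for
#' reduced test models.
#'
#' @param ... Named overrides, e.g. `fixed_params(tau_AHP = 3)`.
#' @return Named list of fixed parameters.
#' @export
fixed_params <- function(...) {
  p <- list(
    area = 300,            # membrane area, um^2
    C_m = 1,               # membrane capacitance, uF/cm^2
    g_l = 0.3,             # leak conductance density, mS/cm^2
    E_K = -80,             # K Nernst potential, mV
    E_Na = 70,             # Na Nernst potential, mV
    E_l = -39.2,           # leak reversal, mV
    V_T = -30.4,           # spike-threshold adaptation potential, mV
    alpha_Ca = 0.00035,    # sAHP increment per spike
    tau_AHP = 6,           # sAHP recovery, s
    E_AMPA = 0,            # AMPA reversal, mV
    E_NMDA = 0,            # NMDA reversal, mV
    alpha_NMDA = 0.5,      # NMDA rise->decay coupling, kHz
    tau_AMPA = 2,          # AMPA decay, ms
    tau_NMDA_decay = 100,  # NMDA decay, ms
    tau_NMDA_rise = 2,     # NMDA rise, ms
    max_delay = 25,        # conduction-delay cap, ms
    sd_w = 0.7,            # synaptic-weight coefficient of variation
    tau_asyn = 700,        # asynchronous-release recovery, ms
    U_max = 0.5,           # asynchronous-rate saturation, 1/ms
    x_0 = 5,               # neurotransmitter per vesicle (dimensionless)
    # integration / implementation constants (not in the biophysics table)
    tau_noise = 5,         # OU correlation time of membrane noise, ms
    dt = 0.05,             # integration step, ms
    refractory = 2,        # spike-extraction dead time, ms
    mg_conc = 1,           # extracellular Mg2+, mM (Jahr-Stevens block)
    input_mean = 5,        # heterogeneous external current mean, pA
    input_sd = 2           # heterogeneous external current sd, pA
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
    }
    p[names(over)] <- over
  }
  if (p$tau_NMDA_rise >= p$tau_NMDA_decay) {
    stop("tau_NMDA_rise must be smaller than tau_NMDA_decay")
  }
  p
}

#' Sample parameter vectors from the box prior
#'
#' Draws independent uniform samples within the prior ranges of each free
#' parameter.
#'
#' @param n Number of parameter vectors to draw (non-negative integer).
#' @param seed Integer seed; identical seeds give identical draws.
#' @param ranges Prior ranges tibble, defaults to [prior_ranges()]. A
#'   subset of rows defines a sub-prior over fewer parameters.
#' @return A tibble with `n` rows and one column per parameter.
#' @export
#' @examples
#' sample_prior(3, seed = 1)
sample_prior <- function(n, seed = NULL, ranges = prior_ranges()) {
  if (length(n) != 1 || is.na(n) || n < 0) {
    stop("`n` must be a single non-negative integer")
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  draws <- purrr::map2(ranges$lower, ranges$upper,
                       function(lo, hi) stats::runif(n, lo, hi))
  names(draws) <- ranges$parameter
  tibble::as_tibble(draws, .name_repair = "minimal")[, ranges$parameter,
                                                     drop = FALSE]
}

#' Validate a single free-parameter vector
#'
#' @param params Named list or one-row data frame of free parameters.
#' @param ranges Prior ranges tibble (subset allowed).
#' @param check_box If `TRUE`, error when a value falls outside its prior
#'   range; otherwise only finiteness and naming are checked.
#' @return The parameters as a named numeric vector, invisibly usable.
#' @keywords internal
validate_params <- function(params, ranges = prior_ranges(),
                            check_box = FALSE) {
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1)
    params <- as.list(params)
  }
  missing <- setdiff(ranges$parameter, names(params))
  if (length(missing)) {
    stop("missing free parameter(s): ", paste(missing, collapse = ", "))
  }
  v <- vapply(ranges$parameter, function(nm) as.numeric(params[[nm]]),
              numeric(1))
  if (any(!is.finite(v))) {
    stop("non-finite free parameter(s): ",
         paste(ranges$parameter[!is.finite(v)], collapse = ", "))
  }
  if (check_box) {
    out <- v < ranges$lower | v > ranges$upper
    if (any(out)) {
      stop("parameter(s) outside the prior box: ",
           paste(ranges$parameter[out], collapse = ", "))
    }
  }
  v
}
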