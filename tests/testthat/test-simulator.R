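mid_params <- function(...) {
  p <- complete_params(list())
  over <- list(...)
  p[names(over)] <- over
  p
}

test_that("identical parameters and seed give identical rasters", {
  fx <- fixed_params(dt = 0.1)
  p <- mid_params()
  a <- simulate_network(p, fx, duration = 15, seed = 4, n_neurons = 30)
  b <- simulate_network(p, fx, duration = 15, seed = 4, n_neurons = 30)
  expect_identical(a$raster$time_s, b$raster$time_s)
  expect_identical(a$raster$electrode, b$raster$electrode)
  c <- simulate_network(p, fx, duration = 15, seed = 5, n_neurons = 30)
  expect_false(identical(a$raster$time_s, c$raster$time_s))
})

test_that("spikes lie inside the recording and cover 12 electrodes worth of ids", {
  fx <- fixed_params(dt = 0.1)
  p <- complete_params(sample_prior(1, seed = 9))
  sim <- simulate_network(p, fx, duration = 10, seed = 2, n_neurons = 30)
  expect_true(all(sim$raster$time_s >= 0))
  expect_true(all(sim$raster$time_s <= 10))
  expect_true(all(sim$raster$electrode %in% 0:11))
  expect_identical(sim$n_electrodes, 12L)
})

test_that("electrode raster conserves the per-neuron spike counts", {
  fx <- fixed_params(dt = 0.1)
  p <- mid_params(noise_sd = 6)
  sim <- simulate_network(p, fx, duration = 10, seed = 3, n_neurons = 30)
  expect_gt(nrow(sim$neuron_spikes), 0)
  expect_identical(nrow(sim$raster), nrow(sim$neuron_spikes))
})

test_that("a disconnected, quiet network produces no spikes and no bursts", {
  fx <- fixed_params(dt = 0.1)
  p <- mid_params(g_AMPA = 0, g_NMDA = 0, U_asyn = 0, noise_sd = 1.5,
                  conn_p = 0.1)
  top <- build_topology(p, fx, n_neurons = 50, seed = 11)
  top$input_current[] <- 0   # external drive disabled
  sim <- simulate_network(p, fx, duration = 20, seed = 11,
                          n_neurons = 50, topology = top)
  expect_identical(nrow(sim$raster), 0L)
  expect_identical(nrow(detect_bursts(sim$raster)), 0L)
})

test_that("silent limit: no synapses and minimal noise give no network bursts", {
  fx <- fixed_params(dt = 0.1)
  p <- mid_params(g_AMPA = 0, g_NMDA = 0, U_asyn = 0, noise_sd = 1.5)
  sim <- simulate_network(p, fx, duration = 60, seed = 8, n_neurons = 50)
  f <- compute_features(sim$raster)
  expect_equal(f$PSIB, 0)
  expect_equal(f$NBR, 0)
})

test_that("more membrane noise never means fewer spikes (fixed topology)", {
  fx <- fixed_params(dt = 0.1)
  for (s in 1:5) {
    p_lo <- mid_params(noise_sd = 1.5)
    top <- build_topology(p_lo, fx, n_neurons = 30, seed = 100 + s)
    n_lo <- nrow(simulate_network(p_lo, fx, 30, seed = s, n_neurons = 30,
                                  topology = top)$raster)
    p_hi <- mid_params(noise_sd = 7)
    n_hi <- nrow(simulate_network(p_hi, fx, 30, seed = s, n_neurons = 30,
                                  topology = top)$raster)
    expect_gte(n_hi, n_lo)
  }
})

test_that("an isolated neuron fires tonically with rate increasing in current", {
  fx <- fixed_params(dt = 0.05)
  p <- mid_params(noise_sd = 0, g_AMPA = 0, g_NMDA = 0, conn_p = 0)
  rates <- vapply(c(12, 15, 20, 25, 30), function(I) {
    top <- build_topology(p, fx, n_neurons = 2, seed = 1)
    top$input_current[] <- c(I, 0)
    sim <- simulate_network(p, fx, duration = 5, seed = 1, n_neurons = 2,
                            topology = top)
    nrow(sim$raster) / 5
  }, numeric(1))
  expect_gt(rates[2], 2)                  # tonic firing above rheobase
  expect_true(all(diff(rates) >= 0))      # f-I curve is non-decreasing
})

test_that("simulation rejects invalid inputs", {
  fx <- fixed_params(dt = 0.1)
  p <- mid_params(); p$g_Na <- Inf
  expect_error(simulate_network(p, fx, 1, seed = 1, n_neurons = 10),
               "non-finite")
  expect_error(simulate_network(mid_params(), fx, -5, seed = 1,
                                n_neurons = 10), "positive")
})

test_that("raster round-trips through the CSV format", {
  fx <- fixed_params(dt = 0.1)
  sim <- simulate_network(mid_params(noise_sd = 6), fx, 5, seed = 2,
                          n_neurons = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster(sim$raster, path)
  back <- read_raster(path, n_electrodes = 12, duration = 5)
  expect_equal(back$time_s, sim$raster$time_s)
  expect_equal(back$electrode, sim$raster$electrode)
  expect_identical(readLines(path, n = 1), "electrode,time_s")
})
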