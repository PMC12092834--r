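empty_raster <- function(duration = 60) {
  as_spike_raster(tibble::tibble(electrode = integer(0),
                                 time_s = numeric(0)),
                  n_electrodes = 12, duration = duration)
}

test_that("network rate conserves spikes and handles trivial rasters", {
  r0 <- network_rate(empty_raster())
  expect_true(all(r0$counts == 0))
  expect_equal(r0$max_rate, 0)
  one <- as_spike_raster(tibble::tibble(electrode = 0:11,
                                        time_s = rep(0.01, 12)),
                         n_electrodes = 12, duration = 60)
  r1 <- network_rate(one)
  expect_equal(r1$counts[1], 12)
  expect_true(all(r1$counts[-1] == 0))
  expect_equal(sum(r1$counts), 12)
})

test_that("Poisson rasters match the expected mean bin count", {
  set.seed(3)
  r_hz <- 5
  spikes <- tibble::tibble(
    electrode = rep(0:11, each = r_hz * 60),
    time_s = runif(12 * r_hz * 60, 0, 60))
  rate <- network_rate(as_spike_raster(spikes, 12, 60))
  expected <- 12 * r_hz * 0.025
  se <- sqrt(expected / length(rate$counts))
  expect_lt(abs(mean(rate$counts) - expected), 3 * se)
})

test_that("crafted two-burst raster is detected with hand-checked timing", {
  b <- detect_bursts(two_burst_raster())
  expect_identical(nrow(b), 2L)
  expect_lt(abs(b$start[1] - 1.0), 0.025 + 1e-9)
  expect_lt(abs(b$start[2] - 5.0), 0.025 + 1e-9)
  expect_true(all(abs(b$duration - 0.30) <= 0.05))
  expect_true(all(b$n_electrodes == 12))
})

test_that("the 50% participation rule excludes a minority-electrode event", {
  # second event on 5 of 12 electrodes: 5 < 6 = 50% of active electrodes
  b <- detect_bursts(two_burst_raster(participating2 = 0:4,
                                      background = FALSE))
  expect_identical(nrow(b), 1L)
  expect_lt(abs(b$start[1] - 1.0), 0.025 + 1e-9)
  # with exactly 6 participating electrodes the event is kept
  b6 <- detect_bursts(two_burst_raster(participating2 = 0:5,
                                       background = FALSE))
  expect_identical(nrow(b6), 2L)
})

test_that("burst detection is empty for empty or zero-activity rasters", {
  expect_identical(nrow(detect_bursts(empty_raster())), 0L)
})

test_that("fragment counting follows the height and prominence rules", {
  mk_rate <- function(counts) {
    structure(list(counts = counts, bin_ms = 25, max_rate = max(counts),
                   duration = length(counts) * 0.025,
                   breaks = seq(0, length(counts)) * 0.025),
              class = "mea_rate")
  }
  win <- function(n) list(start = 0, stop = n * 0.025)
  # unimodal: one peak
  uni <- c(0, 2, 8, 2, 0)
  expect_identical(detect_fragments(win(5), mk_rate(uni),
                                    kernel_sd_ms = 0), 1L)
  # bimodal, both peaks above max/16, valley deeper than max/20
  bi <- c(0, 8, 1, 7, 0)
  expect_identical(detect_fragments(win(5), mk_rate(bi),
                                    kernel_sd_ms = 0), 2L)
  # second bump below the max/16 height rule
  low2 <- c(0, 16, 0.5, 0.9, 0.5, 0)
  expect_identical(detect_fragments(win(6), mk_rate(low2),
                                    kernel_sd_ms = 0), 1L)
})

test_that("ISI series values follow the straddling-interval definition", {
  r <- as_spike_raster(tibble::tibble(electrode = 0, time_s = c(0, 1, 3)),
                       n_electrodes = 1, duration = 4)
  s <- isi_series(r)
  on <- !is.na(s$isi[, 1])
  expect_equal(unique(s$isi[s$grid < 1 & on, 1]), 1)
  expect_equal(unique(s$isi[s$grid >= 1 & on, 1]), 2)
  # regular train: constant series, zero temporal sd
  rr <- as_spike_raster(tibble::tibble(electrode = 0, time_s = 0:10),
                        n_electrodes = 1, duration = 11)
  ss <- isi_series(rr)
  expect_equal(stats::sd(ss$isi[!is.na(ss$isi[, 1]), 1]), 0)
  # electrodes with < 2 spikes are excluded
  r1 <- as_spike_raster(tibble::tibble(electrode = c(0, 1), time_s = c(1, 2)),
                        n_electrodes = 2, duration = 4)
  expect_identical(isi_series(r1)$excluded, c(0L, 1L))
})

test_that("identical ISI series on two electrodes correlate perfectly", {
  st <- cumsum(c(0.5, rep(c(0.2, 0.8, 0.4), 10)))
  r <- as_spike_raster(tibble::tibble(electrode = rep(0:1, each = length(st)),
                                      time_s = rep(st, 2)),
                       n_electrodes = 2, duration = max(st) + 1)
  f <- compute_features(r)
  expect_equal(f$mean_ISI_CC, 1, tolerance = 1e-9)
})

test_that("ISI-distance matches the brute-force oracle on constructions", {
  a <- seq(0, 10, by = 0.1)
  expect_equal(isi_distance(a, a), 0)
  # 2:1 periodic ratio: |I| = 0.5 everywhere
  b <- seq(0, 10, by = 0.2)
  expect_equal(isi_distance(a, b), 0.5, tolerance = 1e-6)
  expect_equal(oracle_isi_distance(a, b), 0.5, tolerance = 1e-6)
  # equal period, arbitrary phase: identical ISIs, distance 0
  cph <- seq(0.037, 9.9, by = 0.1)
  expect_lt(isi_distance(a, cph), 1e-9)
  # symmetry and oracle agreement on an irregular pair
  set.seed(8)
  t1 <- sort(runif(60, 0, 10)); t2 <- sort(runif(40, 0, 10))
  expect_equal(isi_distance(t1, t2), isi_distance(t2, t1))
  expect_equal(isi_distance(t1, t2, dt_s = 5e-4),
               oracle_isi_distance(t1, t2), tolerance = 1e-3)
  expect_error(isi_distance(1, t2), "at least 2")
})

test_that("MAC separates rhythmic from flat and noisy rates", {
  mk_rate <- function(counts) {
    structure(list(counts = counts, bin_ms = 25, max_rate = max(counts),
                   duration = length(counts) * 0.025),
              class = "mea_rate")
  }
  expect_equal(mac(mk_rate(rep(5, 2400))), 0)      # zero variance
  tt <- seq_len(2400) * 0.025
  expect_gte(mac(mk_rate(50 + 40 * sin(2 * pi * tt / 2))), 0.95)
  set.seed(4)
  expect_lt(mac(mk_rate(rpois(2400, 5))), 0.2)
})

test_that("feature conventions hold on degenerate rasters", {
  f <- compute_features(empty_raster())
  expect_equal(f$MFR, 0)
  expect_equal(f$NBR, 0)
  expect_equal(f$NBD, 0)
  expect_equal(f$PSIB, 0)
  expect_equal(f$n_FBs, 0)
  expect_equal(f$CV_IBI, 0)
  expect_equal(f$MAC, 0)
  expect_true(all(vapply(f, is.finite, logical(1))))
})

test_that("equally spaced bursts give CV_IBI 0 and the exact burst rate", {
  r <- make_fixture("crafted-raster", n_bursts = 3, period_s = 10,
                    background_hz = 0, duration = 31, seed = 2)
  f <- compute_features(r)
  expect_equal(f$CV_IBI, 0, tolerance = 1e-9)
  expect_equal(f$NBR, 3 / 31 * 60)
  # all spikes inside bursts
  expect_equal(f$PSIB, 100)
})

test_that("binarized correlations match hand-computed constructions", {
  # identical trains on all electrodes
  st <- seq(0.1, 9.9, by = 0.3)
  same <- as_spike_raster(
    tibble::tibble(electrode = rep(0:11, each = length(st)),
                   time_s = rep(st, 12)), 12, 10)
  bc <- binarized_cc(same)
  expect_equal(bc$mean, 1)
  expect_equal(bc$sd, 0)
  # two perfectly anti-phase groups: within-group CC +1, across -1;
  # mean over the 66 pairs is (30 - 36) / 66 = -1/11
  even <- seq(0.0125, 9.99, by = 0.05)   # every even 25 ms bin
  odd <- even + 0.025
  anti <- as_spike_raster(dplyr::bind_rows(
    tibble::tibble(electrode = rep(0:5, each = length(even)),
                   time_s = rep(even, 6)),
    tibble::tibble(electrode = rep(6:11, each = length(odd)),
                   time_s = rep(odd, 6))), 12, 10)
  bca <- binarized_cc(anti)
  expect_equal(bca$mean, -1 / 11, tolerance = 1e-9)
  # independent Poisson trains: mean CC near zero
  set.seed(5)
  pois <- as_spike_raster(
    tibble::tibble(electrode = rep(0:11, each = 300),
                   time_s = runif(3600, 0, 60)), 12, 60)
  expect_lt(abs(binarized_cc(pois)$mean), 0.05)
  # fewer than two usable electrodes
  expect_equal(binarized_cc(empty_raster())$mean, 0)
})

test_that("features are invariant to time shifts up to bin effects", {
  r <- two_burst_raster()
  shifted <- as_spike_raster(
    tibble::tibble(electrode = r$electrode, time_s = r$time_s + 0.5),
    12, 60)
  f0 <- compute_features(r)
  f1 <- compute_features(shifted)
  expect_equal(f1$NBR, f0$NBR)
  expect_equal(f1$MFR, f0$MFR)
  expect_equal(f1$NBD, f0$NBD, tolerance = 0.025 / 0.3)
  expect_equal(f1$PSIB, f0$PSIB, tolerance = 0.05)
  expect_equal(f1$MAC, f0$MAC, tolerance = 0.05)
  expect_equal(f1$mean_ISI, f0$mean_ISI, tolerance = 0.05)
})

test_that("features are invariant under electrode relabelling", {
  r <- two_burst_raster(participating2 = 0:6)
  perm <- c(7L, 2L, 11L, 0L, 5L, 9L, 1L, 10L, 3L, 8L, 6L, 4L)
  relabelled <- as_spike_raster(
    tibble::tibble(electrode = perm[r$electrode + 1L],
                   time_s = r$time_s), 12, 60)
  f0 <- compute_features(r)
  f1 <- compute_features(relabelled)
  expect_equal(as.numeric(f1), as.numeric(f0), tolerance = 1e-8)
})

test_that("one code path serves simulated and externally loaded rasters", {
  fx <- fixed_params(dt = 0.1)
  sim <- simulate_network(complete_params(list(noise_sd = 6)), fx, 10,
                          seed = 3, n_neurons = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster(sim$raster, path)
  loaded <- read_raster(path, n_electrodes = 12, duration = 10)
  expect_equal(compute_features(loaded), compute_features(sim$raster),
               tolerance = 1e-6)
})
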