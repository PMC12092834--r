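#' Network firing rate from a spike raster
#'
#' Bins spikes from all electrodes into fixed-width time bins (25 ms by
#' default), producing the population rate vector that drives
#' network-burst detection.
#'
#' @param raster A `mea_raster` (see [as_spike_raster()]).
#' @param bin_ms Bin width in milliseconds.
#' @return A list of class `mea_rate`: `counts` (spikes per bin summed
#'   over electrodes), `bin_ms`, `max_rate` (maximum bin count),
#'   `duration`, `breaks` (bin edges, s).
#' @export
network_rate <- function(raster, bin_ms = 25) {
  duration <- raster_duration(raster)
  stopifnot(duration > 0)
  n_bins <- ceiling(duration * 1000 / bin_ms)
  breaks <- seq(0, n_bins) * bin_ms / 1000
  idx <- pmin(floor(raster$time_s * 1000 / bin_ms) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(counts = counts, bin_ms = bin_ms,
                 max_rate = if (length(counts)) max(counts) else 0,
                 duration = duration, breaks = breaks),
            class = "mea_rate")
}

#' Detect network bursts from a spike raster
#'
#' A network burst (NB) opens when the 25 ms-binned network firing rate
#' stays at or above 1/4 of its maximum for at least 50 ms, and closes
#' when it stays below 1/50 of the maximum for at least 50 ms. A
#' candidate NB is kept only if at least 50% of the active electrodes
#' (mean firing rate above 0.02 Hz) fire at least one spike within its
#' window. Fragment counts per burst are computed with
#' [detect_fragments()].
#'
#' @param raster A `mea_raster`.
#' @param bin_ms Rate bin width (ms).
#' @param start_frac,stop_frac Start/stop thresholds as fractions of the
#'   maximum rate (defaults 1/4 and 1/50).
#' @param sustain_ms Time the rate must remain above threshold to open
#'   or close a burst (default 50 ms).
#' @param active_rate_hz Minimum mean electrode rate to count as active.
#' @param participation Minimum fraction of active electrodes that must
#'   fire during the burst.
#' @param kernel_sd_ms Gaussian smoothing width for fragment detection.
#' @return Tibble with one row per network burst: `start`, `stop`
#'   (seconds), `duration`, `n_spikes` (spikes inside the window),
#'   `n_fragments`, `n_electrodes` (participating electrodes).
#' @export
detect_bursts <- function(raster, bin_ms = 25, start_frac = 1 / 4,
                          stop_frac = 1 / 50, sustain_ms = 50,
                          active_rate_hz = 0.02, participation = 0.5,
                          kernel_sd_ms = 50) {
  empty <- tibble::tibble(start = numeric(0), stop = numeric(0),
                          duration = numeric(0), n_spikes = integer(0),
                          n_fragments = integer(0),
                          n_electrodes = integer(0))
  if (!nrow(raster)) return(empty)
  rate <- network_rate(raster, bin_ms)
  if (rate$max_rate == 0) return(empty)
  duration <- rate$duration

  counts <- rate$counts
  th_start <- start_frac * rate$max_rate
  th_stop <- stop_frac * rate$max_rate
  k <- max(1L, round(sustain_ms / bin_ms))   # consecutive bins required

  # active electrodes over the whole recording
  per_elec <- table(factor(raster$electrode,
                           levels = seq_len(raster_n_electrodes(raster)) - 1L))
  active <- as.integer(names(per_elec))[as.numeric(per_elec) / duration >
                                          active_rate_hz]
  n_active <- length(active)
  if (n_active == 0) return(empty)

  above_start <- counts >= th_start
  below_stop <- counts < th_stop
  run_start <- runs_of_length(above_start, k)   # bins opening a burst
  run_stop <- runs_of_length(below_stop, k)

  in_burst <- FALSE
  starts <- integer(0); stops <- integer(0)
  i <- 1L
  n_bins <- length(counts)
  while (i <= n_bins) {
    if (!in_burst && run_start[i]) {
      in_burst <- TRUE
      starts <- c(starts, i)
      i <- i + k
    } else if (in_burst && run_stop[i]) {
      in_burst <- FALSE
      stops <- c(stops, i - 1L)
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  if (in_burst) stops <- c(stops, n_bins)
  if (!length(starts)) return(empty)

  start_s <- (starts - 1L) * bin_ms / 1000
  stop_s <- pmin(stops * bin_ms / 1000, duration)

  sm <- smooth_rate(counts, bin_ms, kernel_sd_ms)
  keep <- logical(length(starts))
  n_spk <- integer(length(starts))
  n_frag <- integer(length(starts))
  n_part <- integer(length(starts))
  el <- raster$electrode; tt <- raster$time_s
  for (j in seq_along(starts)) {
    inwin <- tt >= start_s[j] & tt <= stop_s[j]
    part <- length(intersect(unique(el[inwin]), active))
    keep[j] <- part >= participation * n_active
    n_spk[j] <- sum(inwin)
    n_part[j] <- part
    n_frag[j] <- count_fragments(sm[starts[j]:stops[j]], rate$max_rate)
  }
  tibble::tibble(start = start_s, stop = stop_s,
                 duration = stop_s - start_s, n_spikes = n_spk,
                 n_fragments = pmax(n_frag, 1L),
                 n_electrodes = n_part)[keep, ]
}

# TRUE at positions where a run of >= k consecutive TRUEs begins (marked
# at every bin of the run's first k-window onset position)
runs_of_length <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(as.integer(x))
  ok <- logical(n)
  if (n >= k) {
    win <- cs[k:n] - c(0, cs)[1:(n - k + 1)]
    ok[seq_len(n - k + 1)] <- win == k
  }
  ok
}

smooth_rate <- function(counts, bin_ms, kernel_sd_ms) {
  if (kernel_sd_ms <= 0) return(as.numeric(counts))
  sd_bins <- kernel_sd_ms / bin_ms
  half <- ceiling(4 * sd_bins)
  kern <- stats::dnorm(seq(-half, half), sd = sd_bins)
  kern <- kern / sum(kern)
  as.numeric(stats::filter(c(rep(0, half), counts, rep(0, half)),
                           kern, sides = 2))[(half + 1):(half + length(counts))]
}

#' Count fragments (sub-peaks) within a network burst
#'
#' Peaks of the Gaussian-smoothed in-burst network firing rate are
#' counted when they reach at least 1/16 of the recording's maximum
#' firing rate and have prominence at least 1/20 of that maximum.
#'
#' @param burst One row of [detect_bursts()] output (or a list with
#'   `start`, `stop` in seconds).
#' @param rate A `mea_rate` from [network_rate()].
#' @param kernel_sd_ms Gaussian smoothing width (ms).
#' @param height_frac,prominence_frac Peak height and prominence rules
#'   as fractions of the maximum firing rate.
#' @return Integer fragment count (>= 1 for any non-empty burst window).
#' @export
detect_fragments <- function(burst, rate, kernel_sd_ms = 50,
                             height_frac = 1 / 16,
                             prominence_frac = 1 / 20) {
  sm <- smooth_rate(rate$counts, rate$bin_ms, kernel_sd_ms)
  i0 <- max(1L, floor(burst$start * 1000 / rate$bin_ms) + 1L)
  i1 <- min(length(sm), ceiling(burst$stop * 1000 / rate$bin_ms))
  max(1L, count_fragments(sm[i0:i1], rate$max_rate, height_frac,
                          prominence_frac))
}

# peak count in a smoothed segment under height + prominence rules
count_fragments <- function(seg, max_rate, height_frac = 1 / 16,
                            prominence_frac = 1 / 20) {
  n <- length(seg)
  if (n < 3) return(as.integer(n > 0 && any(seg >= max_rate * height_frac)))
  is_peak <- which(seg[2:(n - 1)] > seg[1:(n - 2)] &
                     seg[2:(n - 1)] >= seg[3:n]) + 1L
  is_peak <- is_peak[seg[is_peak] >= max_rate * height_frac]
  if (!length(is_peak)) return(0L)
  prom <- vapply(is_peak, function(p) peak_prominence(seg, p), numeric(1))
  sum(prom >= max_rate * prominence_frac)
}

# topographic prominence of peak at index p within segment
peak_prominence <- function(seg, p) {
  h <- seg[p]
  left <- seg[seq_len(p - 1)]
  right <- seg[seq(p + 1, length(seg))]
  hl <- higher_valley(rev(left), h)
  hr <- higher_valley(right, h)
  h - max(hl, hr, min(seg))
}

# lowest point before the first sample exceeding h (Inf-side base rule)
higher_valley <- function(side, h) {
  if (!length(side)) return(-Inf)
  ex <- which(side > h)
  if (length(ex)) min(side[seq_len(ex[1] - 1)], h) else min(side)
}

#' Continuous inter-spike-interval time series per electrode
#'
#' For every time point between an electrode's first and last spike, the
#' instantaneous ISI is the time between the previous and the next
#' spike. The series is sampled piecewise-constant on the rate grid.
#'
#' @param raster A `mea_raster`.
#' @param bin_ms Sampling grid (ms), matching the rate bins.
#' @return A list with `grid` (bin-center times, s) and `isi` (matrix,
#'   time x electrode, `NA` outside an electrode's first/last spike;
#'   electrodes with fewer than 2 spikes are all-`NA` and listed in
#'   `excluded`).
#' @export
isi_series <- function(raster, bin_ms = 25) {
  duration <- raster_duration(raster)
  n_el <- raster_n_electrodes(raster)
  n_bins <- ceiling(duration * 1000 / bin_ms)
  grid <- (seq_len(n_bins) - 0.5) * bin_ms / 1000
  isi <- matrix(NA_real_, nrow = n_bins, ncol = n_el)
  excluded <- integer(0)
  for (e in seq_len(n_el) - 1L) {
    st <- raster$time_s[raster$electrode == e]
    if (length(st) < 2) {
      excluded <- c(excluded, e)
      next
    }
    inside <- grid >= st[1] & grid < st[length(st)]
    k <- findInterval(grid[inside], st)
    isi[inside, e + 1L] <- st[k + 1L] - st[k]
  }
  list(grid = grid, isi = isi, excluded = excluded)
}

#' ISI-distance between two spike trains
#'
#' Time-resolved dissimilarity of two spike trains from the ratio of
#' their instantaneous inter-spike intervals (Kreuz-style): at each time
#' `t` in the common support, with intervals `Ia`, `Ib`,
#' `I(t) = Ia/Ib - 1` if `Ia <= Ib`, else `-(Ib/Ia - 1)`; the distance
#' is the time average of `|I(t)|`. Zero iff the instantaneous ISIs
#' agree everywhere; symmetric in the two trains.
#'
#' @param a,b Sorted spike-time vectors (s), each with >= 2 spikes.
#' @param dt_s Evaluation grid step (s).
#' @return The average dissimilarity (>= 0), or `NA` if the trains do
#'   not overlap.
#' @export
isi_distance <- function(a, b, dt_s = 0.001) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both spike trains need at least 2 spikes")
  }
  lo <- max(a[1], b[1])
  hi <- min(a[length(a)], b[length(b)])
  if (hi <= lo) return(NA_real_)
  tt <- seq(lo, hi - dt_s / 2, by = dt_s)
  ia <- inst_isi(a, tt)
  ib <- inst_isi(b, tt)
  r <- ifelse(ia <= ib, ia / ib - 1, -(ib / ia - 1))
  mean(abs(r))
}

inst_isi <- function(train, tt) {
  k <- findInterval(tt, train, left.open = FALSE)
  k <- pmin(pmax(k, 1L), length(train) - 1L)
  train[k + 1L] - train[k]
}

#' Maximum autocorrelation component of the network firing rate
#'
#' The maximum of the mean-removed, variance-normalized autocorrelation
#' of the binned network rate over lags between `min_lag_s` and half the
#' recording, clamped below at zero. A burst-detection-free measure of
#' rhythmicity.
#'
#' @param rate A `mea_rate`.
#' @param min_lag_s Smallest lag considered (default 0.1 s).
#' @return Value in `[0, 1]`; 0 for a constant (zero-variance) rate.
#' @export
mac <- function(rate, min_lag_s = 0.1) {
  x <- rate$counts
  if (length(x) < 4 || stats::var(x) == 0) return(0)
  max_lag <- floor(length(x) / 2)
  min_lag <- max(1L, round(min_lag_s * 1000 / rate$bin_ms))
  if (min_lag > max_lag) return(0)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[-1]
  max(0, max(ac[min_lag:max_lag]))
}

#' Mean and sd of pairwise correlations between binarized spike trains
#'
#' Each electrode's spike train is binarized on the 25 ms grid (any
#' spike in bin = 1) and Pearson correlations are computed over all
#' electrode pairs; zero-variance trains are excluded.
#'
#' @param raster A `mea_raster`.
#' @param bin_ms Bin width (ms).
#' @return List with `mean`, `sd` (0 when fewer than 2 usable
#'   electrodes / pairs) and `n_pairs`.
#' @export
binarized_cc <- function(raster, bin_ms = 25) {
  duration <- raster_duration(raster)
  n_el <- raster_n_electrodes(raster)
  n_bins <- ceiling(duration * 1000 / bin_ms)
  bins <- matrix(0L, nrow = n_bins, ncol = n_el)
  idx <- pmin(floor(raster$time_s * 1000 / bin_ms) + 1L, n_bins)
  for (e in seq_len(n_el) - 1L) {
    bins[unique(idx[raster$electrode == e]), e + 1L] <- 1L
  }
  usable <- which(apply(bins, 2, stats::var) > 0)
  if (length(usable) < 2) return(list(mean = 0, sd = 0, n_pairs = 0L))
  cc <- stats::cor(bins[, usable])
  vals <- cc[upper.tri(cc)]
  list(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n_pairs = length(vals))
}

#' Names of the MEA summary features in canonical order
#' @param include_bin_cc Include the two binarized-correlation features.
#' @return Character vector.
#' @export
feature_names <- function(include_bin_cc = TRUE) {
  nm <- c("MFR", "NBR", "NBD", "PSIB", "n_FBs", "CV_IBI",
          "mean_ISI_CC", "sd_ISI_CC", "ISI_dist", "mean_ISI",
          "sd_ISI_temp", "sd_ISI_elec", "MAC")
  if (include_bin_cc) nm <- c(nm, "mean_binCC", "sd_binCC")
  nm
}

#' Compute the MEA summary-statistic vector of a spike raster
#'
#' The thirteen features used to train the posterior estimator, plus the
#' two optional binarized-correlation features: mean firing rate (MFR,
#' Hz), network-burst rate (NBR, per min), mean network-burst duration
#' (NBD, s), percentage of spikes in bursts (PSIB, %), mean fragments
#' per burst (n_FBs), coefficient of variation of inter-burst intervals
#' (CV_IBI), mean/sd of pairwise Pearson correlations between ISI time
#' series, mean pairwise ISI-distance, mean instantaneous ISI and its
#' temporal and across-electrode standard deviations (s), and the
#' maximum autocorrelation component (MAC).
#'
#' Degenerate rasters follow fixed conventions and never produce
#' non-finite values: with no bursts, NBD = PSIB = n_FBs = CV_IBI = 0
#' (CV_IBI also 0 with fewer than 3 bursts); ISI statistics are 0 when
#' fewer than 2 spikes/electrodes are available; MAC is 0 for a
#' zero-variance rate. Identical code handles simulated and recorded
#' rasters.
#'
#' @param raster A `mea_raster` or `mea_sim` (its raster is used).
#' @param bin_ms Analysis bin width (ms).
#' @param include_bin_cc Include `mean_binCC`/`sd_binCC` columns.
#' @param isi_dist_step Grid step (s) for the ISI-distance integral.
#' @return A one-row tibble with the feature columns of
#'   [feature_names()].
#' @export
compute_features <- function(raster, bin_ms = 25, include_bin_cc = TRUE,
                             isi_dist_step = 0.005) {
  if (inherits(raster, "mea_sim")) raster <- raster$raster
  duration <- raster_duration(raster)
  n_el <- raster_n_electrodes(raster)
  rate <- network_rate(raster, bin_ms)
  bursts <- detect_bursts(raster, bin_ms)

  mfr <- nrow(raster) / n_el / duration
  nbr <- nrow(bursts) / duration * 60
  nbd <- if (nrow(bursts)) mean(bursts$duration) else 0
  psib <- if (nrow(bursts) && nrow(raster)) {
    100 * sum(bursts$n_spikes) / nrow(raster)
  } else 0
  n_fbs <- if (nrow(bursts)) mean(bursts$n_fragments) else 0
  cv_ibi <- if (nrow(bursts) >= 3) {
    ibi <- diff(bursts$start)
    if (mean(ibi) > 0) stats::sd(ibi) / mean(ibi) else 0
  } else 0

  iss <- isi_series(raster, bin_ms)
  have <- which(colSums(!is.na(iss$isi)) > 0)
  if (length(have)) {
    elec_mean <- colMeans(iss$isi[, have, drop = FALSE], na.rm = TRUE)
    time_mean <- rowMeans(iss$isi[, have, drop = FALSE], na.rm = TRUE)
    mean_isi <- mean(iss$isi[, have], na.rm = TRUE)
    sd_isi_temp <- if (sum(is.finite(time_mean)) > 1) {
      stats::sd(time_mean[is.finite(time_mean)])
    } else 0
    sd_isi_elec <- if (length(elec_mean) > 1) stats::sd(elec_mean) else 0
  } else {
    mean_isi <- 0; sd_isi_temp <- 0; sd_isi_elec <- 0
  }

  # pairwise Pearson CC of ISI series on overlapping support
  ccs <- numeric(0)
  if (length(have) >= 2) {
    for (i in seq_along(have)[-length(have)]) {
      for (j in seq((i + 1), length(have))) {
        a <- iss$isi[, have[i]]; b <- iss$isi[, have[j]]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) >= 3 && stats::var(a[ok]) > 0 && stats::var(b[ok]) > 0) {
          ccs <- c(ccs, stats::cor(a[ok], b[ok]))
        }
      }
    }
  }
  mean_cc <- if (length(ccs)) mean(ccs) else 0
  sd_cc <- if (length(ccs) > 1) stats::sd(ccs) else 0

  # mean pairwise ISI-distance over electrodes with >= 2 spikes
  trains <- lapply(seq_len(n_el) - 1L, function(e) {
    raster$time_s[raster$electrode == e]
  })
  good <- which(vapply(trains, length, integer(1)) >= 2)
  dists <- numeric(0)
  if (length(good) >= 2) {
    for (i in seq_along(good)[-length(good)]) {
      for (j in seq((i + 1), length(good))) {
        d <- isi_distance(trains[[good[i]]], trains[[good[j]]],
                          dt_s = isi_dist_step)
        if (is.finite(d)) dists <- c(dists, d)
      }
    }
  }
  isi_dist <- if (length(dists)) mean(dists) else 0

  out <- tibble::tibble(
    MFR = mfr, NBR = nbr, NBD = nbd, PSIB = psib, n_FBs = n_fbs,
    CV_IBI = cv_ibi, mean_ISI_CC = mean_cc, sd_ISI_CC = sd_cc,
    ISI_dist = isi_dist, mean_ISI = mean_isi, sd_ISI_temp = sd_isi_temp,
    sd_ISI_elec = sd_isi_elec, MAC = mac(rate)
  )
  if (include_bin_cc) {
    bc <- binarized_cc(raster, bin_ms)
    out$mean_binCC <- bc$mean
    out$sd_binCC <- bc$sd
  }
  stopifnot(all(vapply(out, is.finite, logical(1))))
  out
}

#' Compute features for a list of rasters or simulations
#'
#' @param rasters List of `mea_raster`/`mea_sim` objects.
#' @param ... Passed to [compute_features()].
#' @return Tibble with one row per recording, in input order.
#' @export
compute_features_batch <- function(rasters, ...) {
  dplyr::bind_rows(lapply(rasters, compute_features, ...))
}
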