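---
title: "Inferring network biophysics from MEA activity: model, features, and amortized posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring network biophysics from MEA activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Cultured networks of human excitatory neurons on multi-electrode arrays
(MEAs) show rich spontaneous dynamics — irregular spiking, synchronous
network bursts, burst fragments — and these patterns shift with drugs,
genome edits and disease. `measbi` links such recordings back to
biophysics: a mechanistic network model simulates activity for any
parameter choice, a summary-statistic layer reduces a recording to 13
MEA features, and a conditional density estimator trained on prior
simulations returns, for any observed feature vector, the full
posterior over the model's ten free parameters. This vignette documents
the model, the numerical choices, and what the included tests do and do
not establish.

## The network model

One hundred single-compartment Hodgkin-Huxley neurons sit on a square
grid. Each neuron carries transient Na\eqn{^+} (m³h) and
delayed-rectifier K\eqn{^+} (n⁴) currents with Traub–Miles-style rate
functions parameterized by a threshold-shift potential
\(V_T = -30.4\) mV, a leak (reversal \(-39.2\) mV), and a slow
after-hyperpolarization (sAHP) conductance that increments by
\(\alpha_{Ca}\) at every spike and decays with \(\tau_{AHP} = 6\) s —
the slow brake that terminates and spaces network bursts. Conductance
densities are converted to absolute conductances through the membrane
area (300 µm²), so channel, synaptic (nS) and sAHP conductances enter
one current balance; integration uses exponential Euler for the
membrane and gating variables (dt = 0.05 ms by default, 0.1 ms in the
reduced test model) with gating rates tabulated on a 0.02 mV grid.
Spikes are upward crossings of 0 mV with a 2 ms dead time.

Excitability is heterogeneous: each neuron draws a constant input
current once per topology from Normal(5, 2) pA. The scale was fixed
once against the measured rheobase of the isolated model neuron
(≈ 11–12 pA for mid-prior conductances), placing essentially all
neurons below threshold: spontaneous activity is then driven by the
membrane noise — an Ornstein–Uhlenbeck voltage perturbation with 5 ms
correlation time and stationary standard deviation `noise_sd`, whose
increments are added to the membrane potential — and amplified by the
recurrent synapses. At the low end of the noise prior an unconnected
network is essentially silent; at the high end isolated neurons fire at
several Hz.

Synapses are conductance-based AMPA (2 ms decay) and NMDA
(2 ms rise / 100 ms decay, Jahr–Stevens magnesium block at 1 mM)
receptors. Each ordered neuron pair connects with probability
`conn_p`; weights are lognormal with mean 1 and coefficient of
variation 0.7 (positivity guaranteed), and conduction delays grow with
grid distance up to 25 ms. Release is governed by Tsodyks–Markram
short-term depression: a presynaptic spike releases a fraction
\(U\cdot x\) of the resource \(x\), which then recovers with timescale
\(\tau_D\). Asynchronous release follows the Wang-style extension: a
residual variable gains `U_asyn` per spike (ceiling \(U_{max} = 0.5\)
ms⁻¹), decays with 700 ms, and drives a Poisson stream of
single-vesicle events each releasing \(U\cdot x/x_0\) with
\(x_0 = 5\) vesicles per release site. The biophysical description
leaves the unit of an asynchronous event open; the single-vesicle
quantum convention was fixed after observing that scaling evoked
release by \(x_0\) drives the network into saturated tonic firing
(~190 Hz) with no bursting anywhere near the mid-prior — the
single-vesicle convention restores the burst-and-recover dynamics the
model is meant to produce.

Twelve virtual electrodes form a 4 × 3 interior grid (the corner-free
layout of a 12-electrode MEA well); every neuron reports to its nearest
electrode, and all downstream analysis sees only the electrode raster.

The ten free parameters and their uniform prior ranges are in
`prior_ranges()`; everything else is fixed in `fixed_params()`.
Separate random streams drive topology, initial conditions, membrane
noise, and asynchronous events, so a fixed topology can be reused while
noise varies, and a `(params, seed, dt, duration)` tuple reproduces a
raster bit for bit.

## Features

`compute_features()` reduces a raster to the 13 summary statistics used
for training (plus two optional binarized-correlation features):

* **Rate and bursts.** The network firing rate is the 25 ms-binned
  spike count over all electrodes. A network burst opens when the rate
  holds at ≥ 1/4 of its maximum for 50 ms, closes when it holds below
  1/50 of the maximum for 50 ms, and counts only if at least half of
  the active electrodes (mean rate > 0.02 Hz) spike inside it. From
  this: burst rate (NBR, min⁻¹), mean duration (NBD, s), percentage of
  spikes in bursts (PSIB), fragments per burst (peaks of the 50 ms
  Gaussian-smoothed in-burst rate with height ≥ max/16 and prominence
  ≥ max/20), and the CV of inter-burst (onset-to-onset) intervals.
* **ISI structure.** Each electrode's instantaneous inter-spike
  interval series (time between previous and next spike, sampled on
  the 25 ms grid between first and last spike) yields the mean ISI,
  its temporal and across-electrode standard deviations, the mean and
  sd of pairwise Pearson correlations between ISI series (computed on
  overlapping support; constant pairs excluded), and the mean pairwise
  ISI-distance (time-averaged |ISI ratio − 1| dissimilarity).
* **MAC.** The maximum of the normalized autocorrelation of the
  network rate over lags from 0.1 s to half the recording — an
  oscillation measure that does not depend on burst detection. The lag
  window is a documented choice; zero-variance rates score 0.

Degenerate recordings never produce non-finite features: silent or
burst-free rasters report zeros for the burst block (CV also zero with
fewer than three bursts), and correlation statistics fall back to zero
when fewer than two usable electrodes exist. These conventions keep
silent prior simulations in the training set, so the estimator learns
that silence is what large swaths of parameter space produce.
Simulated and loaded rasters go through literally the same code path.

The raw-signal path (`bandpass()`, 5th-order Butterworth 100–3500 Hz
applied forward-backward so spike times carry no group delay;
`detect_spikes()`, |signal| > 4 × whole-trace RMS with a 2 ms dead time
and extremum timing, both polarities) is exercised against synthetic
extracellular traces (`synth_extracellular()`): templates at known
times plus white noise. The fixture sizes used in tests (e.g. 200
spikes at 10× noise over 20 s) were chosen from the Gaussian crossing
statistics so that the expected false-positive count stays well below
the 5% precision budget.

## Amortized posterior estimation

With a uniform prior, the conditional density \(q(\theta\mid x)\)
fitted to prior simulations is the posterior. The estimator is a
conditional masked autoregressive flow written in plain R: a stack of
MADE blocks (default 5 transforms, 50 hidden units) whose shift and
log-scale for each coordinate depend on earlier coordinates and the
feature vector, with a standard-normal base, soft-clamped log-scales
(|α| ≤ 4), and reversed coordinate order between blocks. Training
minimizes negative log-likelihood with Adam (batch 200, learning rate
10⁻³) and early stopping on a 10% validation split; gradients are
hand-derived backpropagation through the masked layers, and a
finite-difference check of those gradients is part of the development
history. Parameters are logit-mapped to the prior box before entering
the flow, so posterior samples are inside the box by construction;
features are z-scored with training-set statistics (the same
convention used to normalize displayed features by prior sd).
Observations further than 10 training sd from the training mean
trigger a misspecification warning rather than a failure.

Evaluation is amortized: `posterior_for()` standardizes the
observation and returns a handle; sampling, log-density, the joint
mode (best-of-10⁴ samples plus BFGS refinement in the unbounded
space), gridded 1-D/2-D conditionals, conditional correlation
matrices (50 conditioning draws × 50 points per pair, one-sample
t-test against zero with a Shapiro–Wilk normality screen),
active-subspace sensitivity scores (eigen-decomposition of the outer
product of range-scaled log-density gradients), posterior-predictive
checks (kernel densities on 1000 samples; every univariate and
pairwise marginal must put the ground truth above 50% of its maximum
density; Scott-rule bandwidths, on which the criterion mildly
depends), and the parameter recovery error (mean absolute marginal
deviation from truth, normalized by prior range — 0.25 for a
prior-wide uniform marginal with a central truth, 0.5 at an edge) all
operate on the handle without retraining.

The comparison layer mirrors how conditions are analyzed: per-network
two-sample Kolmogorov–Smirnov tests on 50 + 50 marginal samples with a
median-difference direction (raw p-values by default; Holm correction
optional), Mann–Whitney feature comparisons, per-line-per-MEA feature
averaging, and a hard guard that refuses to compare posteriors from
different MEA batches unless explicitly overridden — cross-batch
comparisons confound culture-batch variability with the effect of
interest.

## Scaled-down study sizes

The full-scale protocol (300,000 three-minute simulations of 100
neurons) is a cluster-scale computation. The package's tests and the
acceptance script instead run a reduced study sized for a single CPU:
a 5-parameter sub-prior (`noise_sd`, `g_AMPA`, `conn_p`, `tau_D`,
`U_std` — the parameters with the most direct pathways to activity;
the others clamped at prior midpoints), 600 prior simulations of a
30-neuron network for 30 s at dt = 0.1 ms, a 5 × 50 flow, and 10
held-out ground truths for posterior-predictive checking. These sizes
were fixed once when the study was designed. At this scale the
posterior is broader than a cluster-scale one, so the meaningful
checks are relative: recovery error for the well-identified
parameters beats the uniform-prior baseline, conditionals are
narrower than marginals, and the binarized-CC features remain
strongly correlated with the ISI-CC features ("strongly positive",
r > 0.6, a bar set before the study was run).

Analytic components are checked against oracles rather than scale:
the depression fixed point \((1-e^{-T/\tau_D})/(1-(1-U)e^{-T/\tau_D})\)
to 10⁻⁸, ISI-distance values on periodic constructions (0 and 0.5),
filter/detector behavior against crossing statistics, the toy
simulator \(x = \theta + \varepsilon\) with its truncated-Gaussian
posterior (posterior mean within 0.03, sd within 30%),
simulation-based calibration rank uniformity, the \(\sqrt{1-\rho^2}\)
conditional-narrowing factor on a correlated Gaussian, and the
uniform-marginal recovery-error values 1/4 and 1/2.

## What the synthetic data does not show

The generator emulates the statistical structure of MEA recordings —
burst timing, participation, ISI correlations — but not spike-sorting
artifacts, electrode drift, culture-to-culture variability beyond the
modeled parameters, inhibitory interneurons or astrocyte dynamics
(absent from the modeled preparation), or vendor acquisition formats.
Passing tests therefore establish that the inference machinery
recovers parameters *of this model from this model's output* at
reduced scale; they do not validate the biological fidelity of the
model itself, which rests on the experimental literature the model
derives from. Posteriors for strongly misspecified observations are
flagged only through the feature-range warning.

## Known limitations

* The reduced-scale flow is trained on 600 points; its posteriors are
  diffuse, and weakly identified parameters (`tau_D`, `U_std`) often
  show near-prior marginals.
* The 50%-of-maximum posterior-predictive criterion is intrinsically
  harsh for the reduced model. For a *calibrated* unimodal posterior,
  the ground truth lands inside the ≥ 50%-of-max region of a 2-D
  Gaussian marginal with probability exactly
  \(P(\chi^2_2 \le 2\ln 2) = 0.5\), so requiring all univariate and
  pairwise marginals to pass simultaneously has low probability unless
  marginals are flat-topped. The full 10-parameter model has exactly
  such plateaus (compensation ridges make marginals wide), but the
  reduced sub-prior removes those degenerate directions: its marginals
  are peaked, and the reduced-scale pass rate is low even though
  calibration ranks are near-nominal. An under-trained estimator with
  prior-like posteriors would pass the criterion trivially; the
  package reports the honest pass rate instead. Kernel density
  estimates used by the check reflect samples at the prior boundaries,
  the standard correction for box-bounded marginals.
* Burst detection on very sparse tonic rasters can report occasional
  single-bin "bursts" — a property of any max-rate-relative threshold
  rule, shared with the reference procedure.
* The exact Hodgkin-Huxley rate functions, magnesium-block constants
  and input-current distribution are reimplementation choices exposed
  in `fixed_params()`; alternative conventions change quantitative
  simulator output but not the inference contracts.
* Model storage uses R serialization at run time; no portable
  on-disk model format is provided.

## A worked example

```{r example}
library(measbi)

# simulate a recording from known parameters
truth <- complete_params(list(noise_sd = 5, g_AMPA = 0.6, conn_p = 0.4,
                              tau_D = 500, U_std = 0.2))
sim <- simulate_network(truth, fixed_params(dt = 0.1), duration = 30,
                        seed = 1, n_neurons = 30)
compute_features(sim)

# train a reduced estimator and recover the parameters
ts <- make_fixture("reduced-model", n = 600, seed = 101)
model <- train_nde(ts, seed = 7, min_n = 400, batch_size = 100)
post <- posterior_for(compute_features(sim), model)
tidy(post)
posterior_mode(post)
autoplot(post, true_params = unlist(truth[reduced_ranges()$parameter]))
```
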