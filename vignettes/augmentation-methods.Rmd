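---
title: "Synthetic time-series augmentation for fermentation soft sensors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic time-series augmentation for fermentation soft sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Soft sensors infer a hard-to-measure process quality variable — here the
ethanol concentration of a very-high-gravity (VHG) fermentation — in real
time from signals that are cheap to measure online: pH, redox potential,
capacitance and broth temperature. Training such a regression model runs
into two chronic problems of bioprocess data: experiments are few (a
campaign yields on the order of ten cycles), and probes fail — a redox
electrode can go silent for a whole cycle, a capacitance probe can drift
out of calibration and report a consistent bias.

`fermaug` implements, end to end, a strategy for making the soft sensor
robust under exactly these conditions: train a convolutional variational
autoencoder (VAE) on the handful of available experiments, sample a large
pool of synthetic experiments from its latent prior, and train the
regression model on original-plus-synthetic blends. The package then
quantifies — over repeated leave-one-experiment-out splits — whether the
augmented training sets improve the mean and tighten the spread of the
held-out prediction metrics.

Because the underlying laboratory campaign data are not publicly
deposited, the package ships a fermentation simulator that reproduces the
statistical structure the analysis depends on; every stage of the pipeline
is exercised and tested against simulated studies.

## The fermentation simulator

Each simulated cycle integrates a deliberately minimal kinetic model —
Monod growth with linear ethanol inhibition and a substrate-gated
maintenance term:

$$
\frac{dX}{dt} = \mu_{max}\,\frac{S}{K_s+S}\,
  \max\!\left(0,\,1-\frac{P}{P_{max}}\right) X,
\qquad
\frac{dS}{dt} = -\frac{1}{Y_{xs}}\frac{dX}{dt} - m\,\frac{S}{K_s+S}\,X,
\qquad
\frac{dP}{dt} = -Y_{ps}\frac{dS}{dt}
$$

with \(X\) cells, \(S\) substrate and \(P\) ethanol (g/L). No richer
mechanistic detail is warranted: the downstream analysis consumes only the
statistical shape of the trajectories, so the simplest model that produces
sigmoidal ethanol accumulation, matching substrate depletion and modest
biomass growth is the right one. The defaults (`ferm_sim_params()`) were
chosen once so that a noise-free cycle converts about 230 g/L of sugar and
plateaus near 108 g/L ethanol over 10 h — the endpoint regime of the
emulated process — on a 500-point even grid (1-minute-scale sampling).

The probe channels are derived through invented but physically sensible
sensor maps: capacitance is affine in viable cells (dielectric probes
track biomass), redox declines affinely with ethanol, pH drifts slightly
around its control setpoint, and the temperature channel follows the
process's control cascade — setpoints 34, 32, 30, 28 °C with 2 °C drops
triggered as ethanol crosses 30, 60 and 90 g/L (the trigger concentrations
are not documented for the original process; evenly spaced values below
the 108 g/L aeration trigger were fixed once). The maps matter only in
that they make the four probe channels informative about ethanol, which is
what gives the soft sensor something to learn. Micro-aeration at the end
of the run is recorded as a flagged window with no kinetic effect, since
no aeration kinetics are specified anywhere.

Between-experiment variability is modelled by lognormal multipliers (mean
1, CV 5 % by default) applied per cycle to the kinetic constants and
initial conditions, plus additive Gaussian sensor noise per channel.
Cycles are i.i.d. given the multipliers; carry-over effects of the cell
treatment between real cycles are not modelled. Seeds split
hierarchically (study seed → experiment sub-seed), so enlarging a study
never perturbs earlier experiments.

The default study contains 11 cycles and two sensor faults that mirror
the documented probe problems: one experiment with a completely missing
redox channel and one with a +10 pF/cm capacitance offset (an
uncalibrated probe). What the simulator does *not* emulate — spatial
inhomogeneity, autocorrelated sensor drift, the physiological state of
recycled cells — bounds what passing tests can show: they validate the
pipeline's behaviour under the assumed statistical structure, not its
performance on any particular real campaign.

## Preprocessing

The failed redox channel is imputed by K-nearest neighbours over
time-aligned samples pooled across experiments: each incomplete row finds
the `k = 5` complete rows nearest in Euclidean distance over its observed
channels and takes their mean. The method is named for the original
analysis but its configuration is not; pooled time-aligned samples with
uniform weights is the plainest reading, and the unit tests pin the
implementation against an exhaustive nearest-neighbour scan.

Normalization is min–max to [0, 1] per channel, matching the sigmoid
output of the VAE decoder. In evaluation runs the normalizer is fitted on
the training originals only and reused unchanged for the held-out
experiment — no leakage; a consequence is that held-out values can fall
slightly outside [0, 1], which is correct behaviour.

The channel order (pH, redox, capacitance, temperature, ethanol,
substrate, cells) is frozen package-wide and recorded in every artifact.
A `regrid()` operation (linear interpolation onto an even grid) supports
series of other lengths; the canonical shape is 500 × 7.

## The variational autoencoder

The encoder applies five 1-D convolutional layers (ReLU, kernel 5,
stride 1, "same" padding, filter counts 32–32–48–64–64) followed by one
dropout layer (rate 0.2), flattens the resulting 500 × 64 feature map
into a 32,000-vector, and passes two dense layers of 512 and 64 units
before projecting to a 10-dimensional latent mean and log-variance. The
decoder mirrors the process and ends in a sigmoid. Only the layer count,
the final 64-filter map, the dense widths and the latent size are fixed
by the emulated architecture; kernel size, strides, the earlier filter
counts, dropout rate, optimizer and learning rate are undocumented, so
they are package defaults and all are `vae_config()` fields.

Training minimizes the negative evidence lower bound: a summed-squared-
error reconstruction term (the unit-variance Gaussian log-likelihood up
to a constant) plus the closed-form KL divergence of the diagonal
Gaussian posterior to the standard-normal prior, weighted 1 with no
annealing. Losses are recorded per epoch in the minimized convention.
Optimization is full-batch Adam at 1e-3 — with roughly a dozen training
series there is no reason to subsample. The implementation is written in
R with the hot inner operations (fused Adam update, im2col/col2im, tensor
reshaping) in C++ via Rcpp; gradients were verified against finite
differences during development and training is deterministic for a fixed
seed under a single-threaded BLAS.

Generation draws latent vectors from the standard-normal prior, decodes,
and inverse-normalizes; synthetic series are tagged `synthetic` in every
artifact and manifest so they can never silently mix with originals.

One genuinely open protocol question is whether the VAE should be
retrained inside every evaluation split. The package trains it once on
all original experiments and reuses the pool across splits, which is the
natural reading of a three-stage generate-then-evaluate workflow; note
that this means the held-out experiment of any given split contributed to
the generator's training, so the evaluation isolates the regression
model's robustness, not generator generalization.

## The soft sensor and the evaluation protocol

The regression model is a 4-80-60-1 feedforward network (ReLU hidden
layers, linear output) trained on stacked rows of the normalized training
collection by mean-squared error with mini-batch Adam. It is a pointwise
map — the prediction at a timestep uses only that timestep's four probe
values — which the tests assert via row-permutation equivariance.

Evaluation repeats, `n_iter` times: draw one original experiment
uniformly at random as the test set (whole series held out together);
compose the training collection per regime — `Original` (10 original
sets), `Augmented10` (those 10 plus 10 synthetic sampled without
replacement), `Augmented100` (those 10 plus the full synthetic pool);
fit the normalizer on the training originals; train the network; predict
the held-out experiment. Four metrics are recorded per iteration in
normalized target space: the generalized R² (negative when predictions
are worse than the mean), adjusted R² computed with *N equal to the
number of training sets* (10/20/110) and p = 4 predictors — the set count
rather than the row count is what makes the adjustment respond to
augmentation — MAE, and RMSE.

Regime distributions are compared metric-wise: percent change of mean
and standard deviation against the Original baseline, Welch's
unequal-variance t-test on means, Levene's mean-centred test on
variances, significance flagged at p < 0.05 with no multiple-testing
correction (none is used in the emulated protocol). The MAE definition
applies the absolute value; a signed mean error would cancel to ≈ 0 and
could not produce the reported positive values.

## Problem sizes used by the tests and the acceptance script

The shipped acceptance runs use a scaled-down study chosen as a sensible
desk-scale workload: 11 simulated experiments on the full 500-point grid,
a 30-epoch VAE (the loss curve has visibly flattened by then on this
data), a synthetic pool of 40, 20 repeated splits per regime, and an FNN
configuration of 40 epochs, batch 512, learning rate 3e-3 — settings at
which the network reaches held-out R² ≈ 0.98 on clean simulated test
experiments, so further epochs buy nothing. At this scale the directional
conclusions are reproduced: augmented regimes raise mean held-out R²,
shrink its standard deviation, and rescue the anomalous-capacitance test
case; the 20-iteration distributions are too small for the Welch and
Levene p-values to reach significance reliably, and no test asserts that
they do. The fidelity diagnostics (histogram overlap against a
uniform-noise baseline) are evaluated with the VAE trained at its default
100 epochs — the epoch selection the loss curve motivates — because
channels whose trajectories ramp nearly linearly in time have close to
uniform marginals, making uniform noise a deceptively strong baseline
that an under-trained 30-epoch decoder only ties. The headline magnitudes of the original campaign depend on the
unavailable laboratory data and are not reproduction targets; what the
package reproduces exactly is the derived-column arithmetic of the
reported comparison table.

## Numerical choices and degenerate inputs

* ODE integration uses `deSolve::ode` (lsoda, rtol = atol = 1e-8); the
  kinetic core clamps the tiny negative excursions an adaptive solver may
  probe, and the public `kinetic_rhs()` rejects negative states outright.
* Ethanol-yield conservation \(Y_{ps}(S_0 - S) = P - P_0\) holds to
  1e-6 · S0 in noise-free runs and is tested.
* Constant channels make min–max or z-score normalization ill-defined and
  are rejected by name. Imputation requires at least one fully observed
  sample and errors if `k` exceeds the number of complete samples.
* The latent heads are initialised at small scale so an untrained
  posterior starts near the prior; zeroed heads give exactly
  `mu = logvar = 0`.
* Welch's test with two zero-variance samples is degenerate: equal means
  return t = 0, p = 1, unequal means are an error. Levene's statistic is
  0 with p = 1 when the absolute deviations are constant.
* t-SNE (no R implementation of it is available to depend on, so the
  package carries a compact exact O(n²) implementation suitable for the
  ~100-point embeddings it draws) uses perplexity 10 by default, binary
  search for per-point precisions, early exaggeration for the first 100
  of 500 gradient-descent iterations.

## Known limitations

* Simulated cycles are smoother and more mutually similar than real
  campaign data; absolute metric values on simulation are optimistic.
* The VAE's reconstruction-dominated objective (3,500-dimensional SSE
  against a 10-dimensional KL) means prior samples decode to
  conservative, interpolation-like series; this suffices for the
  augmentation mechanism studied here but underrepresents tail
  behaviour.
* Determinism is guaranteed under a single-threaded BLAS; multi-threaded
  BLAS reductions may differ in the last bits, in which case only
  statistical reproducibility is promised.
* The anomalous-case score depends on a single held-out experiment and a
  single training run per regime; it is a demonstration, not a
  distribution.
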