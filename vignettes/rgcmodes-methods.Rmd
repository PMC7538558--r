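---
title: "Latent-state analysis of retinal population activity: models and methods"
author: "rgcmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-state analysis of retinal population activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcmodes)
```

# Overview

`rgcmodes` implements an unsupervised analysis of retinal ganglion cell
(RGC) population activity recorded on a high-density 64x64 multi-electrode
array (MEA). The pipeline is:

1. **Rate inference.** Spike trains are converted to smooth firing rates by
   MAP estimation under a log-Gaussian Cox process (LGCP).
2. **Neuron selection.** Silent and tonically firing neurons -- whose rate
   derivative spans less than a fixed range -- are removed, since a
   (near-)constant rate carries no stimulus information.
3. **Latent-variable modeling.** The joint distribution of the standardized
   population rate vector is modeled with energy-based models: a
   Gaussian-visible restricted Boltzmann machine (RBM), a mean-covariance
   RBM (mcRBM), or -- for temporal structure -- a conditional RBM (cRBM),
   all trained by contrastive divergence (CD).
4. **Mode visualization.** Each binary latent state (or single unit) is
   interpreted by averaging the stimulus frames associated with the samples
   that activate it, a spike-triggered-average (STA) idea lifted to latent
   states; cRBMs get a slot-wise temporal variant that preserves history
   order.
5. **Evaluation.** The association between stimuli and latent states is
   quantified by the plug-in mutual information normalized by the stimulus
   entropy (NMI, in [0, 1]), against a shuffled-label permutation null.

Because public MEA recordings of this kind are not available, the package
ships a synthetic retina simulator that generates stimuli and spike trains
with the statistical structure the analysis assumes. All tests and the
bundled acceptance script run exclusively on this simulator.

# Models

## Energy-based latent models

For binary visibles the RBM energy is
$E(\mathbf v,\mathbf h) = -\mathbf a^\top\mathbf v - \mathbf b^\top\mathbf h
- \mathbf v^\top W \mathbf h$, and $P(\mathbf v,\mathbf h)\propto e^{-E}$.
Real-valued firing rates use linear visible units with independent unit
Gaussian noise,
$E = \tfrac12\lVert\mathbf v-\mathbf a\rVert^2 - \mathbf b^\top\mathbf h -
\mathbf v^\top W\mathbf h$; standardization upstream enforces the unit
noise scale. Conditionals factorize: hidden units are independent logistics
given $\mathbf v$, visibles are independent unit Gaussians (or logistics)
given $\mathbf h$.

The **mcRBM** splits the latent layer into *mean* units, which shift the
conditional mean exactly as in the Gaussian RBM, and *precision* units,
which gate the conditional covariance through factor loadings $C$ and a
nonpositive pooling matrix $P$:
$$E(\mathbf v, \mathbf h^m, \mathbf h^c) =
  \tfrac12\lVert\mathbf v-\mathbf a\rVert^2
  - \mathbf b_m^\top \mathbf h^m - \mathbf v^\top W \mathbf h^m
  - \tfrac12\sum_k h^c_k \sum_f P_{fk} (C_{\cdot f}^\top \mathbf v)^2
  - \mathbf b_c^\top \mathbf h^c.$$
With $P \le 0$, each active precision unit adds positive-semidefinite
curvature $C\,\mathrm{diag}(-P\mathbf h^c)\,C^\top$ to the visible
precision, so conditioned on the latents the visibles are *exactly*
Gaussian with precision $I + C\,\mathrm{diag}(s)\,C^\top$ and every binary
latent vector indexes one Gaussian mode of the rate distribution. Some
published variants length-normalize $\mathbf v$ inside the covariance term;
this implementation keeps the raw $\mathbf v$ because that choice keeps the
conditional Gaussian exact and the joint density proper (the energy grows
quadratically in every direction), at the cost of making the covariance
gating scale-sensitive -- acceptable here because inputs are standardized.
After every update $P$ is projected back onto the nonpositive orthant.

The **cRBM** conditions a Gaussian RBM on `order` delayed copies of the
visible vector spaced `spacing` bins apart. Autoregressive weights $A_k$
and history-to-hidden weights $B_k$ act purely as *dynamic biases*
($\hat{\mathbf a} = \mathbf a + \sum_k A_k \mathbf v_{t-k\cdot s}$,
$\hat{\mathbf b} = \mathbf b + \sum_k B_k^\top \mathbf v_{t-k\cdot s}$), so
CD training carries over unchanged with two extra gradient blocks. For
drifting gratings the spacing is anchored by the *counterphase rule*: the
most delayed layer must see activity half a stimulus period back,
`order * spacing * bin_width = period / 2`. With 12 layers this is only
satisfiable when the half period is a multiple of 12 bins, which is why the
temporal-mode experiment samples at 24 Hz (half period of a 1 Hz grating =
12 bins, spacing 1); at 30 Hz the rule has no integer solution and the
package refuses with the nearest feasible spacing.

## Training

CD-k with momentum and weight decay; defaults (`train_config()`):
learning rate `1e-3`, momentum 0.9, weight decay `1e-4`, batch 64, k = 1,
and layer sizes 16 mean units / 64 factors / 16 precision units. The
experiment replicas raise the learning rate to `1e-2` and use 30-40 epochs
so training converges within their problem sizes; all settings are recorded
in each run's configuration hash. The mcRBM negative phase defaults to one
hybrid Monte Carlo (HMC) trajectory per update on the marginal free energy
(latents integrated out; 20 leapfrog steps, step size adapted toward 90%
acceptance), with blocked Gibbs through the exact conditionals available as
an alternative; both are exercised by the tests. Training aborts, keeping
the last stable checkpoint, if the reconstruction error or free energy
diverges.

Every conditional, the free energy, its gradient, and the CD update
direction are validated against brute-force enumeration oracles on models
small enough to enumerate (<= 12 units, partition function by exhaustive
summation; Gaussian visibles integrated analytically per hidden
configuration).

## LGCP rate inference

Counts in bins of one stimulus frame (1/30 s by default) are modeled as
Poisson with intensity $\exp(g_b)$, $g \sim \mathcal{GP}(m, k)$ with a
squared-exponential kernel (defaults: lengthscale 0.25 s, variance 1, $m$
set per neuron to the log empirical mean rate). The MAP is found by a
damped Newton (Laplace) iteration in the stable
$B = I + W^{1/2} K W^{1/2}$ parameterization, with backtracking on the
penalized likelihood. Long recordings are fit in chunks of 400 bins with
60-bin overlaps and stitched on chunk interiors; at the default lengthscale
the overlap is several correlation lengths, and chunked fits agree with
whole-series fits to ~1e-4 relative error (tested). Non-convergence of any
neuron is an error; no partial output is returned.

A practical note on accuracy: at single-train intensities of a few Hz, each
time point effectively sees only a handful of spikes within one correlation
length, so the posterior standard deviation of the log-rate is ~0.6 and the
pointwise RMSE of *any* estimator smoothing at that scale is a few Hz. The
package's LGCP benchmark (sinusoid 5 + 4 sin(2 pi t) Hz, 30 s) sits at
~2.9 Hz median RMSE, which is at that statistical floor: fits converge to
the truth as counts grow (tested at 20x intensity).

## Mutual-information evaluation

Stimulus labels (orientation x phase bin for gratings, trajectory index for
natural scans) and latent state identities are compared by the plug-in MI
in bits (base 2; the normalization by stimulus entropy makes the NMI
base-invariant). The estimator is intentionally uncorrected; instead every
comparison carries a shuffled-label permutation null (or its fixed-margin
contingency-table equivalent) so finite-sample bias is visible rather than
hidden.

One estimator property matters for study design: when the latent state has
many bits, almost every sample gets a unique state and the plug-in MI
saturates at the stimulus entropy *regardless of the true association* --
the permutation null saturates with it. Condition comparisons therefore use
a compact latent space (4 mean + 4 precision units for the 64-neuron
impairment replica) in which state occupancy concentrates and the NMI is
discriminative. The impairment sweep additionally reports the mean NMI over
a small ensemble of training seeds (default 2) so that condition orderings
are not artifacts of CD training noise.

# The synthetic retina

## What it emulates

Stimuli: drifting square-wave gratings (8 orientations at 45-degree steps;
spatial frequencies 0.011 / 0.023 / 0.045 cycles/degree; temporal frequency
1 Hz; Michelson contrast 0.5, exact by construction), and sliding-window
scans over a procedural brick-wall texture. Frames are 64x64 pixels mapped
1:1 onto the electrode lattice; the pixel-to-visual-angle convention is
fixed at 45 degrees across the frame width, so cycles/degree is
well-defined (any fixed convention preserves the frequency ordering, which
is all the analysis uses). Temporal phase labels are discretized to 8 bins
per cycle.

Encoder: each neuron is a linear-nonlinear cascade with a
difference-of-Gaussians receptive field on the lattice (center sigma 6 px
~ 4 degrees; surround ratio 2; surround weight 0.9, i.e. nearly balanced
with a small positive DC so ON cells respond to full-field luminance while
OFF cells modulate on dark bars), ON/OFF polarity, gain drawn from
(80, 160) Hz per unit drive (stimulus modulation ~10-30 Hz over a 1-3 Hz
baseline), and 1-3 frames of latency. The center sigma places the DoG
passband over the three grating frequencies, with 0.045 cycles/degree the
best-resolved -- the regime the impairment experiment needs.

Spikes are drawn from a log-Gaussian Cox process: piecewise-constant
intensity per frame, optionally modulated by a smooth log-normal
perturbation (s.d. 0.2 in the experiments, mean-corrected), then Poisson
counts with uniform spike times within bins. The generator is thus the same
model family the rate-inference stage assumes, which is deliberate: it
makes the LGCP benchmark a well-posed recovery problem.

## Impairment model

Pharmacological GABA-receptor blockade is emulated as an ordinal impairment
level (0 / 1 / 2) acting through four graded mechanisms, all monotone in
level:

* **RF widening** (1.5x / 2x center sigma): coarser spatial integration.
* **RF positional scatter** (s.d. 4 / 8 px, slowly varying): scrambles the
  spatial phase each neuron reports in proportion to stimulus frequency
  (~90 degrees of phase at 0.045 cycles/degree vs ~22 at 0.011), producing
  the frequency-selective part of the information loss.
* **Latency jitter** (s.d. 5 / 8 frames, slowly varying): smears temporal
  phase at every frequency.
* **ON/OFF mixing** (rectification mix 0.5 / 1.0 toward full-wave): the
  frequency-doubling signature of disinhibition. At full mixing a grating
  and its counterphase partner drive identical responses, so impaired
  latent states pool counterphase stimuli -- visible as a spread of the
  per-state stimulus histogram.

Two candidate mechanisms were evaluated and rejected during design, and the
reasons are instructive: strong RF widening alone *increases* low-frequency
information (widening shifts the DoG passband toward the grating band), and
partial ON/OFF mixing alone *increases* it too (frequency doubling raises
modulation power while a residual amplitude asymmetry keeps counterphase
pairs separable). The final grading combines weak widening with positional
scatter, which degrades high frequencies selectively without boosting
sensitivity anywhere.

## What it does not emulate

No biophysical retinal circuitry (bipolar/amacrine pathways, adaptation,
receptor pharmacodynamics), no spike sorting artifacts, no electrode noise
or cell-type diversity beyond ON/OFF polarity and parameter heterogeneity.
Passing tests on this generator show the analysis recovers the structure
the generator puts in -- stimulus-locked population modes degraded by
graded impairment -- not that it would behave identically on a real
recording.

# Numerical and convention choices

* **Binning**: half-open `[t, t + dt)`; boundary spikes go to the later
  bin; a spike exactly at the recording end lands in the last bin.
* **Square-wave gratings** are computed from the fractional phase (bright
  on `[0, 0.5)`), which makes a frame and its half-period partner exactly
  counterphase in floating point.
* **Binarization** of latent probabilities thresholds at 0.5 with ties
  rounding up; Bernoulli sampling under a seed is available for sensitivity
  checks. Because RBM-family hiddens are conditionally independent given
  the visibles, thresholding equals the per-sample MAP state (tested).
* **State identities** encode the bit vector as a double (exact to 52
  units).
* **Stimulus-response lag** in STA calls defaults to 0 and is configured to
  the known simulated latency (2 frames) in the experiment replicas.
* **Derivative range** uses forward finite differences of the inferred
  (smooth) rate; a linear ramp therefore counts as "tonic", which is
  documented behavior. The selection threshold default (5 Hz/s) is
  calibrated on the synthetic populations to drop silent and constant
  neurons; it is a required, logged configuration value, not a universal
  constant.
* **Determinism**: every stochastic stage takes a seed derived from the
  experiment seed by fixed offsets; reruns of `run_experiment()` with an
  identical configuration produce byte-identical CSV artifacts (tested).
  Stage caching was considered and omitted: artifacts are cheap to
  recompute at these problem sizes and caching would complicate the
  byte-reproducibility guarantee.

# Problem sizes

The experiment replicas are scaled to desk sizes, chosen once: the
8-orientation grating replica uses 114 neurons in one 16x16-electrode patch
and 6 s per orientation (1440 samples); the impairment sweep uses 64
neurons over the full lattice (one orientation, 32 s per condition, 3
frequencies x 3 levels); the temporal replica uses 64 neurons, two motion
directions at 24 Hz for 16 s each, a 12-layer cRBM, and spacing from the
counterphase rule. The full-lattice choice for the impairment sweep matters
at 0.011 cycles/degree: within a single patch all neurons sit at nearly the
same spatial phase of so coarse a grating and the intact phase code is
degenerate, whereas the full lattice spans half a cycle.

# Limitations

* The plug-in MI is biased upward at small sample-to-state ratios; all
  reported NMIs must be read against their permutation nulls, not as
  absolute information estimates.
* LGCP hyperparameters are fixed configuration values, not learned; the
  optional marginal-likelihood grid search from the design was not needed
  for any shipped analysis and is not implemented.
* mcRBM training with an HMC negative phase is sensitive to learning rate;
  divergence is detected and aborts rather than being silently repaired.
* The cRBM counterphase rule requires commensurate sampling; for stimuli
  without a temporal period the spacing is a plain configuration value.
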