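# rgcmodes

Unsupervised latent-state analysis of retinal ganglion cell (RGC)
population activity, for computational neuroscientists studying how visual
stimuli are encoded in the joint firing of many neurons recorded on
high-density multi-electrode arrays (64x64 lattice).

The package implements the full analysis chain:

* **Firing-rate inference** from spike trains by MAP estimation under a
  log-Gaussian Cox process (Poisson counts, Gaussian-process log-intensity
  with a squared-exponential kernel), followed by removal of silent/tonic
  neurons whose rate-derivative range
  `max(dr/dt) - min(dr/dt)` falls below a threshold.
* **Energy-based latent models** of the standardized population rate
  vector `v`: the Gaussian-visible restricted Boltzmann machine (RBM) with
  energy `E(v,h) = ||v - a||²/2 - b'h - v'Wh`, the mean-covariance RBM
  (mcRBM) whose *precision* units gate the conditional covariance through
  factor loadings (`precision = I + C diag(-P h_c) C'`, `P <= 0`), and the
  conditional RBM (cRBM) whose autoregressive and history-to-hidden weights
  act as dynamic biases over a window of delayed rate frames. All are
  trained by contrastive divergence; the mcRBM negative phase uses hybrid
  Monte Carlo on the marginal free energy.
* **Mode visualization**: state/unit-triggered stimulus averaging (the
  spike-triggered-average idea applied to binary latent states), with a
  temporal slot-wise variant for cRBMs.
* **Evaluation**: plug-in mutual information between stimulus labels and
  latent states, normalized by the stimulus entropy
  (`NMI = I(X;Y)/H(X)` in [0, 1]), always reported against a
  shuffled-label permutation null.
* **A synthetic retina simulator** (drifting square gratings,
  natural-scene scans, LN-cascade populations, log-Gaussian Cox spike
  generation, graded encoding impairment emulating GABA-receptor blockade)
  that provides ground truth for every stage.

See the methods vignette (`vignettes/rgcmodes-methods.Rmd`) for the models,
parameter choices and design rationale.

## Worked example

A compact end-to-end run: a 1 Hz drifting grating shown to a synthetic
48-neuron population, rates inferred from the sampled spikes, an mcRBM
trained on the standardized rates, and the latent states scored against the
stimulus phase.

```r
library(rgcmodes)

cfg <- experiment_config(
  stimulus = list(orientations = 0, duration_per_orientation_s = 16),
  population = list(n_neurons = 48),
  model = list(kind = "mcrbm",
               train = list(n_hidden = 4, n_factors = 16, n_precision = 4,
                            epochs = 25, learning_rate = 0.01)),
  analysis = list(label = "phase"),
  evaluation = list(null_reps = 100),
  seed = 42)
res <- run_experiment(cfg, out_dir = "artifacts")

print(res$mi)
head(res$census, 3)
bm <- best_frame_match(res$sta[[1]], res$stimulus)
cat(sprintf("top state images phase bin %d (r = %.2f over %d samples)\n",
            bm$label$phase_bin, bm$r, res$sta[[1]]$n_samples_averaged))
```

```
<mi_result> I = 1.1319 bits, H(stim) = 2.9899 bits, NMI = 0.3786 (n = 480)
   state_id count   fraction
16      250   207 0.43125000
15      245   197 0.41041667
17      252    17 0.03541667
top state images phase bin 5 (r = 0.88 over 207 samples)
```

Reading the output: the stimulus phase (8 bins per cycle) carries ~3 bits;
the trained model captures 1.13 bits of it (NMI 0.38, far above the
permutation null, whose 95th percentile here is 0.06). Occupancy
concentrates on two states that split the grating cycle, and the
top state's triggered average correlates at r = 0.88 with a single pure
grating frame -- the state "images" a specific stimulus phase. The
`artifacts/` directory receives the spike trains (TSV), inferred rates,
selection report, states, census, NMI table and triggered averages (CSV),
plus a JSON meta record carrying the configuration hash.

Larger replicas of the grating, impairment-sweep and temporal-mode
experiments are exercised in `tests/testthat/test-acceptance.R` and by
`scripts/acceptance.R`.

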