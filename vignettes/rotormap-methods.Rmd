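---
title: "rotormap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rotormap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
**rotormap**: how the synthetic excitation data is generated, how phase maps
and phase singularities (PS) are defined and computed, how the classical
restoration reference and the learned predictors work, and where the
package's known limitations lie. Code chunks are illustrative and not
evaluated during build; the same computations are exercised by the test
suite.

## 1. The excitable-medium generator

Electrical excitation is simulated with a two-variable phenomenological
reaction–diffusion model of cardiac tissue,

$$\partial_t V = D\,\nabla^2 V - kV(V-a)(V-1) - Vr,$$
$$\partial_t r = \varepsilon(V, r)\,\bigl(kV(a+1-V) - r\bigr),
\qquad \varepsilon(V,r) = \varepsilon_0 + \mu_1 r/(V+\mu_2),$$

with $a = 0.09$, $k = 8.2$, $\varepsilon_0 = 0.01$, $\mu_1 = 0.07$,
$\mu_2 = 0.3$, $D = 1$ on a $200\times200$ grid. Integration is explicit
Euler with no-flux boundaries.

Numerical choices (all recorded in `simulationConfig()` and validated):

* **Time step** `dt = 0.05`, well inside the diffusive stability bound
  `dt <= dx^2/(4D)`; the bound is enforced by the class validity method.
* **Grid spacing** `dx = 0.9`. Together with `dt` and the snapshot stride of
  10 Euler steps this calibrates the dominant rotor period to roughly 100
  stored snapshots (measured: 104 at seed 1, 106 at seed 2 via
  `dominantPeriod()`), and a mean PS density of about 4 per
  $128\times128$ frame over the first 2,500 snapshots. The regime is *not*
  stationary: wavebreak accumulates, and over a 5,000-snapshot horizon the
  seed-1 mean density roughly doubles (4.1 per frame in the first half, 9.5
  in the second, 6.8 overall), with strong excursions in both directions.
* **Laplacian**: 9-point isotropic stencil
  ($\tfrac23$ cross $+\tfrac16$ diagonal $-\tfrac{10}3$ center). The 5-point
  stencil produces visibly anisotropic wave break at this resolution; both
  stencils are available (`stencil = 5` or `9`).
* **Initiation protocol**: spiral-wave chaos does not self-start from random
  point stimuli alone at these parameters. Episodes therefore use an S1–S2
  cross-field protocol (a plane-wave band at $t=0$, a half-field rectangle at
  $t=116$) followed by seeded random point stimulations inside a configurable
  window. All randomness derives from `config@seed`; episodes are exactly
  reproducible and the caller's RNG stream is left untouched.
* A transient of 180 time units is discarded before snapshots are recorded.

```{r}
library(rotormap)
cfg <- simulationConfig(nSnapshots = 2500L, seed = 1L)
movie <- simulateEpisode(cfg)
dominantPeriod(movie)   # ~100 snapshots per rotor turn
```

**Generator realism.** The regime exhibits alternating chaotic and laminar
episodes with strong fluctuations in the number of simultaneous rotors;
per-seed mean PS density varies by a factor of about two. The defaults were
frozen before the acceptance measurements and were not adjusted afterwards.

## 2. Phase maps

Three classical per-pixel phase definitions are provided:

* `hilbertPhase()` — the argument of the analytic signal of the
  mean-subtracted trace (FFT-based, processed in pixel blocks to bound
  memory). Constant traces are an error (vector input) or marked missing
  (movie input). This is the package's ground-truth definition.
* `delayEmbeddingPhase()` — `atan2` of the delay-embedded trace;
  `autoEmbedDelay()` picks the delay from the first autocorrelation zero
  crossing (about a quarter period).
* `linearInterpPhase()` — piecewise-linear phase between detected upstrokes,
  anchored at $-\pi$.

Phases live in $[-\pi, \pi)$; `wrapPhase()` is the canonical wrap, and all
learned and classical processing of phase uses the trigonometric encoding
$\phi \mapsto (\cos\phi, \sin\phi)$ (`trigEncode()` / `trigDecode()`), so no
averaging ever crosses the branch cut.

## 3. Phase singularities

`detectPS()` evaluates the discrete line integral of wrap-corrected phase
differences around every $2\times2$ plaquette; a winding of $\pm2\pi$ marks a
PS with chirality $\pm1$ at the plaquette center (`x = column`, `y = row`,
0-based, offset $+0.5$). Topological charge is conserved by construction;
the test suite verifies net-charge conservation on 1,000 planted vortex
fields. Class-map and probability-map encodings
(`encodePSClassMap()`, `psFromProbability()`) convert between point sets and
image targets for the direct predictors; connected components are labelled
with an 8-connected labeller (neighbors across edges *or* corners).

## 4. Degradations

`degradeMovie()` reproduces measurement imperfections: unclipped i.i.d.
Gaussian noise (`addNoise`), per-axis sparsification to a pixel lattice
(`sparsify`, fraction $\xi$ per axis), block-mean low resolution
(`lowresMovie`), electrode layouts (8×8 grids with large/small circular
apertures and a star/ring arrangement, `electrodeLayout`) and random
star-shaped tissue masks (`randomTissueMask`). All are seeded; datasets
record the seed so inputs regenerate exactly.

## 5. Classical restoration reference

`restorePipeline()` composes three phasor-domain stages with disk-shaped
spatio-temporal kernels (diameter $d$ pixels × 3 frames):

1. **Outlier removal** — remove values whose local Kuramoto order parameter
   $r$ (kernel $d=5$) falls below 0.9;
2. **Inpainting** — Jacobi-style iterative filling with kernel phasor means
   (≥30% valid entries per kernel, repeated to completion);
3. **Smoothing** — kernel phasor averaging ($d=7$).

**Known limitation.** The fixed $r<0.9$ threshold is calibrated for mild
(optical-mapping-like) noise. At $\sigma = 0.3$ on unit-range excitation the
noisy-phase $r$ distribution lies almost entirely below 0.9 (median ≈ 0.74 at
128×128), so the outlier stage removes ~96% of all pixels and the pipeline
then reconstructs from scattered noisy anchors, landing in the high-50s to
mid-60s in angular accuracy depending on the episode — *worse than no
restoration*. Plain phasor smoothing alone reaches 96.7% on the same data. The package keeps the pipeline literal rather than
silently re-tuning it; users facing heavy noise should use
`restorePipeline(..., preset = "custom", smoothD = 7)` or the learned
predictors. The shipped acceptance measurement reports the literal pipeline's
honest number.

## 6. Learned predictors

Five compact encoder–decoder CNNs are implemented from scratch (R front end,
C++ conv/pool/upsample kernels; no external DL framework is available in the
target environment):

| Variant | Input | Latent | Output / loss |
|---|---|---|---|
| M1 | $N_t$ frames as channels | conv stack | 2-channel $(\cos,\sin)$, tanh + MSE |
| M2 | per-frame shared encoder | convolutional LSTM | as M1 |
| M3 | as M1 | U-Net skip concatenations | as M1 |
| M1A | as M1 | as M1 | 2-class per-pixel softmax + cross-entropy |
| M1B | as M1 | as M1 | PS probability, sigmoid + weighted Hausdorff ($\alpha=-3$) |

Every stage is 3×3 convolution + batch norm + ReLU (configurable count per
stage), 2× max pooling down and nearest-neighbor upsampling up. Training is
mini-batch Adam with an episode-respecting validation split; all gradients
are analytic and verified against finite differences for all five variants in
the test suite. The weighted Hausdorff loss implements the probability-
weighted distance to the nearest true point plus a generalized-mean
(soft-min) term per true point, with an analytic gradient.

Indirect PS prediction runs `detectPS()` directly on the predicted phase
map. Smoothing the prediction first was evaluated and rejected: at the
reduced scales used in the tests a $d=5$ phasor smoothing displaces and
merges nearby cores, roughly halving the PS F-score while barely changing
angular accuracy.

## 7. Problem sizes and budgets

The package's reference experiments are deliberately reduced-scale so that
the entire test suite runs on one CPU core in tens of minutes:

* episodes of 700–2,500 snapshots at 200×200, resized to 128×128 for
  classical processing and 32×32 for network training;
* ~650 training samples from two episodes, one held-out test episode
  (episode-disjoint by construction);
* encoder widths (8, 16, 32), latent 64, 2 convolutions per stage.

At this scale the phase predictors reach the low-to-mid-90s in angular
accuracy rather than the ~99% attainable with 20,000 samples at 128×128 and
hundreds of epochs; the PS F-scores are correspondingly lower. The package
API supports the full-scale settings (`side = 128`, widths 64/128/256,
latent 512, 3 convolutions per stage) unchanged.

## 8. Reproducibility

Everything that consumes randomness takes an explicit seed and restores the
caller's RNG state. `scripts/acceptance.R` recomputes the two headline
numbers (dominant rotor period; literal classical-restoration accuracy at
$\sigma=0.3$) from scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
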