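---
title: "Pooling, complex cells and orientation maps in a two-layer sparse predictive coding model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling, complex cells and orientation maps in a two-layer sparse predictive coding model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpcv1)
```

## The model

`sdpcv1` implements a two-layer convolutional sparse coding network with
hierarchical predictive-coding feedback, as a model of simple and complex
cells in primary visual cortex. The generative model is

$$
x = W_S^\top \gamma_S + \epsilon_S, \qquad
p_S(\gamma_S) = W_C^\top \gamma_C + \epsilon_C,
$$

where $x$ is a whitened grayscale image, $\gamma_S, \gamma_C \ge 0$ are
sparse response maps (rate-coded simple and complex cell layers), $W_S, W_C$
are convolutional dictionaries with unit-norm kernels, $W^\top\gamma$
denotes the transpose convolution, and $p_S$ is a max-pooling operator
between the layers. Responses and weights are found by minimising

$$
F = \tfrac12\lVert \epsilon_S \rVert_2^2
  + \tfrac12\lVert \epsilon_C \rVert_2^2
  + \lambda_S \lVert \gamma_S \rVert_1
  + \lambda_C \lVert \gamma_C \rVert_1 .
$$

Inference alternates non-negative proximal gradient sweeps over
$\gamma_S$ and $\gamma_C$; the $\gamma_S$ update receives
$-\,p_S^{-1}(\epsilon_C)$, the second-layer prediction error routed backwards
through the recorded pooling argmax switches (the standard unpooling
approximation of the max-pooling derivative). Removing that term
(`feedback = FALSE`) is the feedback-ablation control: the first layer then
evolves exactly as a single-layer sparse coding model.

Three pooling operators are available and composable
(see `pooling_spec()`):

* `spatial_2d` — 2×2, stride 2, per feature plane (retinotopic invariance);
* `feature_1d_circular` — kernel 4, stride 1, across adjacent feature planes
  on a circular ring;
* `feature_2d_toroidal` — 2×2, stride 1, across feature planes arranged
  row-major on a $\sqrt M \times \sqrt M$ toroidal grid.

The scientific question is how the choice among `spatial_2d`,
`feature_2d_toroidal` and the composites controls (i) the emergence of
phase-invariant (complex) units in the second layer, measured by the
modulation ratio F1/F0 under drifting gratings, and (ii) the emergence of a
topographic orientation map in the first layer, measured by the local
homogeneity index (LHI) and pinwheel statistics.

## Numerical choices

**Inference.** The loss is convex in each activity block but the max-pooling
makes it only piecewise quadratic in $\gamma_S$, so a fixed step derived
from the convolutional operator norm does not majorise it across switch
flips. The solver therefore uses monotone accelerated proximal steps: a
Nesterov candidate is accepted only when its block objective (evaluated with
the true max pooling) does not increase, otherwise the momentum sequence
restarts at the current iterate. The recorded loss trace is consequently
non-increasing, and divergence is impossible by construction. Step sizes
default to `"auto"`: $\eta = 0.9/L$ per layer with $L$ estimated by 20 power
iterations of the layer's convolutional operator; for the first layer the
maximum unpool multiplicity of the pooling spec (1 for non-overlapping
spatial pooling, 4 for the stride-1 feature poolings) is added to $L$
because the feedback path contributes curvature of its own. Pooling switches
are recomputed at every iteration; ties inside a window go to the first
element in a row-major (channel-major for feature stages) scan. Inference
stops when the relative loss change falls below `inference_tol` (default
`1e-4`) or at `inference_max_iters` (200; capped at 16 inside a training
step, where warm convergence matters less than update throughput).

**Learning.** Dictionaries follow the Hebbian-style correlation of activity
and prediction error with momentum 0.9, and every kernel is renormalised to
unit Euclidean norm after each step; kernels whose update collapses to zero
are kept at their previous value and logged as dead. The correlation sums
over all convolutional positions; the trainer applies the learning rate to
the minibatch mean. Under this convention the default `learning_rate = 0.1`
moves unit-norm kernels by a few percent per step, which is the regime in
which oriented receptive fields develop; much smaller rates leave the random
initialisation essentially untouched and much larger ones collapse the
dictionary onto a single template. The sparsity penalties ramp linearly from
0 to their targets (default 0.1 per layer) over the first half of training.

**Whitening.** Inputs are whitened with the retina-style ramp
$R(f) = f\,e^{-(f/f_c)^4}$, $f_c = 0.4 \times$ Nyquist. Each image's
spectrum is divided by its own radially averaged amplitude — an isotropic
estimate of the 1/f trend — and multiplied by $R$. Normalising only the
isotropic trend preserves the oriented spectral energy that drives
orientation learning (a full per-bin flattening destroys it), removes DC,
and makes the operation idempotent up to rescaling. The batch is rescaled
jointly into $[-1, 1]$.

## The synthetic image generator

`synthetic_images()` emulates the aspects of natural scenes this model
feeds on: a $1/f$-amplitude noise background (40% of the contrast) plus
randomly placed, uniformly oriented smooth bars of random polarity, length
and width, normalised to $[-1,1]$. Its radially averaged amplitude spectrum
falls approximately like $1/f$ and its edge orientations are uniform on
$[0^\circ, 180^\circ)$, both of which are checked by the test suite. What it
does *not* reproduce: occlusion structure, broadband texture, curvature,
scale mixing, and the long-range contour correlations of photographs.
Passing tests on this generator therefore demonstrate that the model
mechanics behave as designed under controlled natural-like statistics, not
that identical percentages would be measured on photographic datasets.

## Measurement battery

Preferred stimulus parameters are assigned empirically by default: a family
of static gratings spanning 12 orientations × 4 spatial frequencies × 4
phases (14-pixel circular mask, whitened like the training input) is
presented and each unit takes the argmax-response parameters, as an
experimenter would. Log-Gabor fits of the first-layer kernels (and of
`backproject()`ed second-layer kernels, the ridge-regularised linear map
$V^* = \arg\min \tfrac12\lVert x - V^\top\gamma_C\rVert^2$) provide the
model-based alternative (`optimal = "gabor"`); at desk scale the
back-projections are noisy enough that response maximisation is the more
reliable assignment, which is why it is the default.

Each unit is then swept with a drifting grating (one full 360° phase cycle)
and a rotating grating (one 180° orientation cycle — orientation is
$\pi$-periodic, and one sweep is taken as the modulation cycle). The
response is the steady-state activity at the spatial position of maximal
response, chosen on the best frame and then held fixed. F0 is the curve
mean, F1 twice the modulus of the discrete Fourier component at one cycle
per sweep over the number of frames; units with F1/F0 > 1 are simple,
others complex, and units with F0 = 0 are flagged non-responsive and
excluded from the population percentages (they are reported separately).
The rectified-sine model $(a\cos(\phi - \phi_0) - b)_+$ is fitted by exact
harmonic regression when the best cosine never clips and by seeded
Nelder-Mead/BFGS refinement otherwise; $\chi = b/|a|$ maps to F1/F0 through
the closed-form piecewise expression implemented in `chi_to_f1f0()`
(branches meeting at $\chi = -1$, value 1; undefined above 1; the
vanishing-width limit at $\chi = 1$ is taken as 2).

LHI uses a Gaussian of $\sigma = 1$ grid unit truncated at $3\sigma$, with
wraparound distances on the declared topology and the centre site excluded
(its own orientation is undefined at a singularity); the normaliser is the
truncated window's weight sum. Pinwheels are strict 3×3 toroidal local
minima below 0.2. Pinwheel density divides the count by $M_s/c$ with column
size $c = (180^\circ/\overline{\mathrm{HWHH}})^2$ (the per-column-area
reading; the alternative grouping is available via `per_area = FALSE`).
HWHH is measured primarily from the rotating-grating curve (half width at
half of peak-minus-baseline, interpolated, wraparound), with the
log-Gabor-derived value reported alongside.

## Study scales

The published protocol trains on 96×96 natural images for 28125 iterations
at batch 32 — far beyond a desk-scale test budget. The package therefore
defines a `"reduced"` scale used by the tests and the acceptance script:
28×28 synthetic whitened images (pool of 1024), $M_s = M_c = 36$, 800
training iterations at batch 8, inference capped at 16 iterations inside
training and 30 during probing, 16 frames per probe sweep. These sizes were
fixed once so that a full train-and-probe run takes a few minutes on one
CPU core. The `"full"` scale mirrors the published settings and expects an
external natural-image dataset via `load_image_dataset()`.

At the reduced scale the qualitative ordering of the pooling variants
reproduces reliably: the first layer is purely simple, feature-only pooling
yields an essentially simple second layer, spatial pooling preserves
orientation selectivity, and feature pooling combined with feedback raises
the first-layer map homogeneity above the spatial-only and
feedback-ablated controls. The extreme percentages of the full-scale study
(a fully complex second layer under spatial + circular feature pooling)
require the phase-sheeted feature arrangement that only emerges with far
longer training on richer data; at this scale only part of the responsive
second layer crosses the F1/F0 < 1 line, and the corresponding check is
expected to fall short honestly rather than being relaxed.

## Worked example

```{r example, eval = FALSE}
imgs <- synthetic_images(1024, 28, seed = 1, whiten = TRUE)
fit <- sdpc(imgs,
            layers = list(sdpc_layer(36, 7), sdpc_layer(36, 4)),
            pooling = pooling_spec("spatial_2d", "feature_1d_circular"),
            control = sdpc_control(iterations = 800, seed = 1))
summary(fit)
units <- probe_population(fit, layers = 2, samples_per_cycle = 16,
                          infer_iters = 40)
population_summary(units)
om <- orientation_map(fit)
compute_lhi(om)
```

## Known limitations

* The reduced scale underestimates phase invariance relative to the
  published full-scale study (see above); percentages from
  `run_experiment(scale = "reduced")` should be read as orderings, not
  absolute replication.
* The $\ell_0$-constrained formulation of the generative model is not
  implemented (the study itself relaxes it to $\ell_1$); the trainer is
  two-layer only, though the loss evaluator and inference accept one-layer
  networks.
* Learned or energy-based (sum-of-squares) pooling families are out of
  scope.
* The orientation assignment for second-layer units depends on grating
  response maximisation over a finite grid; units responsive only to
  stimuli outside the grid would be mislabelled (none were observed at the
  default grid).
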