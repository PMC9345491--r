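# sdpcv1 — pooling, complex cells and orientation maps in a sparse predictive coding model of V1

Simple cells in primary visual cortex are phase-selective; complex cells are
phase-invariant but still orientation-tuned. Some species (carnivores,
primates) additionally arrange orientation preference into smooth cortical
maps with pinwheel singularities, while rodents show a salt-and-pepper
layout — yet both have complex cells. `sdpcv1` implements a computational
account of this diversity: a two-layer convolutional sparse coding network
with predictive-coding feedback in which a single mechanism — the choice of
max-pooling operator between the layers — controls which phenomena emerge.

The generative model is

```
x        = W_S' γ_S + ε_S          γ_S ≥ 0, sparse
p(γ_S)   = W_C' γ_C + ε_C          γ_C ≥ 0, sparse
```

with loss `F = ½‖ε_S‖² + ½‖ε_C‖² + λ_S‖γ_S‖₁ + λ_C‖γ_C‖₁`. Inference is a
monotone accelerated proximal descent on `F` over the activities (the
feedback term routes `ε_C` back through the pooling argmax switches);
learning is a momentum Hebbian update of the unit-norm convolutional
dictionaries. The pooling operator `p` can act on retinotopic space
(`spatial_2d`, 2×2 stride 2), on a circular feature ring
(`feature_1d_circular`, kernel 4), on a toroidal feature grid
(`feature_2d_toroidal`, 2×2), or compositions of these.

The analysis battery mirrors the electrophysiology toolchain: drifting- and
rotating-grating protocols, modulation ratio F1/F0 (simple iff F1/F0 > 1),
the rectified-sine response model `(a·cos(φ−φ₀)−b)₊` with rectification
index χ = b/|a| and its closed-form mapping to F1/F0, log-Gabor
receptive-field fits, second-layer back-projection, local homogeneity index
(LHI), pinwheel detection and density, and population statistics
(R_φ / R_θ percentages, χ medians, signed-rank tests, HWHH-vs-LHI
regression).

## Worked example

```r
library(sdpcv1)

imgs <- synthetic_images(1024, 28, seed = 1, whiten = TRUE)
fit <- sdpc(imgs,
            layers  = list(sdpc_layer(36, 7), sdpc_layer(36, 4)),
            pooling = pooling_spec("spatial_2d", "feature_1d_circular"),
            control = sdpc_control(iterations = 800, seed = 1))
units <- probe_population(fit, layers = 1:2, samples_per_cycle = 16,
                          infer_iters = 30)
population_summary(units, lhi = compute_lhi(orientation_map(fit)))
```

prints, for a reduced-scale network trained with spatial + circular feature
pooling (exact numbers vary with the seed):

```
layer 1: R_phi = 0.0%, R_theta = 5.6% (n = 36; nonresponsive 0/0)
  chi_phi = 0.21 +/- 0.05, chi_theta = 0.46 +/- 0.42 (median +/- MAD), one-tailed signed-rank p = 3.9e-05
layer 2: R_phi = 85.7%, R_theta = 50.0% (n = 36; nonresponsive 22/22)
  chi_phi = -4.44 +/- 4.85, chi_theta = -0.99 +/- 2.49 (median +/- MAD), one-tailed signed-rank p = 0.0148
HWHH ~ LHI: slope -8.62 deg/unit (p = 0.0359)
```

Read: every first-layer unit is simple (R_φ = 0) and orientation-tuned;
most responsive second-layer units are complex (R_φ = 86%), and χ_φ sits
far below χ_θ (signed-rank p = 0.015) — phase invariance without matching
orientation invariance. The negative HWHH-on-LHI slope says units inside
iso-orientation domains are the more sharply tuned ones, as in cortical
maps. Percentages move with the training seed at this scale. `run_experiment()` wraps training, probing
and the map analyses for one configuration; `experiment_grid()` and
`experiment_report()` orchestrate the pooling-by-size studies. A thin
command-line wrapper with `train` / `probe` / `analyze` / `grid` / `report`
subcommands is installed at `inst/cli/sdpc.R`.

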