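---
title: "A neural saliency-map model with center-surround competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neural saliency-map model with center-surround competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salnet)
```

salnet simulates bottom-up visual salience as the steady state of a layered
network of mean-field neural populations. This vignette is the package's own
account of the model: what is computed, which parameters matter, what the
synthetic stimulus generator does and does not emulate, and where we made
numerical and design choices that a maintainer should know about.

## The model

### Feature extraction

An input image is normalized to RGB values in $[0,1]$ and downsized by exact
area averaging to three working resolutions, 384×216, 192×108 and 96×54
(width × height). Nine feature images at 96×54 drive the network:

* **Luminance** $F_{lum} = (V_r + V_g + V_b)/3$.
* **Colour opponency** (4 channels): rectified differences normalized by
  luminance, e.g. red $= g(V_r - V_g)/F_{lum}$ and blue
  $= g(V_b - V_y)/F_{lum}$ with $V_y = \min(V_r, V_g)$ and
  $g(x) = \max(x, 0)$. Where $F_{lum} = 0$ the features are defined as 0:
  black pixels carry no chromatic signal. This guard is a definition, not an
  epsilon-regularization, and is covered by tests.
* **Orientation** (4 channels): magnitude responses of complex Gabor filters
  $G_\theta(x,y) = \exp\!\big(-(x_\theta^2 + (\gamma y_\theta)^2)/2\sigma^2\big)
  \exp(i\,\omega_0 x_\theta)$ with $\gamma = 0.5$, $\sigma = 2$,
  $\omega_0 = 2$ and $\theta \in \{0°, 45°, 90°, 135°\}$, applied to the
  intensity image at all three resolutions; the finer responses are
  block-averaged to 96×54 and the three magnitudes averaged.

Choices worth recording:

* **Magnitude before downsizing.** We take $|O_\theta|$ at the native
  resolution and then block-average. Downsizing the complex response first
  would let opposite-phase responses cancel inside each block and destroy the
  fine-scale structure the multi-resolution scheme exists to preserve.
* **Kernel support.** The Gabor envelope is elongated along the rotated $y$
  axis (effective SD $\sigma/\gamma = 4$ px), so the default half-width of 12
  px truncates the tail at $e^{-4.5} \approx 0.011$. Tests show features move
  by less than 0.5% (relative to the peak response) when the half-width grows
  from 12 to 24, so 12 is kept as a sensible default and is configurable.
* **Orientation convention.** $\theta$ is the carrier direction in screen
  coordinates ($y$ down). The envelope is elongated perpendicular to the
  carrier, so the $\theta = 0$ channel responds most strongly to *vertical*
  bars and $\theta = 90$ to horizontal ones. A generated-bar test pins this
  pairing down, and an exact rotation identity (rotating the image by 90°
  permutes paired channels) is verified at the kernel level.
* **Convolution boundary.** Zero padding with same-size output; the FFT
  implementation is tested against a direct double-loop sum at $10^{-10}$.
* Gabor kernels are used exactly as defined — no zero-mean or unit-energy
  normalization is applied.

### Network dynamics

The proposed network has 13 maps of 54×96 populations: nine feature maps,
three conspicuity maps (luminance, colour, orientation) and one saliency map.
Each population's rate $A_{m,i}$ follows

$$\tau \frac{dA_{m,i}}{dT} = -A_{m,i} + b + 0.5\,g(S^L_{m,i} + S^{FPost}_{m,i})$$

with $\tau = 0.03$ s and baseline $b$ (0 unless stated). Both lateral and
feedforward transmission pass through depressing synapses: a resource
$z \in (0,1]$ per presynaptic population,

$$\frac{dz}{dT} = -U_{SE}\,A\,z + \frac{1-z}{\tau_{rec}},$$

with $U_{SE} = 0.5$ for both classes, $\tau^L_{rec} = 0.1$ s and
$\tau^F_{rec} = 0.05$ s. Depression is what keeps the competition from
collapsing to winner-take-all: highly active populations transiently weaken
their own outgoing connections, so non-salient objects retain residual
activity at steady state.

Lateral connectivity within every map is a difference of Gaussians over
population distance $d$ (in grid cells):

$$w^L(d) = \frac{w_E}{2\pi\sigma_L^2} e^{-d^2/2\sigma_L^2}
         - \frac{w_I}{2\pi(\beta\sigma_L)^2} e^{-d^2/2(\beta\sigma_L)^2}$$

with $w_E = 2$, $\beta = 15$ fixed and $w_I$, $\sigma_L$ the scientifically
interesting knobs: local excitation plus long-range inhibition implements
center-surround competition, and $w_I$ sets the excitatory–inhibitory
balance. Feedforward weights are the separable 5×5 profile with taps 1.13,
0.71, 0.14 at offsets 0, ±1, ±2. Inputs are the feature images scaled by
$C_{lum} = 30$, $C_{col} = 15$, $C_{ori} = 20$; the conspicuity maps pool
their feature maps and the saliency map pools the conspicuity maps. A reduced
comparison variant (`brecht_saiki_config()`) has four feature maps fed by raw
red/green values and single-scale 0°/90° Gabor magnitudes (gains 30), two
conspicuity maps, a saliency map without lateral connections, and a fixed
lateral profile $w_E = 5$, $w_I = 250$, $\sigma_L = 3.2$, $\beta = 15$
elsewhere.

### Numerics

* **Time grid.** Forward Euler with $dt = 1$ ms applied to per-second
  derivatives (the 0.001 update factor); "$t = 400$" means 400 steps.
  The update is *synchronous*: all activities and resources advance from the
  previous step's values. A sweep order (Gauss–Seidel) would make results
  depend on map ordering and be unreproducible.
* **Initial conditions.** $A(0) = 0$, $z(0) = 1$: activity rises from rest
  with full synaptic resources. (Nothing else would be defensible without
  additional assumptions.)
* **Boundaries.** Populations outside the grid do not exist; all sums are
  truncated (equivalently, zero-padded). No toroidal wrap.
* **Self-connection.** Lateral sums run over *all* populations of a map,
  including $j = i$.
* **Stability and guards.** With these parameters the Euler factors satisfy
  $0.001/\tau < 1$ and $0.001(U_{SE} A + 1/\tau_{rec}) < 1$ throughout the
  tested regimes, so $A \ge 0$ and $z \in (0,1]$ are conserved; the simulator
  checks both and *aborts* with a divergence error rather than clamping, so
  pathology is visible.
* **Fast paths equal explicit sums.** Each DoG Gaussian factorizes over the
  two axes, so the unablated lateral drive is computed with small dense
  matrix products per axis; ablated maps use an explicit sparse masked weight
  matrix (kept pairs only), in double precision. Both paths are tested
  against brute-force double-loop weight sums on small grids at $10^{-9}$.
* **Saliency-layer lateral connections.** The activity equation is stated for
  every map, and only the reduced variant is said to lack saliency-layer
  lateral connections; the proposed model therefore keeps them, with one
  shared profile across layers. Both choices are configurable per map.
* **Ablation scope.** "Remove 60% of lateral connections" is implemented as
  independent Bernoulli removal over *directed* pairs, with an independent
  mask per map by default (`scope = "global"` shares one mask). Masks are
  drawn once per run from the given seed and held fixed.

## Evaluation

**NSS** (Normalized Scanpath Saliency) z-scores the saliency map with its own
mean and *population* (divide-by-N) standard deviation and averages the
z-scores at the fixated grid cells. Population SD is a documented choice
(sample SD would change scores by a factor $\sqrt{N/(N-1)} \approx 1.0001$
here). NSS is affine-invariant; fixations are evaluated at grid-cell
resolution after floor-scaling pixel coordinates
(`cell = floor(px * grid/stim)`), a mapping that is monotone and surjective.
Out-of-bounds fixations are dropped with a warning, not clamped — clamping
would pile mass onto edge cells and inflate edge saliency. Stimuli with
undefined NSS (constant maps) are excluded from aggregates and counted,
rather than scored 0.

**Fixation simulation** normalizes the map to sum 1 and samples cells from the
resulting categorical distribution. **Parameter recovery** estimates $w_I$ by
grid search: for each candidate, the mean NSS of the candidate's saliency
maps against the generated fixations; the argmax (ties broken toward the
smaller $w_I$, for deterministic reporting) is the estimate. Saliency maps
are deterministic given the configuration, so maps are simulated once per
(stimulus, $w_I$) and reused across sampling replicates.

## The synthetic stimulus generator

`default_bar_layout()` reproduces the classic colour + orientation pop-out
display: one vertical red bar among nine horizontal blue bars, a 5×2 grid of
180×36 px bars on a black 1920×1080 background (the geometry is our choice of
a typical display; it is fully configurable). `random_bar_layout()` draws
randomized variants — target cell, colour pair from {red, green, blue,
yellow}, target/distractor orientation assignment, and jittered centres — and
is the stimulus source for recovery experiments.

What the generator emulates: isolated, high-contrast, single-feature pop-out
targets of the kind used to characterize center-surround competition. What it
does not emulate: natural-image statistics — broadband luminance structure,
texture, clutter, semantic content. Passing tests on these displays show the
competition machinery weights a unique feature correctly; they do not certify
eye-movement prediction performance on natural scenes, which additionally
depends on feature richness and on fixation behaviour beyond bottom-up
salience.

## Problem sizes used in the checks

The packaged checks run the full 96×54, 13-map network at 400 steps for the
pop-out analyses (single runs take a few seconds); the recovery experiment
uses 20 random bar stimuli × 20 fixations, the grid {120, 160, 200, 240,
280} with $\sigma_L = 6.4$, and 5 sampling replicates, with maps shared
across replicates. Operator-equivalence oracles run on grids of at most 16×9
(lateral/feedforward) and 16×16 images (convolution), where brute-force
double loops are exact and fast. A `resize_feature_set()` helper supports
reduced-resolution experiments; lateral length scales must then be rescaled
by the caller.

## Known limitations

* Scanpaths are not modeled: no saccade sequencing, fixation durations, or
  inhibition of return. NSS deliberately scores only the spatial
  correspondence between a map and a set of fixations.
* The border shapes the solution. The inhibitory Gaussian's SD
  ($\beta\sigma_L = 48$ cells at the defaults) is of the order of the grid,
  so truncation at the border modulates activity across the *whole* map, not
  a thin edge band; with baseline drive and no stimulus the upper maps settle
  to a border-shaped (though exactly mirror-symmetric) profile rather than a
  uniform one. This is a property of the model at these parameters, not a
  numerical artifact.
* On bar-array stimuli with $\sigma_L = 6.4$, the averaged NSS-vs-$w_I$
  recovery curve is cleanly peaked for strongly inhibited generators
  (e.g. $w_I = 280$) but nearly flat between 120 and 160 for weakly
  inhibited ones: weak competition produces similar maps across the low end
  of the grid, so the argmax there is sensitive to fixation-sampling noise
  at 20 fixations per stimulus. Richer stimulus sets sharpen it.
* Top-down cognition, learning, neuron types and phase synchronization are
  out of scope; the model is purely bottom-up.
* Only PNG, JPEG and TIFF rasters are read; reading eye-tracking archives in
  other formats is left to the user (the fixation CSV dialect is
  `x,y[,observer]`, 0-based pixels).

## A worked call

```{r example, eval = FALSE}
stim <- generate_bar_stimulus(default_bar_layout())
fs   <- extract_features(build_pyramid(stim$image))
sim  <- simulate_saliency(fs, network_config(w_i = 140, sigma_l = 3.2))
region_saliency(sim$saliency, stim)
autoplot(sim$saliency)
```
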