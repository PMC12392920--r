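# salnet

Simulation of bottom-up visual salience with a biologically motivated neural
network. salnet is for researchers who want a saliency-map model whose
internals are neural — excitatory-center/inhibitory-surround lateral
connectivity, short-term synaptic depression, mean-field population dynamics —
so that hypotheses about neurobiological disturbances (excitatory–inhibitory
imbalance, altered baseline activity, synaptic disconnection) can be expressed
as parameter changes and their effect on salience measured, including against
eye-movement data.

## The model in brief

An RGB image is downsized to a 96×54 grid and decomposed into nine feature
images: luminance, four rectified colour-opponency channels
(red–green, blue–yellow, e.g. `g(V_r − V_g)/F_lum` with `g(x) = max(x, 0)`),
and four orientation channels from complex Gabor filters
(γ = 0.5, σ = 2, ω₀ = 2; θ ∈ {0°, 45°, 90°, 135°}) applied at three
resolutions. These drive a 13-map network (9 feature maps → 3 conspicuity
maps → 1 saliency map) of rate units

    τ dA/dT = −A + b + 0.5 g(S_L + S_F),   τ = 30 ms

with depressing synapses (`dz/dT = −U_SE A z + (1 − z)/τ_rec`) on all lateral
and feedforward connections. Lateral weights follow a difference of
Gaussians,

    w_L(d) = w_E/(2πσ_L²) exp(−d²/2σ_L²) − w_I/(2π(βσ_L)²) exp(−d²/2(βσ_L)²)

(w_E = 2, β = 15), so each map performs center-surround competition; `w_I`
sets the excitatory–inhibitory balance. The saliency map read out after 400
1-ms Euler steps is scored against fixations with Normalized Scanpath
Saliency (NSS: mean z-scored saliency at fixated cells), fixations can be
*sampled* from a map, and `w_I` can be recovered from fixations by grid
search. A reduced 7-map comparison variant (`brecht_saiki_config()`) is
included. See the vignette (`vignettes/saliency-model.Rmd`) for the full
account.

## Worked example

```r
library(salnet)

stim <- generate_bar_stimulus(default_bar_layout())   # red vertical bar among 9 blue horizontal bars
fs   <- extract_features(build_pyramid(stim$image))
sim  <- simulate_saliency(fs, network_config(w_i = 140, sigma_l = 3.2))
sim
#> <salnet_sim> variant 'proposed', 96 x 54 grid, readout t = 400 ms
#>   saliency range [2.543e-13, 49.33]; min activity 0; z in [0.2866, 1.0000]

region_saliency(sim$saliency, stim)
#> # A tibble: 11 × 3
#>    region       n_cells mean_saliency
#>    <chr>          <int>         <dbl>
#>  1 distractor_1       9        37.8
#>  2 target            18        42.0
#>  3 distractor_2       9        29.4
#>  4 distractor_3       9        29.3
#>  5 distractor_4      10        26.2
#>  6 distractor_5      10        26.1
#>  7 distractor_6       9        29.4
#>  8 distractor_7       9        29.4
#>  9 distractor_8       9        38.0
#> 10 distractor_9       9        38.0
#> 11 background      4887         0.544
```

The unique red vertical bar ends up the most active region of the saliency
map (42.0), every blue distractor is partially suppressed by the competition
but survives (26–38 — synaptic depression prevents winner-take-all collapse),
and the background stays near zero. Raising `w_i` sharpens this contrast;
`baseline = 1` raises it; `ablate_connections(cfg, 0.6, seed)` (random
removal of 60% of lateral connections) lowers it. `nss()`,
`sample_fixations()`, `estimate_parameter()` and `run_recovery()` build the
evaluation layer on top; results have `tidy()`/`glance()`/`autoplot()`
methods.

A command-line front-end with `saliency`, `evaluate`, `recover`,
`make-stimulus` and `dynamics` subcommands is installed at
`inst/cli/salnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/salnet.R", package="salnet"))')" \
    saliency --demo-bars --wI 140 --sigmaL 3.2 --out out/
```

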