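Package: salnet
Title: Neural Saliency-Map Simulation with Center-Surround Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a biologically motivated saliency-map model of bottom-up
    visual attention. Luminance, red-green and blue-yellow colour-opponency, and
    multi-scale Gabor orientation features extracted from an image drive a layered
    network of mean-field neural populations whose lateral difference-of-Gaussians
    connectivity (local excitation, distant inhibition) and short-term synaptic
    depression implement center-surround competition. Includes synthetic bar-array
    stimulus generation, perturbation experiments (excitatory-inhibitory balance,
    baseline activity, random connection ablation), Normalized Scanpath Saliency
    (NSS) scoring against fixation data, saliency-driven fixation simulation, and
    grid-search parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
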