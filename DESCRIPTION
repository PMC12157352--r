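Package: v1rings
Title: Spatial Integration in a Layered Spiking Model of Primary Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse spatial summation of drifting-grating
    disk and ring (annulus) stimuli in a two-layer conductance-based spiking
    model of cat primary visual cortex. The package provides an LGN front-end
    (centre-surround spatiotemporal filtering feeding leaky integrate-and-fire
    units), a pinwheel orientation-preference map, a probabilistic connectome
    builder (thalamocortical Gabor sampling, layer 4 push-pull wiring, layer
    2/3 local plus orientation-biased long-range horizontal connectivity), an
    exponential integrate-and-fire network integrator with Tsodyks-Markram
    short-term depression, cyclegram-based membrane-potential and spike-train
    measures (VmDC, VmF1, VmSD, mean firing rate, spikes F1), and the
    spatial-integration indices (suppression index, residual, non-linearity
    index, linearity index) together with ground-truth-known synthetic trace
    generators for validating the analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
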