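Package: gcalsim
Title: Self-Organizing Retina-LGN-V1 Map Simulation with Gain Control,
    Adaptation, and Lateral Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate simulation of visual cortical map development in the
    GCAL family (gain control, homeostatic adaptation, laterally connected):
    a retina sheet, LGN On/Off channels with difference-of-Gaussians receptive
    fields and divisive contrast gain control, and a recurrently settling V1
    sheet whose afferent and lateral-inhibitory connection fields self-organize
    by Hebbian learning with divisive normalization under homeostatic threshold
    adaptation. Includes the synthetic stimulus families used for training
    (pairs of oriented Gaussians) and testing (sinusoidal gratings), contrast
    response and orientation-map measurements, and a registry of perturbation
    protocols modelling first-episode and chronic schizophrenia as reduced
    subcortical drive versus reduced cortical lateral inhibition with elevated
    afferent plasticity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
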