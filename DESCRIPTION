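Package: rgcmodes
Title: Latent-State Modeling of Retinal Ganglion Cell Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised analysis of retinal ganglion cell (RGC) population
    activity recorded on high-density multi-electrode arrays. Firing rates are
    inferred from spike trains by log-Gaussian Cox process MAP estimation;
    the joint rate distribution is modeled with Gaussian-visible, mean-
    covariance and conditional restricted Boltzmann machines trained by
    contrastive divergence; latent binary states are related back to the
    visual stimulus by state-triggered stimulus averaging and quantified with
    normalized mutual information. A synthetic retina simulator (drifting
    square gratings, natural-scene scans, graded encoding impairment)
    provides ground-truth data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
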