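Package: rodcone
Title: Linear-Nonlinear Models of Rod-Cone Interactions in Retinal Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying nonlinear interactions between rod- and
    cone-mediated signals at the retinal output. Provides a synthetic
    retina that generates band-limited Gaussian noise stimuli, paired
    flashes, and noisy responses from kinetically-distinct rod and cone
    temporal filters summed through a shared rectifying synaptic
    nonlinearity; estimation of linear-nonlinear (LN) cascade models from
    stimulus-response data by regularized reverse correlation; parameter-free
    prediction of paired-flash interactions with interaction and biphasic
    indices; and a simulated dichoptic brightness-matching task with an
    adaptive staircase, crossing-weighted match estimation, and perceptual
    interaction indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
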