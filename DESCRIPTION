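Package: glomcode
Title: Population Coding Analytics for Fly Optic Glomerulus Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analyzing population codes for visual
    feature detection in the Drosophila optic glomeruli. Includes an
    ideal-observer spot-discriminability simulation over natural-image-like
    (1/f^2) backgrounds, parametric stimulus generators (random-dot coherence
    fields, drifting grating plus probe composites, saccade playback
    displacement), a ground-truth generator for glomerulus trial tensors with
    a shared multiplicative gain and behavior coupling, core response
    analytics (dF/F, peak amplitudes, noise correlations, complete-linkage
    clustering, shared-gain extraction, Spearman gain-behavior tests with
    Holm correction, multinomial decoding with trial-shuffle controls),
    fictive- and free-walking behavior analytics (Li minimum cross-entropy
    thresholding, saccade detection, inter-turn-interval statistics), and
    gain-modulation analyses including a multiplicative visual-by-motor
    independence test with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    nnet,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
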