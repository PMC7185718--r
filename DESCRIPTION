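Package: bistream
Title: Hierarchical Auditory Streaming Simulation with Distributed Bistability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates perceptual bistability during auditory streaming with a
    three-stage hierarchical model of the auditory system. ABA triplet tone
    sequences are passed through a cochlea-like peripheral analysis, a
    spectral-scale central analysis and a probabilistic object analysis that
    groups features by temporal coherence (windowed non-negative
    factorization) and object continuity (conjugate Bayesian source
    tracking). Adaptation, inhibition and noise can be injected at any stage
    to produce spontaneous alternations between 'fused' and 'segregated'
    percepts. Includes the percept read-out heuristic, bistability hallmark
    metrics (response deviation, Kolmogorov-Smirnov response-length
    deviation, deviation ratios, buildup curves), a synthetic
    reference-listener generator, and ensemble machinery for sweeping
    adaptation/inhibition magnitudes within and across stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    boot,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
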