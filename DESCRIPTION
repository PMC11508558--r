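Package: hsfocus
Title: Focus-Measure Evaluation for Hyperspectral Imaging Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for benchmarking autofocus sharpness operators on
    through-focus image stacks from pushbroom hyperspectral imaging
    microscopes and conventional video imagers.  Implements a registry of
    22 focus measures (gradient, statistical and frequency-domain
    families), a principal-component-analysis reference that defines the
    ideal focus position in stacks lacking human-comprehensible visual
    anchors, five focus-curve quality criteria (accuracy, unimodality,
    width at 50% and 90% of maximum, smoothness) with a Euclidean overall
    score and per-family ranking tables, plus a synthetic through-focus
    stack generator with known ground truth (defocus blur law, detector
    noise, Poisson-noise and nonuniform-illumination robustness
    protocols) so the whole pipeline can be exercised without instrument
    data.  Stacks are read and written as ENVI raw/header pairs or
    multi-page TIFF with a JSON position manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
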