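Package: calcimech
Title: Quantification of Calcium Transients, AFM Nanoindentation and
    Patch-Clamp Recordings in Chondrocyte Mechanobiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipelines for three measurement modalities used to
    characterise TRPV4 channel function in chondrocytes: ratiometric
    calcium-imaging transient quantification (watershed cell segmentation,
    responder classification by a baseline mean + 3 SD rule, response
    latency, and peak-filtered area under the curve), AFM force-curve
    analysis (contact-point extrapolation and spherical-indenter Hertz
    modulus fitting with cantilever-deflection correction), and patch-clamp
    summary statistics (current density, basal-minus-inhibited current
    differences, and unitary-current estimation from amplitude histograms).
    A synthetic-data generator produces traces, two-channel image stacks,
    force curves and single-channel records with known ground truth for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite
Suggests:
    mclust,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'synth-traces.R'
    'synth-stack.R'
    'synth-curve.R'
    'synth-patch.R'
    'trace-metrics.R'
    'imaging.R'
    'indentation.R'
    'ephys.R'
    'stats-util.R'
    'io.R'
    'pipeline.R'
    'calcimech-package.R'
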