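Package: thermoderm
Title: Melanoma Detection from Dermoscopy Images via Thermal Exchange
    Optimization and Extreme Learning Machines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated pipeline for discriminating malignant melanoma
    from benign pigmented lesions in dermoscopy images. Implements the
    Thermal Exchange Optimization (TEO) metaheuristic and a developed
    variant (dTEO) with a sinusoidal chaotic stream and Gaussian mutation;
    an Extreme Learning Machine classifier whose per-neuron sigmoid
    activation parameters are tuned by dTEO; lesion segmentation by Otsu
    thresholding of normalized red and CIE-X channels with morphological
    cleanup; statistical, geometric, co-occurrence texture and invariant
    moment feature extraction; wrapper feature selection driven by the
    Matthews correlation coefficient; a benchmark-function validation
    suite; and a synthetic dermoscopy image generator for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    mgcv,
    png,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
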