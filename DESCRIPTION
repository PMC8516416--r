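Package: sopquant
Title: Quantification of Notch and Bazooka Clusters at the Sensory Organ
    Precursor Daughter Interface
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-quantification pipeline for fluorescence time-lapse
    recordings of Drosophila sensory organ precursor (SOP) daughter cells.
    Builds interface-intensity kymographs with reference-region
    photobleaching correction, counts inter-nuclear protein clusters with a
    Renyi-entropy autothreshold and printed size and intensity filters,
    measures two-channel co-movement on kymographs with Costes
    autothresholds and thresholded Manders coefficients, fits
    single-exponential fluorescence recovery after photobleaching (FRAP)
    curves, quantifies fixed-size interface regions normalised to epidermal
    references, and reports group comparisons with an F-test-then-t-test
    convention. A seeded synthetic-data generator with planted ground truth
    emulates the imaging so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
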