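Package: alseg
Title: Pool-Based Active Learning for Radiograph Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pool-based active learning for pixel-wise semantic segmentation of
    hip radiographs (femoral head and acetabulum). Implements five acquisition
    queries - random, K-Means++ cluster-based diversity, centroid-distance
    representativeness, class-wise Shannon entropy over Monte Carlo Dropout
    ensembles, and their Borda-count fusion - together with the
    retrain-from-scratch active-learning cycle, dice and dice+focal objectives,
    a synthetic two-bone hip-phantom generator with three-channel binary masks,
    and a small dropout-capable reference segmenter so the full experiment runs
    on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
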