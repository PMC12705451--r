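Package: aquaqc
Title: Autonomous Quality and Hallucination Assessment for Virtual Tissue Staining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control for generative virtual staining of label-free
    tissue images. Implements forward (autofluorescence to stain) and backward
    (stain to autofluorescence) transform networks trained with composite
    adversarial losses, iterative cycle inference between the two image
    domains, an ensemble temporal classifier producing per-image accept/reject
    confidence scores, model-level gating by a linear discriminant threshold,
    a full scalar metric suite (mean squared error, Pearson correlation,
    peak signal-to-noise ratio, pooled t statistics, binned Kullback-Leibler
    divergence, Hellinger distance, G-tests, ROC and precision-recall curves),
    and hand-crafted histochemical quality metrics based on stain-vector
    colour deconvolution and nuclei segmentation. A seeded synthetic
    paired-histology generator makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
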