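Package: lesionmorph
Title: Morphometry and Statistics for Radiofrequency Ablation Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies radiofrequency catheter-ablation lesions from
    photographs of ex vivo cardiac tissue and analyses how catheter contact
    force, contact angle and contact area determine lesion area and depth.
    Ships the published 5-angle by 8-force measurement grid (lesion area,
    lesion depth and lesion-area to contact-area ratios) as versioned CSV
    fixtures, recovers the contact-area grid by inverting the ratios, and
    implements the image pipeline (calibration, segmentation, grayscale
    conversion, 40 percent-of-white thresholding, hole filling, region
    moments, major-axis alignment, depth measurement, morphology
    classification) together with a ground-truth synthetic lesion-photograph
    generator and the study's statistics: Pearson and Spearman correlation
    with t-distribution p-values and Evans labels, a balanced-design
    replicate-level correlation reconstruction, logarithmic versus linear
    least-squares comparison, and pooled t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
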