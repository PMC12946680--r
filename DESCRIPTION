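Package: petalfall
Title: Color-Calibrated Petal Phenotyping and Hierarchical Abscission Funnels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative phenotyping of floral abscission in
    ornamental cherries and similar perennials. Implements a six-patch
    color-chart calibration stage (3x3 linear correction matrix fitted by
    least squares on patch means), a dominant-petal-color pipeline (Gaussian
    smoothing, polygonal region-of-interest masking, HSV value filtering,
    exact top-k color counting, hue-sorted palette bars), a stage-wise
    abscission "funnel" that classifies per-flower fates into sequential
    gates (petal, flower pedicel-peduncle, calyx, fruit pedicel-peduncle,
    peduncle-branch) and summarizes retention proportions and event timing,
    the nonparametric and Welch group comparisons used alongside such data,
    and a synthetic-data module producing ground-truthed chart/petal images
    and simulated flower cohorts so the whole pipeline is verifiable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    tools,
    utils,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
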