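Package: fetalt2star
Title: Fetal Lung T2* Relaxometry, Normative Modelling and Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis pipeline for multi-echo gradient-echo MRI of
    the fetal lungs. Simulates digital thorax phantoms and multi-echo magnitude
    images with Rician noise, performs voxelwise mono-exponential T2* mapping
    (log-linear and bounded non-linear least squares), computes per-lung region
    statistics (mean T2*, volume, histograms), gliding-box lacunarity as a
    tissue-heterogeneity score, gestational-age normative models with z-scores
    and centiles (including the published fetal lung T2* reference model), and
    observer reliability via absolute-agreement two-way mixed-effects
    intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    minpack.lm,
    sandwich,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
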