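Package: ctperf
Title: Phantom-Based Comparison of Flat-Panel and Multidetector CT Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates 4D contrast-enhanced CT perfusion acquisitions of a
    digital brain phantom under a fast multidetector protocol (30 phases in
    about 48 s) and a slow flat-panel C-arm protocol (10 rotational sweeps at
    6 s pitch with two mask runs), computes Tmax, TTP, CBF, CBV and MTT maps
    by block-circulant truncated-SVD deconvolution, segments hypoperfusion and
    infarct-core volumes by absolute Tmax, relative CBF and hemispheric
    median-normalization thresholds, and quantifies between-protocol agreement
    with Pearson correlation, intraclass correlation, Bland-Altman limits of
    agreement, mixed-model method contrasts and Wilcoxon-Mann-Whitney tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    lme4,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
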