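Package: dwinlm
Title: Non-Local Means Denoising and Quality Metrics for Diffusion-Weighted MR Phantom Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for optimizing patch-based denoising of breast
    diffusion-weighted magnetic resonance (DWMR) images. Simulates
    tissue-mimicking phantom image series with mono-exponential b-value
    decay and Rician noise, denoises with non-local means (direct,
    Gaussian-weighted, and integral-image accelerated variants) and with
    median, adaptive Wiener, and total-variation comparators, quantifies
    image quality with region-of-interest SNR, CNR, and apparent diffusion
    coefficient estimates, and sweeps the non-local means smoothing factor
    to locate the optimum balancing noise suppression against resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
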