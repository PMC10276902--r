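Package: admixwave
Title: Wavelet Decomposition of Local Ancestry and Recombination Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximal-overlap discrete wavelet transform (MODWT) methods with Haar
    wavelets for decomposing genomic signals (local ancestry proportion,
    recombination rate) into per-scale variance and correlation components,
    with chromosome-length-weighted genome-wide summaries, among-chromosome and
    scaling components, and weighted block-jackknife confidence intervals.
    Includes preprocessing of irregular genomic tracks onto even physical or
    genetic grids (diploid ancestry dosage, recombination-map unit conversion),
    a forward Wright-Fisher junction simulator of admixed populations under
    drift and polygenic selection against introgressed ancestry, and the
    coalescent expectation of the neutral ancestry wavelet variance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
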