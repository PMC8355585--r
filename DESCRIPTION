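Package: glyquant
Title: Quantitation of Stable-Isotope-Labeled Glycans from MALDI-MS Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for duplex stable-isotope-labeling glycan quantitation
    from MALDI-MS ASCII peak lists. Builds combinatorial N-glycan composition
    databases with derivatization and adduct arithmetic, computes theoretical
    isotope patterns by elemental convolution, centroids profile spectra by
    Gaussian fitting, groups centroids into charge-assigned isotope envelopes,
    exhaustively matches envelopes to glycan candidates, pairs light with
    heavy channels, and reports abundance ratios corrected for isotopic
    overlap between the light channel's higher isotopologues and the heavy
    channel's quantitation peak. Includes a synthetic-spectrum generator so
    every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
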