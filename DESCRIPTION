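Package: fermadm
Title: Fermatean Fuzzy Dynamic Multi-Attribute Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-attribute decision making (MADM) with Fermatean
    fuzzy evaluations collected over several time periods. Provides the
    Fermatean fuzzy number algebra (score, accuracy, indeterminacy, comparison
    and complement), the dynamic weighted averaging and geometric aggregation
    operators (FFDyWA/FFDyWG) together with their per-period counterparts
    (FFWA/FFWG), a two-stage ranking pipeline over an alternatives x attributes
    x periods decision tensor, intuitionistic fuzzy dynamic baselines for
    comparison, JSON/CSV readers and writers for decision tensors and ranking
    reports, a seeded synthetic tensor generator, and a command-line interface.
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
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
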