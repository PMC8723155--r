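Package: sgtree
Title: Clinical Subgroup Identification on Hierarchical Clustering Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clinical subgroups of samples in omics datasets by
    hierarchically clustering the samples, enumerating every branch point
    whose left and right subclusters are both above a minimum size, testing
    each such cluster pair against every clinical outcome with an
    automatically dispatched statistical test (Fisher's exact test for
    categorical outcomes, Welch's t-test for continuous outcomes, the
    log-rank test for survival outcomes, or user-supplied test functions),
    applying Bonferroni correction over the number of valid cluster pairs,
    and rendering annotated dendrogram visualizations. Multiple omics blocks
    can be combined by max-normalized distance-matrix fusion. A planted
    subgroup simulator generates fully synthetic benchmark datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    patchwork,
    survival,
    ape,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
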