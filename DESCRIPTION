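Package: slodr
Title: Strategic Slicing and the Criteria of Spearman's Law of Diminishing Returns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Examines how two structural-equation criteria of Spearman's law
    of diminishing returns (SLODR) - negatively skewed latent ability and a
    positive correlation between latent ability and within-individual
    residual variance - depend on the correlation between within-individual
    mean performance and within-individual variability. Provides strategic
    slicing of a sample into stripes of the mean-variability plane to
    manipulate that correlation, a maximum-likelihood single-factor model
    with regression factor scores and fit indices, per-cell SLODR criterion
    evaluation with a size-weighted joint probability, and a synthetic
    score generator with controllable mean-variance coupling, skewing,
    censoring and disturbance so the full pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
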