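Package: millisplit
Title: Multiplicative (Binary-Splitting) Models of Millipede Trunk Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generative and inferential tools for the multiplicative model of
    millipede trunk segmentation, in which a small number of embryonic primary
    segments subdivide through cycles of binary splitting into 2^n definitive
    ventral units. Provides a generative model (splitting specifications with
    dyadic positional markers, anterior truncation, and taxon-specific gonopod
    vocabularies), a body-plan layer mapping leg pairs to dorsal rings (collum,
    haplosegmental rings, diplosegments, fusion anomalies), encodings of
    published normal and homeotic specimens, dyadic-consistency inference
    (run decomposition, splitting-cycle estimation, exhaustive anchor/node/block
    fitting, parsimony comparison against a sequential-determination null), and
    seeded synthetic-phenotype generators for measuring the classifier's
    discrimination between the two segmentation models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
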