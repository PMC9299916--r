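Package: moaclust
Title: Clustering and Network Analysis of Multiple Herbicide Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing co-occurrence of herbicide resistance across
    modes of action (MoAs). Builds binary species-by-MoA incidence matrices
    from resistance records, consolidates them by merging related HRAC groups
    and filtering to multi-resistant species and well-represented MoAs,
    computes Jaccard proximities between MoAs, clusters MoAs by
    complete-linkage agglomeration with elbow and balance-based selection of
    the number of clusters, constructs prevalence- and proximity-weighted MoA
    networks, and provides summary statistics (per-species MoA counts, Mood's
    median test, prevalence versus multi-resistance correlation). Includes a
    planted-partition generator of synthetic resistance matrices for
    validation, and bundles the published ten-MoA Jaccard proximity matrix as
    a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    ape,
    xml2,
    withr,
    optparse
Config/testthat/edition: 3
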