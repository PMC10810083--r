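Package: cofluct
Title: Edge Time Series, High-Amplitude Co-Fluctuation Events, and
    Structural Modularity
Version: 0.1.0
Authors@R:
    person("cofluct", "maintainers", email = "maintainers@cofluct.dev",
           role = c("aut", "cre"))
Description: Edge-centric analysis of parcellated neural time series.
    Decomposes nodal signals into edge co-fluctuation time series whose
    temporal mean is exactly static functional connectivity, detects
    statistically significant high-amplitude "events" in the root-mean-square
    co-fluctuation amplitude against circular-shift surrogates with FDR
    control, clusters event co-fluctuation patterns with Lin's concordance and
    recursive consensus modularity maximization, extracts the bipartition each
    cluster centroid induces, and tests that bipartition's induced modularity
    on a directed weighted structural connectome against independent and
    geometry-preserving permutation nulls. Includes a planted-structure
    synthetic data generator so every stage is verifiable without imaging
    data, plus file readers/writers and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
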