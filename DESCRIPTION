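Package: rangeOverlap
Title: Kernel Home-Range Overlap Analysis for Territorial Social Carnivores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying territory overlap between neighbouring
    social-carnivore groups from GPS telemetry. Implements fixed-kernel
    utilisation distributions with the reference (hRef) bandwidth, 50/75/95
    percent isopleth extraction on a raster grid, directional dyadic overlap,
    exclusive-kernel utilisation intensity, time spent in overlap zones,
    rank-based group comparisons (Mann-Whitney, Kruskal-Wallis, Tukey-type
    pairwise comparisons on ranks), and AICc-based multimodel inference with
    random-intercept linear mixed models fitted by profiled maximum
    likelihood. Includes an Ornstein-Uhlenbeck movement simulator with
    closed-form isopleth and overlap oracles for validation, and an
    end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
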