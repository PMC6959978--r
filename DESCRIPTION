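Package: telocorrect
Title: Division Orientation Analysis and Simulation of Telophase Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification and simulation of mitotic division orientation in
    stratified epithelia. Provides the angle geometry and binning conventions
    used to score planar, oblique and perpendicular divisions relative to the
    basement membrane; distribution statistics (radial histograms, cumulative
    frequency distributions, Kolmogorov-Smirnov uniformity and two-sample
    tests, categorical chi-square tests); per-division telophase-correction
    statistics conditioned on basal contact; a stochastic two-step simulator
    of division orientation (LGN-biased anaphase entry followed by
    basal-contact-dependent telophase correction) with genotype presets;
    synthetic ground-truth micrograph generators and the corresponding image
    metrics (junction continuity, orthogonal linescans, background-subtracted
    channel ratios, radial cortical profiles, tissue stratification metrics);
    and clonal lineage-tracing fate classification with density arrays and a
    clone simulator.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
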