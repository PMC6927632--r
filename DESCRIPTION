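Package: streamstatus
Title: Multimetric Stream Bioassessment and Abundance Versus
    Presence/Absence Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A configurable multimetric engine for benthic-invertebrate
    stream bioassessment in the Water Framework Directive tradition:
    saprobic index, class-weighted fauna-index family, richness and
    proportion metrics, module aggregation with the worst-of rule, and
    five-band ecological status classification. On top of the engine it
    implements a full comparison of abundance-based and
    presence/absence-based assessment: paired assessment, ordinal
    class-deviation cross-tabulation and congruence statistics,
    abundance-contribution analysis of the general degradation module,
    and zero-truncated Poisson resampling that propagates within-site
    abundance uncertainty into percentile confidence intervals. A
    trait-structured synthetic community generator makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
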