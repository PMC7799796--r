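Package: caregap
Title: Spatial Accessibility Gap Analysis for Residential and Day-Care Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-phase pipeline for locating gaps in the spatial
    accessibility of care services for older adults across a hierarchy of
    regions, districts and municipalities. Phase one computes multimodal
    travel-time reachability of residential homes and day-care/day-services
    centres, by road shortest paths (individual transport) and by filtered,
    score-ranked public-transport timetable connections. Phase two converts
    reachability into recipient-weighted coverage indicators within 30- and
    60-minute budgets and assigns each district a three-tier accessibility
    class (good / lowered / poor). Phase three ranks districts with TOPSIS
    closeness scores and examines associations between demand, capacity and
    accessibility with Pearson correlations and bootstrap percentile
    confidence intervals. A seeded synthetic-region generator produces study
    areas with planted, known gap classes for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
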