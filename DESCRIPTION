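Package: locohcv
Title: Time-Scaled Local Convex Hull Home Ranges with Cross-Validated
    Parameter Selection
Version: 0.1.0
Authors@R:
    person("locohcv", "maintainers", email = "locohcv@example.org",
           role = c("aut", "cre"))
Description: Home-range estimation for animal GPS trajectories using
    time-scaled local convex hulls (T-LoCoH). Each fix is surrounded by
    the convex hull of its k nearest neighbours under a time-scaled
    distance with scaling factor s; the collection of normalized hulls is
    interpreted as a probability density, and the (k, s) pair maximizing
    the total log probability of held-out points is selected by a
    coarse-to-fine grid search. Includes utilization-distribution
    isopleths, revisitation (NSV) and visit-duration (MNLV) metrics, a
    seeded multi-patch trajectory simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
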