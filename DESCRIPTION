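Package: planktomaps
Title: Discrete-Time Phytoplankton-Zooplankton Maps: Stability, Bifurcation and Chaos Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for a toxin-modified phytoplankton-zooplankton model with
    Holling type-II grazing and its discrete-time counterparts: the forward-Euler
    map, a positivity-preserving nonstandard finite difference (Mickens) map and a
    hybrid-controlled map. Provides fixed points with existence conditions and
    boundedness bounds, Jury-criterion stability classification, Neimark-Sacker
    normal-form analysis (first Lyapunov quantity and bifurcation direction),
    period-doubling analysis via center-manifold reduction, hybrid chaos-control
    stability regions, orbit iteration, maximal Lyapunov exponents, and
    bifurcation-diagram and parameter-region scan tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
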