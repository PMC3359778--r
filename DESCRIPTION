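Package: shimmerwave
Title: Single-Agent Analysis of Shimmering-Wave Propagation in Giant Honeybee Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how shimmering waves propagate across the surface
    of Giant honeybee (Apis dorsata) nests, one agent bee at a time. Provides a
    frame-differencing motion-energy metric over per-bee regions of interest,
    onset (time-zero) detection of abdomen-flipping wave incidents, wave-strength
    categorization, angular-sector neighbourhood statistics with trigger-neighbour
    assignment, and the three bucket-bridging test statistics (linearity,
    continuity, graduality) together with ensemble time courses, transfer-time and
    propagation-speed estimation. An agent-based excitable-media simulator with a
    refractory period generates synthetic lattices, waves with known trigger
    ground truth, and rendered grayscale frame stacks, so the whole pipeline is
    testable end to end without field video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
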