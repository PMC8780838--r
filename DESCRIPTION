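Package: sensorgraph
Title: Sensor Graphs for In-Home Mobility Performance Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-day weighted directed multigraphs (room-transition
    adjacency matrices) from passive-infrared motion-sensor event streams
    recorded in the flats of older adults living alone, quantifies each day's
    activity as a weighted percent difference from a baseline graph, filters
    participants and absence days, and fits and compares group-level linear
    activity trends. Includes a semi-Markov resident simulator that generates
    synthetic event logs, flat topologies, participant statuses and geriatric
    assessment records with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
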