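Package: healthpass
Title: Contactless Check-In Records, Visitor Liability Scoring, and
    Adaptive Venue Access Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing anonymous venue check-in/check-out record
    streams during a public-health crisis and for the adaptive access-control
    models built on them: radar-map visitor liability scoring from voluntary
    six-item forms, venue availability estimation from member, propagation and
    crowdedness risks, per-class mean waiting times in the M/M/s
    non-preemptive priority queue with a discrete-event validation simulator,
    an agent-based venue-compartment epidemic replay with flatten-the-curve
    metrics, a synthetic campus generator with Poisson arrivals and
    exponential dwell times, and System Usability Scale survey scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
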