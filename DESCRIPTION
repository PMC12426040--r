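Package: pdfsm
Title: Finite-State-Machine Controller for an Automated Peritoneal Dialysis Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A verifiable software model of a clocked finite-state-machine
    controller for an automated peritoneal dialysis machine. Provides a
    ternary (0/1/don't-care) transition-table engine over a 5-bit state
    register and 16 boolean sensor/button inputs; sum-of-products synthesis
    of the five D flip-flop excitation functions with exhaustive equivalence
    checking over all 2^21 (state, input) assignments; a discrete-time
    session simulator with synthetic sensor traces, turbidity-based cycle
    termination, timed delay states and fault injection; safety-property
    verification (fault-to-alarm, alarm recovery, unused-code trap) and
    reachability analysis; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
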