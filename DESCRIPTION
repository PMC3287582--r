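Package: npdl
Title: Process-Algebra Workflow Engine for Genetic-Testing Management
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A process-aware laboratory information management core for genetic-testing
    laboratories. Laboratory tests are defined as lists of procedures with execution-order
    priorities, compiled into control-flow expressions of an ACP-style process algebra
    (sequence, choice, parallel merge, interleaved parallel routing, multi-merge,
    discriminator, bounded and unbounded repetition, guarded execution), formally checked
    by bounded trace enumeration, and interpreted to release, track and complete wet-lab
    steps for individual samples. Includes a concrete textual syntax with parser and
    serializer, an execution engine with an event-sourced instance log, a file-backed
    relational process repository with procedure- and disease-filtered work queues, and
    seeded generators of random expressions and synthetic laboratory workloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
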