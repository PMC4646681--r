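Package: patchadapt
Title: Convergent Local Adaptation to Patchy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Theory and simulation machinery for convergent (parallel) local
    adaptation in continuous patchy landscapes. Provides closed-form rates of
    adaptation by new mutation and by migration under migration-selection
    balance, the probability of parallel adaptation as a function of
    inter-patch distance, killed-Brownian-motion transit-time and
    hitchhiking-haplotype-length distributions, numerical establishment
    probability profiles for spatial branching processes on a deme lattice,
    steady-state migration-selection cline solvers, a forward-time
    individual-based deme-lattice simulator with backward lineage tracing, and
    a multi-patch colonization Markov chain with its Ewens-sampling
    island-model limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
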