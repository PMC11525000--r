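Package: curiomaze
Title: Intellectual Curiosity as Pattern Matching in a Production-System
    Cognitive Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal production-system cognitive engine (chunks, buffers,
    noisy declarative retrieval, softmax conflict resolution, utility learning,
    production compilation) together with a mechanism of intellectual
    curiosity: pattern-matching productions trigger intrinsic reward, task
    continuation is decided by utility-based conflict resolution between
    continue and stop rules, and boredom emerges as production compilation
    removes opportunities for pattern matching. Includes loop-less grid maze
    generation with topological chunk encoding, three maze-search agents
    (random walk, stochastic depth-first search with a chunk stack, and
    depth-first search plus instance-based learning), five outcome indicators
    (up-time ratio, rounds, normalized state-visit entropy, goal rate, newly
    compiled productions), a curiosity-driven actor-critic reinforcement
    learning baseline with a forward-model intrinsic reward, and a factorial
    simulation driver with deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
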