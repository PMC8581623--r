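Package: oligokin
Title: Oligomerization Kinetics of Membrane Receptors from Multi-Copy
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies membrane-receptor oligomerization from multi-copy
    coarse-grained trajectories. Detects oligomers by single-linkage
    clustering of minimum inter-protein distances, counts association and
    dissociation events, clusters oligomer quaternary structures with a
    permutation-invariant RMSD reordering, estimates residence times by
    fitting biexponentials to normalized survival functions with bootstrap
    uncertainties, detects lipid binding sites from dual-cutoff head-group
    contacts via residue-interaction-graph community analysis, and builds
    Markov state models over whole-membrane oligomerization states
    (transition matrices, implied timescales, mean first passage times,
    state lifetimes). Includes a Brownian association/dissociation
    simulator that generates ground-truth-annotated synthetic trajectories
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    igraph,
    minpack.lm
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
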