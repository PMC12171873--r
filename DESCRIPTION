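Package: igmepath
Title: Non-Markovian State Models and Self-Organizing-Map Pathway
    Detection for Transporter Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of membrane-transporter molecular-dynamics
    trajectories with non-Markovian state models and neural-map pathway
    detection.  Builds microstate Markov state models from featurized
    trajectories (chi1 dihedrals, inter-helix distances) via time-lagged
    independent component analysis and k-means, lumps them into metastable
    macrostates with PCCA+, and fits an integrative generalized master
    equation (IGME) long-time propagator validated by Chapman-Kolmogorov
    tests, with mean first passage times and transition-path-theory net
    flux pathways.  Ligand egress routes are detected by training a sheet
    self-organizing map on capped ligand-residue distances, clustering
    neurons by silhouette, and reading pathways off the neuron transition
    network.  Includes seeded synthetic generators (lumped hidden Markov
    chains, Langevin egress in a branching channel, constructed rotamer
    frames) with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    cluster,
    igraph,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
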