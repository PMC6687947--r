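Package: rbmycnv
Title: Copy Number Variation of the RBMY1 Gene Family from Read Depth,
    Phylogenies and Droplet Digital PCR
Version: 0.1.0
Authors@R: person("rbmycnv", "developers", role = c("aut", "cre"),
    email = "rbmycnv@example.org")
Description: Tools for estimating multi-copy gene-family copy number from
    sequencing read depth under a read-pooling (mismapping) model, calibrating
    depth-derived estimates against fibre-FISH gold standards by ordinary
    least squares, counting copy-number change events on a Y-chromosomal
    SNV phylogeny by unit-cost parsimony, converting SNV-calibrated branch
    lengths into per-transmission mutation rates with confidence intervals,
    testing for directional and stabilizing selection with exact binomial
    tests and neutral Monte-Carlo simulation on the phylogeny, and
    quantifying copy number from two-channel droplet digital PCR counts via
    Poisson statistics. Includes a synthetic-data generator that emulates
    every input with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
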