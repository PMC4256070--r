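Package: cngdyn
Title: Coarse-Grained Elastic Network Analysis of Cyclic Nucleotide-Gated
    Channel Models
Version: 0.1.0
Authors@R:
    person("cngdyn", "developers", email = "cngdyn@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating and analysing Calpha-level structural
    models of cyclic nucleotide-gated (CNG) ion channels and related
    tetrameric assemblies.  Builds Gaussian (GNM) and anisotropic (ANM)
    elastic network models, decomposes them into normal modes, and derives
    residue fluctuations, cross-correlations, hinge regions, mode-displaced
    "edge" conformations and domain rotation angles.  Scores structural
    models against ranked evolutionary-coupling tables (top-2L/3 contact
    overlay, cutoff scans, alternative-model discrimination), against
    conservation and hydrophobicity versus residue burial, and computes
    simplified on-axis pore-radius profiles.  Ships deterministic
    synthetic-data generators (toy networks with closed-form spectra,
    C4-symmetric helix bundles, coupling tables with planted precision,
    conservation tracks with planted burial correlation, and a synthetic
    cone-channel heterotetramer) so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
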