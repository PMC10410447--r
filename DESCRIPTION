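Package: cdrcage
Title: Steric Constraints on Antibody CDR-H3 from Light-Chain Loop Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how the light-chain (VL) complementarity-determining
    region (CDR) loops sterically constrain the heavy-chain CDR-H3 loop in
    antibody Fv structures. Provides an IMGT-numbered Fv domain model with
    crystal-set filtering rules, inter-loop radial distribution functions and
    minimum heavy-atom distances with per-bin comparison statistics,
    length-independent CDR-H3 comparison by anchor-superposed dynamic time
    warping, stratified bootstrap tests of CDR-H3 conformational diversity,
    post-processing of biased (metadynamics) conformational ensembles
    (Boltzmann reweighting, RMSF, native-conformation fractions,
    average-linkage frame clustering), discovery and comparison of
    identical-VH/divergent-VL structure pairs, synthetic Fv and ensemble
    generators with known ground truth, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
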