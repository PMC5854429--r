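Package: unspool
Title: Free-Energy Profiles for Nucleosomal DNA Unwrapping from Adaptive-Bias
    and Umbrella Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate potentials of mean force along a DNA end-to-end
    distance reaction coordinate with multi-walker adaptively biased (flooding)
    sampling followed by umbrella-sampling refinement and a self-consistent
    weighted histogram analysis (WHAM) under a combined adaptive plus harmonic
    bias.  Includes reweighting of the unbiased ensemble onto structural
    coordinates (number of unwrapped base pairs, two-dimensional landscapes),
    structural observables for nucleosome unwrapping (per-end unwrapped counts,
    residue contact ratios, end-asymmetry distributions, stage stitching), and
    a synthetic-system module: analytic one-dimensional potentials with exact
    free energies, a Langevin (BAOAB) integrator, and a coarse bead-on-spool
    nucleosome mimic whose site-unbinding free energies are exactly enumerable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
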