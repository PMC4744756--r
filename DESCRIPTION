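Package: hairpinfold
Title: Hydrogen-Bond Pattern Analysis of Beta-Hairpin Folding in MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of molecular dynamics trajectories of beta-hairpin
    peptides. Classifies the four interstrand backbone hydrogen bonds of a
    hairpin as open or closed in every frame using distance and angle criteria,
    assigns each frame a 4-character conformational fingerprint, and estimates
    per-pattern populations, mean hydrogen-bond distances, a folded/unfolded
    classification, and overall folding ratios. Frame-to-frame pattern
    transitions are summarised as row-normalised population change maps from
    which the most probable folding pathway is extracted by a greedy walk.
    Includes a synthetic trajectory generator (Markov chain over patterns with
    pattern-conditional geometry emissions) so every stage of the pipeline can
    be validated against analytic ground truth without running simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
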