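Package: enmexplore
Title: Iterative Elastic-Network Conformer Generation for Large
    Apo-to-Holo Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unbiased generation of protein conformer ensembles spanning
    large apo-to-holo transitions. Slow modes of a contact-weighted
    anisotropic elastic network are linearly combined and applied as
    fixed-magnitude deformations to an all-atom structure; deformed
    conformers are relaxed, clustered at a fixed RMSD radius, and
    representatives are iterated over generations with full lineage
    tracking. Radius-of-gyration and energy filters select close-to-bound
    and intermediate states, and parent chains are exported as
    multi-model PDB ensembles for docking. Includes a synthetic
    two-domain hinge-protein generator so the whole pipeline is testable
    without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
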