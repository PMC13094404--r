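Package: pocketmorph
Title: Gyration-Tensor Morphometrics of Ligand-Binding Pockets
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts ligand-proximal binding pockets from macromolecular
    structures (PDB/mmCIF), computes size-independent shape-anisotropy
    descriptors from the eigenvalues of the gyration (second-moment) tensor,
    classifies pockets into four median-anchored morphological archetypes
    (sphere-like, rod-like, disk-like, strongly anisotropic), and provides
    the comparative statistics used to contrast RNA and protein pocket
    cohorts: Welch tests with Holm or Benjamini-Hochberg correction, Cohen's
    d effect sizes, two-group MANOVA with Pillai's trace, chi-square tests
    of archetype occupancy, unweighted Euclidean distances in eigenvalue-
    ratio space, and stratified bootstrap assessment of partition stability
    via the adjusted Rand index. Includes seed-deterministic generators for
    synthetic pocket point clouds, toy structure fixtures, and descriptor
    cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
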