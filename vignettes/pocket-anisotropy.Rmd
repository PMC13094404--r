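---
title: "Gyration-tensor morphometrics of ligand-binding pockets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gyration-tensor morphometrics of ligand-binding pockets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketmorph)
```

## The problem

Small-molecule binding sites on proteins and on structured RNAs can be
compared geometrically without any reference to sequence or chemistry by
treating each pocket as a bare 3-D point cloud of heavy atoms.
`pocketmorph` implements that program end to end: pocket extraction from a
ligand-bound structure, a scale-free shape description based on the
gyration tensor, a four-class morphological typology, and the statistical
battery needed to compare two pocket cohorts (typically RNA vs protein).

## Pocket definition

A pocket is the set of *complete residues* having at least one heavy atom
within a cutoff (default 6 Å, inclusive `d <= cutoff`) of any heavy atom of
the bound ligand. Before extraction, structures are cleaned: waters
(HOH/WAT/DOD) and monoatomic ions (configurable list) are removed, hydrogen
and deuterium atoms are dropped unless explicitly retained, only the first
model of a multi-model file is used, and for alternate locations only the
first listed conformation is kept (the *first listed*, which is not always
the one labelled "A").

Choices worth noting:

* **Inclusive cutoff.** "Within 6 Å" is implemented as `d <= 6`; the
  boundary case is rare in real coordinates but the convention is fixed and
  tested.
* **Polyatomic ions are retained.** The ion filter targets monoatomic
  species (NA, K, MG, CA, ZN, CL, ...). Groups such as PO4 or SO4 are kept
  by default because they are part of the structural context; the list is a
  function argument for users who disagree.
* **Hydrogen sensitivity.** With `keep_hydrogens = TRUE` the pocket's
  *atoms* include hydrogens but pocket *membership* is always decided on
  heavy-atom distances, so both representations describe the same set of
  pocket-defining residues. This isolates the effect of hydrogen inclusion
  on the descriptors from any change in pocket definition.
* **Atom-level mode** (`level = "atom"`) returns only the individual heavy
  atoms inside the cutoff. It exists for sensitivity analyses; atom-level
  clouds can be fragmented and are not recommended as the primary
  representation.

## Shape descriptors

For a pocket with heavy-atom coordinates \(x_1,\dots,x_N\) (N >= 4), the
gyration tensor is

\[ T = \frac{1}{N} \sum_{i=1}^{N} (x_i - \bar x)(x_i - \bar x)^{\top}, \]

with all atoms weighted uniformly — no masses, no atom types — so the
description is purely geometric. Its eigenvalues
\(\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0\) (Å²) measure dispersion
along the principal axes. Because raw eigenvalues scale with pocket size,
shape is described by the bounded ratios

\[ rEV21 = \lambda_2/\lambda_1, \qquad rEV32 = \lambda_3/\lambda_2, \qquad
   rEV31 = \lambda_3/\lambda_1, \]

each in \([0, 1]\) with 1 = isotropy, and with the algebraic identity
\(rEV31 = rEV21 \cdot rEV32\). Size is carried separately by the atom count
and the radius of gyration \(R_g = \sqrt{\lambda_1+\lambda_2+\lambda_3}\).

The `1/N` normalization (rather than `1/(N-1)`) is deliberate: ratios are
unaffected either way, and `1/N` makes \(R_g\) coincide exactly with the
root-mean-square distance of atoms to their centroid.

Degenerate inputs are flagged, not hidden: fewer than 4 atoms is an error
at tensor time and a `degenerate` flag at extraction time; coplanar clouds
yield \(\lambda_3 = 0\) and are computed normally; collinear clouds
(\(\lambda_2 = 0\)) set `rEV32 = 0` with a warning; negative eigenvalue
round-off below 1e-12 is clamped to zero.

```{r descriptors-example}
cloud <- sample_cloud(5000, sigma = c(9, 4, 1), seed = 1)
shape_descriptors(cloud)[, c("rEV21", "rEV32", "rEV31", "Rg", "n_atoms")]
```

## The four archetypes

Pockets are partitioned in the \((rEV21, rEV32)\) plane by the *global
medians* of the pooled reference cohort, fitted with `fit_thresholds()`:

| rEV21    | rEV32    | archetype              |
|----------|----------|------------------------|
| >= m21   | >= m32   | sphere-like            |
| <  m21   | >= m32   | rod-like               |
| >= m21   | <  m32   | disk-like              |
| <  m21   | <  m32   | strongly anisotropic   |

Ties land on the "high" (isotropic) side; the rule is covered by a
dedicated test, since a median-anchored scheme routinely puts points
exactly on a threshold. `rEV31` is never used for assignment (it is
determined by the other two); it re-enters below as the third coordinate of
the continuous distance space. `classify_pockets()` also records each
pocket's `boundary_margin`, the smallest ratio perturbation that could
change its label.

Because the thresholds are data-adaptive, their sampling variability is the
partition's main fragility. `bootstrap_stability()` quantifies it by
stratified resampling: each group is resampled with replacement at its
original size, thresholds are refitted on the pooled resample, and the
resampled pockets are classified under both the refitted and the original
thresholds. Agreement per replicate is scored with the adjusted Rand index
and the fraction of relabelled pockets. This pairing convention —
replicate labels vs reference-threshold labels *on the same resample* —
isolates threshold variability, which is exactly what the reported metrics
(threshold SDs, reclassification rate) describe. Per-replicate seeds are
drawn once from the master seed, so reports are bit-reproducible.

## Continuous distances

Morphometric similarity between two pockets is the unweighted Euclidean
distance between their \((rEV21, rEV32, rEV31)\) triples. `rEV31` is
included despite its dependence so that overall anisotropy contributes to
the metric; no reweighting is applied. `distance_summary()` aggregates all
pairwise distances into the (group x archetype) block layout: diagonal
blocks average unordered distinct pairs (compactness), off-diagonal blocks
average all cross pairs, self-pairs never contribute, and no centroid
shortcut is used. Group-level summaries report mean, SD and the 5th
percentile; the percentile uses R's default linear-interpolation quantile,
a convention we fix explicitly because "lower 5% quantile" admits several.

## Statistical battery

`compare_groups()` assembles the full comparison of two cohorts:

* **Univariate:** Welch's unequal-variance t tests per descriptor, with
  Holm correction applied *separately* to the shape family
  (rEV21, rEV32, rEV31) and the size family (atom count, Rg); Cohen's d
  with the pooled-SD denominator (equal-n form
  \(\sqrt{(s_1^2+s_2^2)/2}\)), direction group1 − group2. The pooled-SD
  choice is the one that reproduces published effect sizes exactly from
  summary statistics, which is also why a summary-input mode
  (`summary_stats()`) exists alongside raw vectors.
* **Multivariate, per archetype:** one-factor MANOVA on the two independent
  ratios (rEV21, rEV32) with Pillai's trace; rEV31 is excluded from the
  multivariate model because it is algebraically dependent. Box's M is
  computed as a covariance-homogeneity diagnostic and reported only — no
  automatic gate, since a marginal heterogeneity should be judged, not
  silently acted on. Univariate follow-ups use Welch tests with BH-FDR
  correction *per archetype* (the family is the three ratios within one
  archetype); size descriptors get Welch + Holm per archetype.
* **Frequencies:** archetype occupancy counts and a Pearson chi-square test
  of independence (no continuity correction) on the archetype x group
  table.

```{r report-example}
coh <- sample_cohort(seed = 42)
rep <- compare_groups(coh, group_col = "group")
rep$descriptor_tests[, c("descriptor", "p_holm", "cohen_d")]
```

## The synthetic generator

Because descriptor tables and not raw structures are the unit of most
analyses, the package ships two generators.

`sample_cloud()` draws point clouds with a prescribed covariance
eigen-structure, under a Gaussian or a bounded uniform-ellipsoid model. The
ellipsoid option exists because real pockets are bounded; its eigenvalue
ratios equal squared semi-axis ratios, the same targets as the Gaussian
model, so shape tests are model-agnostic. The generator-analyzer closure
(sample → tensor → spectrum recovers the target ratios) is the package's
core self-test.

`sample_cohort()` draws descriptor tables around per-(group, archetype)
centroids. Its default specification, `reference_cohort_spec()`, encodes
the published per-archetype means, SDs and cell counts of the curated
300+300 RNA/protein cohorts, so the default synthetic cohort has the
realistic spread and occupancy of the study conditions. Ratios are clipped
to \([0,1]\) by default (resampling is available); `rEV31` is set to the
product, so the identity holds by construction.

What the generator does *not* emulate: real pockets are concave,
solvent-exposed, discretely sampled atom clouds with chemistry-driven
correlations between shape and size; the generator draws independent
Gaussians per descriptor. Passing tests on synthetic cohorts therefore
demonstrate correctness of the computations and qualitative behaviour of
the pipeline — not biological conclusions about real structures.

`write_toy_complex()` emits minimal PDB/mmCIF fixtures, each designed
around one preprocessing rule (threshold residues, altloc ordering,
hydrogen retention, multi-model files). The hydrogen fixtures use 40 heavy
atoms plus 40 hydrogens per complex: large enough that per-atom hydrogen
jitter perturbs rather than dominates the ratios, which is the regime of
real pockets (hundreds of atoms).

## Problem sizes and numerical tolerances

The test suite checks algebraic identities (ratio product, \(R_g^2\) vs
trace) at 1e-9 over 10,000 random clouds; parameter recovery at n =
100,000 points within 0.02 absolute over 20 seeds; classifier equivalence
on a 101x101 grid for 25 threshold pairs; Welch null calibration over
10,000 simulations at n = 30 per group; and bootstrap stability at 1,000
replicates on 600-pocket cohorts. These sizes make the full suite run in
well under a minute while keeping Monte-Carlo standard errors far below
the asserted tolerances.

## Known limitations

* No cavity detection without a bound ligand, no protonation/repair, no
  symmetry-mate expansion; extraction assumes the deposited coordinates.
* Multi-copy ligands must be disambiguated by the caller
  (`ligand_selector(chain =, resno =)`); cohort-level deduplication is out
  of scope.
* The archetype scheme is deliberately a 4-class median-anchored partition
  of a continuous space; boundaries are operational, and pockets with small
  `boundary_margin` should be interpreted accordingly.
* Published cohort-level quantities that require the original curated
  structure set (group means, per-archetype tables, the observed bootstrap
  ARI) are shipped as reference summaries, not recomputed from structures.
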