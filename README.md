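# pocketmorph

Morphometric analysis of small-molecule binding pockets, for structural
bioinformaticians comparing pocket geometry across macromolecular types
(canonically: RNA vs protein pockets). The package treats a pocket as a
bare 3-D point cloud of heavy atoms and asks purely geometric questions:
how anisotropic is it, which of four recurring shape regimes does it occupy,
and do two cohorts of pockets differ in shape, size, or regime occupancy?

## The method

For a pocket with heavy-atom coordinates $x_1,\dots,x_N$, the gyration
(second-moment) tensor is

$$T = \frac{1}{N}\sum_i (x_i-\bar x)(x_i-\bar x)^\top,$$

with eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$. Shape is carried
by the scale-invariant ratios

$$rEV21=\lambda_2/\lambda_1,\quad rEV32=\lambda_3/\lambda_2,\quad
rEV31=\lambda_3/\lambda_1 \in [0,1],$$

(1 = isotropy, with $rEV31 = rEV21\cdot rEV32$), and size by the atom count
and the radius of gyration $R_g=\sqrt{\lambda_1+\lambda_2+\lambda_3}$.
Pockets are classified into four archetypes — sphere-like, rod-like,
disk-like, strongly anisotropic — by comparing $(rEV21, rEV32)$ to the
global medians of the pooled cohort. On top of this sit the comparison
statistics: Welch tests with Holm / BH correction, Cohen's d, two-group
MANOVA with Pillai's trace, chi-square tests of archetype occupancy,
unweighted Euclidean distances in the 3-ratio space, and a stratified
bootstrap of partition stability scored by the adjusted Rand index.

Pockets are extracted from PDB/mmCIF files as the complete residues having
at least one heavy atom within 6 Å (configurable, 4–6 Å typical) of any
ligand heavy atom, after removing solvent, monoatomic ions, hydrogens and
duplicate altlocs.

## Worked example

```r
library(pocketmorph)

# 1. extract a pocket from a structure file
path <- tempfile(fileext = ".pdb")
write_toy_complex("two_residue_threshold", path)    # designed toy complex
m <- preprocess_structure(read_structure(path, structure_id = "toy"))
extract_pocket(m, "VIB", cutoff = 6)
#> <pocket_cloud> toy / VIB:L101 (residue level, 6 A): 2 atoms in 1 residues [degenerate]

# 2. descriptors of a synthetic anisotropic cloud (target ratios 4/9, 1/4, 1/9)
cloud <- sample_cloud(5000, sigma = c(9, 4, 1), seed = 1)
shape_descriptors(cloud)[, c("rEV21", "rEV32", "rEV31", "Rg", "n_atoms")]
#>       rEV21     rEV32     rEV31       Rg n_atoms
#> 1 0.4188054 0.2413171 0.1010649 3.799139    5000

# 3. a full cohort comparison on a realistic synthetic cohort
coh <- sample_cohort(seed = 42)          # 300 RNA + 300 protein pockets
rep <- compare_groups(coh, group_col = "group")
rep
#> <comparison_report> RNA vs protein
#> thresholds: m21 = 0.592, m32 = 0.580
#>
#> Descriptor comparison (direction RNA - protein):
#>  descriptor   mean1   mean2   p_holm cohen_d pooled_median
#>       rEV21   0.576   0.600 8.06e-02  -0.143         0.592
#>       rEV32   0.541   0.605 7.51e-05  -0.339         0.580
#>       rEV31   0.306   0.360 4.35e-06  -0.397         0.325
#>     n_atoms 238.117 178.947 3.12e-21   0.815       207.500
#>          Rg   9.241   8.736 4.58e-07   0.417         8.998
#>
#> Archetype occupancy chi-square: X2 = 14.026, df = 3, p = 0.00287

# 4. how stable is the median-anchored partition under resampling?
bootstrap_stability(coh, n_replicates = 1000, seed = 17)
#> <stability_report> 1000 replicates (seed 17)
#>   ARI median 0.923 [0.812, 0.987]; P(ARI>=0.9) = 0.673, P(ARI>=0.8) = 0.987
#>   median reclassified fraction 0.030; threshold SD m21 0.0104, m32 0.0161
```

Reading the output: shape effects between the groups are small-to-moderate
(|d| < 0.4) while size effects are large (d ≈ 0.8 for atom count), the
pooled medians anchor the archetype thresholds, the chi-square test says
the two groups occupy the four archetypes at different rates, and the
bootstrap says the partition itself is robust — a median ARI of 0.92 with
only ~3% of pockets reclassified under resampled thresholds.

Published cohort-level summaries (group means/SDs, archetype counts,
pooled medians) ship as `reference_summaries()`,
`reference_archetype_counts()`, `reference_thresholds()` and
`reference_cohort_spec()`, so effect sizes and frequency tests can be
recomputed directly from them via the summary-input mode
(`summary_stats()`, `cohen_d()`, `welch_t()`).

A thin command-line wrapper over these functions is installed at
`inst/cli/pocketmorph.R` (subcommands `extract`, `describe`, `classify`,
`stability`, `compare`, `simulate`).

## Package layout

- `R/structure_io.R` — PDB/mmCIF reading, preprocessing, pocket extraction
- `R/descriptors.R` — gyration tensor, eigen-spectrum, shape descriptors
- `R/archetypes.R` — thresholds, decision tree, ARI, bootstrap stability
- `R/distances.R` — ratio-space distances and block summaries
- `R/stats.R` — Welch/Cohen/Holm/BH/MANOVA/chi-square, full report
- `R/synthetic.R` — cloud, fixture, and cohort generators
- `R/reference_data.R` — published reference summaries
- `vignettes/pocket-anisotropy.Rmd` — the methods vignette
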