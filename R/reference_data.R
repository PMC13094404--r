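#' Reference descriptor summaries for the curated RNA/protein pocket cohorts
#'
#' Published summary statistics (mean, SD, n = 300 per group, and pooled
#' medians) for the five pocket descriptors on the curated RNA and protein
#' ligand-binding pocket datasets the morphometric framework was
#' characterized on. These summaries let effect sizes and Welch tests be
#' recomputed directly via [summary_stats()], [cohen_d()], and [welch_t()]
#' without access to the underlying structures.
#'
#' @return Data frame with columns `descriptor`, `family` (shape/size),
#'   `rna_mean`, `rna_sd`, `protein_mean`, `protein_sd`, `n_per_group`,
#'   `pooled_median`.
#' @export
reference_summaries <- function() {
  data.frame(
    descriptor = c("rEV21", "rEV32", "rEV31", "n_atoms", "Rg"),
    family = c("shape", "shape", "shape", "size", "size"),
    rna_mean = c(0.572, 0.547, 0.309, 244.713, 9.248),
    rna_sd = c(0.171, 0.184, 0.128, 91.756, 1.304),
    protein_mean = c(0.600, 0.600, 0.360, 176.353, 8.759),
    protein_sd = c(0.165, 0.182, 0.144, 57.169, 1.062),
    n_per_group = 300L,
    pooled_median = c(0.592, 0.575, 0.328, 200.500, 9.019),
    stringsAsFactors = FALSE)
}

#' Reference archetype occupancy counts
#'
#' Published archetype counts for the curated cohorts (n = 300 RNA and 300
#' protein pockets), used for frequency and chi-square analyses.
#'
#' @return 4 x 2 integer matrix (archetype x group).
#' @export
reference_archetype_counts <- function() {
  m <- matrix(c(49L, 85L, 91L, 75L,
                86L, 80L, 74L, 60L), ncol = 2L,
              dimnames = list(archetype_levels(), c("RNA", "protein")))
  m
}

#' Reference decision thresholds
#'
#' Global medians of rEV21 and rEV32 over the pooled curated cohorts
#' (n = 600), anchoring the published archetype partition.
#'
#' @return A `decision_thresholds` object with `m21 = 0.592`,
#'   `m32 = 0.575`.
#' @export
reference_thresholds <- function() decision_thresholds(0.592, 0.575, 600L)

#' Reference cohort specification
#'
#' Per-(group, archetype) descriptor distributions (ratio centroids and
#' spreads, atom-count and radius-of-gyration means and SDs, cell counts)
#' matching the published characterization of the curated cohorts. Used as
#' the default [sample_cohort()] specification, so synthetic cohorts mirror
#' the realistic spread and occupancy of the study conditions.
#'
#' @return A [cohort_spec()] data frame with 8 rows.
#' @export
reference_cohort_spec <- function() {
  cohort_spec(data.frame(
    group = rep(c("RNA", "protein"), each = 4L),
    archetype = rep(c("sphere", "rod", "disk", "strongly_anisotropic"), 2L),
    n = c(49L, 85L, 91L, 75L, 86L, 80L, 74L, 60L),
    c21 = c(0.70, 0.46, 0.73, 0.43, 0.72, 0.46, 0.73, 0.46),
    c32 = c(0.69, 0.73, 0.41, 0.42, 0.72, 0.76, 0.45, 0.41),
    s21 = c(0.08, 0.10, 0.09, 0.13, 0.09, 0.09, 0.10, 0.11),
    s32 = c(0.09, 0.10, 0.12, 0.11, 0.09, 0.11, 0.09, 0.11),
    atoms_mean = c(288.33, 251.99, 234.03, 209.60,
                   202.63, 178.64, 164.66, 150.07),
    atoms_sd = c(72.69, 98.55, 68.84, 103.97, 44.04, 60.19, 51.73, 60.99),
    rg_mean = c(9.49, 9.57, 9.04, 8.97, 8.86, 8.93, 8.48, 8.74),
    rg_sd = c(0.93, 1.46, 0.94, 1.59, 0.80, 1.05, 1.01, 1.37),
    stringsAsFactors = FALSE))
}
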