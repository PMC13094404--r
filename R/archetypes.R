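#' Morphological archetype levels
#'
#' The four regions of the (rEV21, rEV32) plane delimited by the global
#' medians: sphere-like (both high), rod-like (low rEV21, high rEV32),
#' disk-like (high rEV21, low rEV32), strongly anisotropic (both low).
#' @export
archetype_levels <- function() c("sphere", "rod", "disk", "strongly_anisotropic")

#' Fit median-based decision thresholds
#'
#' The archetype partition is anchored on the global medians of rEV21 and
#' rEV32 computed over the pooled reference set (both cohorts combined);
#' with an even count the median is the midpoint of the two central order
#' statistics.
#'
#' @param descriptors Data frame with columns `rEV21` and `rEV32` (e.g. from
#'   [describe_pockets()]).
#' @return Object of class `decision_thresholds`: list with `m21`, `m32`,
#'   `reference_n`, and `reference` (the rEV21/rEV32 table the medians were
#'   fit on).
#' @export
fit_thresholds <- function(descriptors) {
  stopifnot(is.data.frame(descriptors),
            all(c("rEV21", "rEV32") %in% names(descriptors)))
  if (nrow(descriptors) < 2L) stop("need at least 2 pockets to fit thresholds")
  ref <- descriptors[, c("rEV21", "rEV32")]
  structure(list(m21 = median(ref$rEV21), m32 = median(ref$rEV32),
                 reference_n = nrow(ref), reference = ref),
            class = "decision_thresholds")
}

#' Construct thresholds from known median values
#'
#' @param m21,m32 Median rEV21 and rEV32 anchoring the partition.
#' @param reference_n Size of the set the medians were computed on (optional).
#' @return A `decision_thresholds` object without a stored reference table.
#' @export
decision_thresholds <- function(m21, m32, reference_n = NA_integer_) {
  stopifnot(m21 > 0, m21 < 1, m32 > 0, m32 < 1)
  structure(list(m21 = m21, m32 = m32, reference_n = reference_n,
                 reference = NULL),
            class = "decision_thresholds")
}

#' @export
print.decision_thresholds <- function(x, ...) {
  cat(sprintf("<decision_thresholds> m21 = %.4f, m32 = %.4f (reference n = %s)\n",
              x$m21, x$m32, x$reference_n))
  invisible(x)
}

# Vectorized decision tree; "high" is >= median (tie assigned to the
# isotropic side).
.classify_ratios <- function(r21, r32, m21, m32) {
  hi21 <- r21 >= m21
  hi32 <- r32 >= m32
  out <- ifelse(hi21 & hi32, "sphere",
         ifelse(!hi21 & hi32, "rod",
         ifelse(hi21 & !hi32, "disk", "strongly_anisotropic")))
  factor(out, levels = archetype_levels())
}

#' Assign pockets to shape archetypes
#'
#' Deterministic median-anchored decision tree on (rEV21, rEV32):
#' `rEV21 >= m21 & rEV32 >= m32` is sphere-like; low rEV21 with high rEV32 is
#' rod-like; high rEV21 with low rEV32 is disk-like; both low is strongly
#' anisotropic. Values exactly at a threshold count as "high".
#'
#' @param descriptors Data frame with `rEV21`, `rEV32` (and ideally
#'   `pocket_id`); extra columns are carried through.
#' @param thresholds A `decision_thresholds` object.
#' @return The input data frame plus columns `archetype` (factor over
#'   [archetype_levels()]) and `boundary_margin`
#'   (`min(|rEV21 - m21|, |rEV32 - m32|)`, the smallest ratio perturbation
#'   that could change the label).
#' @export
classify_pockets <- function(descriptors, thresholds) {
  stopifnot(is.data.frame(descriptors),
            all(c("rEV21", "rEV32") %in% names(descriptors)),
            inherits(thresholds, "decision_thresholds"))
  r21 <- descriptors$rEV21
  r32 <- descriptors$rEV32
  if (any(r21 < 0 | r21 > 1 | r32 < 0 | r32 > 1, na.rm = TRUE)) {
    stop("eigenvalue ratios must lie in [0, 1]")
  }
  out <- descriptors
  out$archetype <- .classify_ratios(r21, r32, thresholds$m21, thresholds$m32)
  out$boundary_margin <- pmin(abs(r21 - thresholds$m21),
                              abs(r32 - thresholds$m32))
  out
}

#' Adjusted Rand index between two partitions
#'
#' Hubert--Arabie chance-corrected pair-counting agreement: 1 for identical
#' partitions (up to label permutation), expectation ~0 for independent
#' random labelings.
#'
#' @param labels_a,labels_b Equal-length label vectors (>= 2 items).
#' @return Scalar ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length")
  }
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 items")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(n)
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Stratified bootstrap stability of the archetype partition
#'
#' Resamples each group (stratum) with replacement at its original size,
#' refits the median thresholds on the pooled resample, and classifies the
#' resampled pockets under both the refitted and the reference thresholds.
#' Agreement per replicate is scored with the adjusted Rand index and the
#' fraction of reclassified pockets, isolating the sensitivity of the
#' partition to sampling variability in the thresholds.
#'
#' @param descriptors Data frame with `rEV21`, `rEV32` and a group column.
#' @param group_col Name of the stratum column (default `"group"`).
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Master seed; per-replicate substreams are derived from it, so
#'   results are fully reproducible.
#' @param thresholds Reference thresholds; default fits them on the full
#'   input with [fit_thresholds()].
#' @return Object of class `stability_report`: list with `n_replicates`,
#'   `ari_median`, `ari_q025`, `ari_q975`, `frac_ari_ge_090`,
#'   `frac_ari_ge_080`, `median_reclassified_fraction`, `threshold_sd_m21`,
#'   `threshold_sd_m32`, `seed`, and the per-replicate vectors in
#'   `replicates`.
#' @export
bootstrap_stability <- function(descriptors, group_col = "group",
                                n_replicates = 1000L, seed = 1L,
                                thresholds = NULL) {
  stopifnot(is.data.frame(descriptors), group_col %in% names(descriptors))
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  groups <- as.character(descriptors[[group_col]])
  strata <- split(seq_len(nrow(descriptors)), groups)
  if (length(strata) < 1L || any(lengths(strata) == 0L)) {
    stop("every stratum must be non-empty")
  }
  if (is.null(thresholds)) thresholds <- fit_thresholds(descriptors)

  r21 <- descriptors$rEV21
  r32 <- descriptors$rEV32

  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  ari <- reclass <- m21_b <- m32_b <- numeric(n_replicates)
  for (b in seq_len(n_replicates)) {
    set.seed(sub_seeds[b])
    idx <- unlist(lapply(strata, function(s) {
      s[sample.int(length(s), length(s), replace = TRUE)]
    }), use.names = FALSE)
    m21_b[b] <- median(r21[idx])
    m32_b[b] <- median(r32[idx])
    lab_ref <- .classify_ratios(r21[idx], r32[idx],
                                thresholds$m21, thresholds$m32)
    lab_boot <- .classify_ratios(r21[idx], r32[idx], m21_b[b], m32_b[b])
    ari[b] <- adjusted_rand_index(lab_ref, lab_boot)
    reclass[b] <- mean(lab_ref != lab_boot)
  }

  structure(list(
    n_replicates = n_replicates,
    ari_median = median(ari),
    ari_q025 = unname(quantile(ari, 0.025)),
    ari_q975 = unname(quantile(ari, 0.975)),
    frac_ari_ge_090 = mean(ari >= 0.90),
    frac_ari_ge_080 = mean(ari >= 0.80),
    median_reclassified_fraction = median(reclass),
    threshold_sd_m21 = sd(m21_b),
    threshold_sd_m32 = sd(m32_b),
    seed = as.integer(seed),
    reference_thresholds = thresholds[c("m21", "m32", "reference_n")],
    replicates = list(ari = ari, reclassified_fraction = reclass,
                      m21 = m21_b, m32 = m32_b)
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d replicates (seed %d)\n", x$n_replicates,
              x$seed))
  cat(sprintf("  ARI median %.3f [%.3f, %.3f]; P(ARI>=0.9) = %.3f, P(ARI>=0.8) = %.3f\n",
              x$ari_median, x$ari_q025, x$ari_q975, x$frac_ari_ge_090,
              x$frac_ari_ge_080))
  cat(sprintf("  median reclassified fraction %.3f; threshold SD m21 %.4f, m32 %.4f\n",
              x$median_reclassified_fraction, x$threshold_sd_m21,
              x$threshold_sd_m32))
  invisible(x)
}

#' Archetype occupancy counts and percentages
#'
#' @param assignments Data frame with an `archetype` column (from
#'   [classify_pockets()]) and a group column.
#' @param group_col Name of the group column; `NULL` for a single pooled
#'   group.
#' @return Data frame with one row per (group, archetype): `n`, `pct_group`
#'   (percent within the group), and `pct_total` (percent of all pockets).
#'   Rows for empty combinations are kept with zero counts.
#' @export
archetype_frequencies <- function(assignments, group_col = "group") {
  stopifnot(is.data.frame(assignments), "archetype" %in% names(assignments))
  arch <- factor(assignments$archetype, levels = archetype_levels())
  grp <- if (is.null(group_col)) {
    factor(rep("all", nrow(assignments)))
  } else if (is.factor(assignments[[group_col]])) {
    assignments[[group_col]]  # empty levels kept as zero rows
  } else {
    factor(as.character(assignments[[group_col]]))
  }
  tab <- table(group = grp, archetype = arch)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n"
  gsize <- rowSums(tab)[out$group]
  out$pct_group <- ifelse(gsize > 0, 100 * out$n / gsize, 0)
  out$pct_total <- if (sum(tab) > 0) 100 * out$n / sum(tab) else 0
  out[order(out$group, match(out$archetype, archetype_levels())), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
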