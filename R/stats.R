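#' Descriptive summary of one group of values
#'
#' @param x Numeric vector (n >= 2).
#' @param descriptor_name Label for the summarized descriptor.
#' @return Object of class `group_summary`: list with `n`, `mean`, `sd`
#'   (sample SD, n-1 denominator), `median`, `descriptor_name`.
#' @export
group_summary <- function(x, descriptor_name = "value") {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 observations")
  structure(list(n = length(x), mean = mean(x), sd = sd(x),
                 median = median(x), descriptor_name = descriptor_name),
            class = "group_summary")
}

#' Construct a group summary from printed statistics
#'
#' Lets published mean/SD/n rows be consumed directly, e.g. to recompute
#' effect sizes from a summary table.
#' @param mean,sd,n Summary statistics of the group.
#' @param median Optional group median.
#' @param descriptor_name Label for the descriptor.
#' @return A `group_summary` object.
#' @export
summary_stats <- function(mean, sd, n, median = NA_real_,
                          descriptor_name = "value") {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = as.integer(n), mean = mean, sd = sd, median = median,
                 descriptor_name = descriptor_name),
            class = "group_summary")
}

.as_summary <- function(x, name = "value") {
  if (inherits(x, "group_summary")) x else group_summary(x, name)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test,
#' \eqn{t = (m_1 - m_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}}, with
#' Welch--Satterthwaite degrees of freedom and a two-sided p value. Accepts
#' raw vectors or `group_summary` objects (so published mean/SD/n rows can
#' be tested directly).
#'
#' @param x,y Numeric vectors or [group_summary()] / [summary_stats()]
#'   objects.
#' @return Object of class `test_result`: list with `statistic`, `df`,
#'   `p_raw`, `p_adjusted` (initially equal to `p_raw`), `adjust_method`
#'   (`"none"`), `family`.
#' @export
welch_t <- function(x, y) {
  s1 <- .as_summary(x)
  s2 <- .as_summary(y)
  if (s1$sd == 0 && s2$sd == 0) stop("both groups have zero variance")
  v1 <- s1$sd^2 / s1$n
  v2 <- s2$sd^2 / s2$n
  t_stat <- (s1$mean - s2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  p <- 2 * pt(-abs(t_stat), df)
  structure(list(statistic = t_stat, df = df, p_raw = p, p_adjusted = p,
                 adjust_method = "none", family = s1$descriptor_name),
            class = "test_result")
}

#' Cohen's d standardized effect size
#'
#' Standardized mean difference with the pooled-SD denominator
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}, which at
#' equal n reduces to \eqn{\sqrt{(s_1^2+s_2^2)/2}}. Direction is group1
#' minus group2.
#'
#' @param x,y Numeric vectors or `group_summary` objects.
#' @return Object of class `effect_size`: list with `cohen_d` and
#'   `direction`.
#' @export
cohen_d <- function(x, y) {
  s1 <- .as_summary(x)
  s2 <- .as_summary(y)
  sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / (s1$n + s2$n - 2)
  if (sp2 <= 0) stop("pooled SD is zero: effect size undefined")
  structure(list(cohen_d = (s1$mean - s2$mean) / sqrt(sp2),
                 direction = "group1 - group2"),
            class = "effect_size")
}

#' Holm step-down familywise adjustment
#'
#' @param p_values Numeric vector of raw p values in \[0, 1\].
#' @param family Label recorded with the adjustment (one family per call).
#' @return Adjusted p values in the input order, capped at 1.
#' @export
holm_adjust <- function(p_values, family = "family") {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  out <- p.adjust(p_values, method = "holm")
  attr(out, "family") <- family
  out
}

#' Benjamini--Hochberg step-up FDR adjustment
#'
#' @param p_values Numeric vector of raw p values in \[0, 1\].
#' @return Adjusted p values in the input order, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Two-group one-factor MANOVA with Pillai's trace
#'
#' Fits a one-factor MANOVA and reports Pillai's trace
#' \eqn{V = \mathrm{tr}(H(H+E)^{-1})} with its standard F approximation.
#' Intended for the two independent ratios (rEV21, rEV32); rEV31 is
#' algebraically dependent on them and must not be included as a response.
#'
#' @param values n x p numeric matrix of responses (p >= 2).
#' @param groups Length-n vector with exactly two levels, each with >= 3
#'   observations.
#' @return Object of class `manova_result`: list with `pillai_trace`,
#'   `approx_F`, `df1`, `df2`, `p`, and `box_m` (Box's M homogeneity
#'   diagnostic, reported for inspection only).
#' @export
manova_two_group <- function(values, groups) {
  values <- as.matrix(values)
  groups <- factor(as.character(groups))
  stopifnot(ncol(values) >= 2L, nrow(values) == length(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 3L)) stop("each group needs >= 3 observations")
  tot <- crossprod(sweep(values, 2L, colMeans(values)))
  within <- Reduce(`+`, lapply(levels(groups), function(g) {
    v <- values[groups == g, , drop = FALSE]
    crossprod(sweep(v, 2L, colMeans(v)))
  }))
  if (rcond(tot) < 1e-12) {
    stop("singular total SSCP matrix (rcond = ", format(rcond(tot)),
         "); responses are collinear")
  }
  fit <- manova(values ~ groups)
  st <- summary(fit, test = "Pillai")$stats
  bm <- .box_m(values, groups)
  structure(list(pillai_trace = unname(st[1L, "Pillai"]),
                 approx_F = unname(st[1L, "approx F"]),
                 df1 = unname(st[1L, "num Df"]),
                 df2 = unname(st[1L, "den Df"]),
                 p = unname(st[1L, "Pr(>F)"]),
                 box_m = bm),
            class = "manova_result")
}

# Box's M test of covariance homogeneity (chi-square approximation).
# Reported as a diagnostic; no automatic gate.
.box_m <- function(values, groups) {
  p <- ncol(values)
  ns <- table(groups)
  k <- length(ns)
  covs <- lapply(levels(groups), function(g) {
    cov(values[groups == g, , drop = FALSE])
  })
  pooled <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, as.list(ns))) /
    (sum(ns) - k)
  if (any(vapply(covs, det, 0) <= 0) || det(pooled) <= 0) {
    # a singular group covariance (e.g. tiny or collinear group): the
    # diagnostic is undefined, not an error
    return(list(statistic = NA_real_, df = p * (p + 1) * (k - 1) / 2,
                p = NA_real_))
  }
  M <- (sum(ns) - k) * log(det(pooled)) -
    sum(mapply(function(S, n) (n - 1) * log(det(S)), covs, as.list(ns)))
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1)) *
    (sum(1 / (ns - 1)) - 1 / (sum(ns) - k))
  stat <- M * (1 - c1)
  df <- p * (p + 1) * (k - 1) / 2
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic \eqn{\sum (O - E)^2 / E} on an r x c contingency table
#' with expected counts from the margins, no continuity correction,
#' df = (r-1)(c-1).
#'
#' @param counts Non-negative r x c matrix of counts with no zero margins.
#' @return Object of class `chisq_result`: list with `statistic`, `df`,
#'   `p`, `expected`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value,
                 expected = ct$expected),
            class = "chisq_result")
}

#' Full two-cohort comparison report
#'
#' Runs the complete comparison battery on a descriptor table with two
#' groups (typically RNA vs protein):
#' \itemize{
#'   \item per-descriptor group summaries, Welch tests with Holm correction
#'     applied separately to the shape family (rEV21, rEV32, rEV31) and the
#'     size family (n_atoms, Rg), Cohen's d, and pooled medians;
#'   \item per-archetype MANOVA on (rEV21, rEV32) with Pillai's trace,
#'     univariate Welch follow-ups on the ratios with BH-FDR correction per
#'     archetype, and size-descriptor Welch tests with Holm correction per
#'     archetype, all with effect sizes;
#'   \item archetype occupancy counts/percentages and a chi-square test of
#'     independence on the archetype x group counts.
#' }
#'
#' @param descriptors Data frame with columns `rEV21`, `rEV32`, `rEV31`,
#'   `n_atoms`, `Rg`, and a group column.
#' @param group_col Name of the group column (default `"group"`).
#' @param thresholds Optional `decision_thresholds`; default fits them on
#'   the pooled input.
#' @param group_order Optional length-2 character vector fixing which group
#'   is "group1" in differences and effect sizes (e.g. `c("RNA",
#'   "protein")`). Defaults to `c("RNA", "protein")` when those labels are
#'   present, otherwise first-appearance order.
#' @return Object of class `comparison_report`: list with `groups`,
#'   `thresholds`, `descriptor_tests` (data frame), `archetype_tests`
#'   (list per archetype), `frequencies`, `chi_square`.
#' @export
compare_groups <- function(descriptors, group_col = "group",
                           thresholds = NULL, group_order = NULL) {
  stopifnot(is.data.frame(descriptors), group_col %in% names(descriptors))
  grp <- as.character(descriptors[[group_col]])
  glev <- unique(grp)
  if (length(glev) != 2L) stop("exactly two groups required, got ",
                               length(glev))
  if (is.null(group_order)) {
    group_order <- if (setequal(glev, c("RNA", "protein"))) {
      c("RNA", "protein")
    } else glev
  }
  stopifnot(setequal(group_order, glev))
  g1 <- group_order[1L]
  g2 <- group_order[2L]

  shape_desc <- intersect(c("rEV21", "rEV32", "rEV31"), names(descriptors))
  size_desc <- intersect(c("n_atoms", "Rg"), names(descriptors))
  all_desc <- c(shape_desc, size_desc)
  if (length(all_desc) == 0L) stop("no descriptor columns found")

  desc_rows <- lapply(all_desc, function(dn) {
    x1 <- descriptors[[dn]][grp == g1]
    x2 <- descriptors[[dn]][grp == g2]
    wt <- welch_t(group_summary(x1, dn), group_summary(x2, dn))
    data.frame(descriptor = dn,
               family = if (dn %in% shape_desc) "shape" else "size",
               mean1 = mean(x1), sd1 = sd(x1), n1 = length(x1),
               mean2 = mean(x2), sd2 = sd(x2), n2 = length(x2),
               pooled_median = median(descriptors[[dn]]),
               t = wt$statistic, df = wt$df, p_raw = wt$p_raw,
               cohen_d = cohen_d(x1, x2)$cohen_d,
               stringsAsFactors = FALSE)
  })
  dt <- do.call(rbind, desc_rows)
  dt$p_holm <- NA_real_
  for (fam in unique(dt$family)) {
    sel <- dt$family == fam
    dt$p_holm[sel] <- holm_adjust(dt$p_raw[sel], fam)
  }

  if (is.null(thresholds)) thresholds <- fit_thresholds(descriptors)
  assignments <- classify_pockets(descriptors, thresholds)
  assignments[[group_col]] <- grp

  arch_tests <- lapply(archetype_levels(), function(a) {
    sub <- assignments[assignments$archetype == a, , drop = FALSE]
    sg <- sub[[group_col]]
    if (min(table(factor(sg, levels = group_order))) < 3L) {
      return(list(archetype = a, n1 = sum(sg == g1), n2 = sum(sg == g2),
                  manova = NULL, shape_univariate = NULL, size_tests = NULL,
                  note = "fewer than 3 pockets in a group; tests skipped"))
    }
    mv <- manova_two_group(as.matrix(sub[, c("rEV21", "rEV32")]), sg)
    shp <- do.call(rbind, lapply(shape_desc, function(dn) {
      x1 <- sub[[dn]][sg == g1]; x2 <- sub[[dn]][sg == g2]
      wt <- welch_t(group_summary(x1, dn), group_summary(x2, dn))
      data.frame(descriptor = dn, t = wt$statistic, df = wt$df,
                 p_raw = wt$p_raw, cohen_d = cohen_d(x1, x2)$cohen_d,
                 stringsAsFactors = FALSE)
    }))
    shp$p_bh <- bh_adjust(shp$p_raw)
    siz <- if (length(size_desc)) {
      s <- do.call(rbind, lapply(size_desc, function(dn) {
        x1 <- sub[[dn]][sg == g1]; x2 <- sub[[dn]][sg == g2]
        wt <- welch_t(group_summary(x1, dn), group_summary(x2, dn))
        data.frame(descriptor = dn, t = wt$statistic, df = wt$df,
                   p_raw = wt$p_raw, cohen_d = cohen_d(x1, x2)$cohen_d,
                   stringsAsFactors = FALSE)
      }))
      s$p_holm <- holm_adjust(s$p_raw, paste0("size:", a))
      s
    } else NULL
    list(archetype = a, n1 = sum(sg == g1), n2 = sum(sg == g2),
         manova = mv, shape_univariate = shp, size_tests = siz, note = NULL)
  })
  names(arch_tests) <- archetype_levels()

  freq <- archetype_frequencies(assignments, group_col = group_col)
  counts <- matrix(freq$n, nrow = length(archetype_levels()),
                   dimnames = list(archetype_levels(), levels(factor(grp))))
  counts <- counts[, group_order, drop = FALSE]
  chi <- chi_square_independence(counts)

  structure(list(groups = group_order, thresholds = thresholds,
                 descriptor_tests = dt, archetype_tests = arch_tests,
                 frequencies = freq, counts = counts, chi_square = chi),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat("<comparison_report> ", x$groups[1L], " vs ", x$groups[2L], "\n",
      sep = "")
  cat(sprintf("thresholds: m21 = %.3f, m32 = %.3f\n",
              x$thresholds$m21, x$thresholds$m32))
  dt <- x$descriptor_tests
  cat("\nDescriptor comparison (direction ", x$groups[1L], " - ",
      x$groups[2L], "):\n", sep = "")
  print(data.frame(descriptor = dt$descriptor,
                   mean1 = round(dt$mean1, digits),
                   mean2 = round(dt$mean2, digits),
                   p_holm = signif(dt$p_holm, 3),
                   cohen_d = round(dt$cohen_d, digits),
                   pooled_median = round(dt$pooled_median, digits)),
        row.names = FALSE)
  cat(sprintf("\nArchetype occupancy chi-square: X2 = %.3f, df = %d, p = %.3g\n",
              x$chi_square$statistic, x$chi_square$df, x$chi_square$p))
  invisible(x)
}
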