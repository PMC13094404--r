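#' Unweighted Euclidean distance in eigenvalue-ratio space
#'
#' Morphometric similarity between two pockets is the unweighted Euclidean
#' distance between their (rEV21, rEV32, rEV31) triples. rEV31 is included
#' despite being the product of the other two ratios, so that overall
#' anisotropy contributes to the metric; no reweighting is applied.
#'
#' @param a,b Numeric length-3 vectors, or one-row data frames / lists with
#'   components `rEV21`, `rEV32`, `rEV31`.
#' @return Non-negative scalar; 0 iff the triples are identical.
#' @export
ratio_distance <- function(a, b) {
  va <- .ratio_vector(a)
  vb <- .ratio_vector(b)
  sqrt(sum((va - vb)^2))
}

.ratio_vector <- function(x) {
  if (is.numeric(x) && length(x) == 3L) return(as.numeric(x))
  comp <- c("rEV21", "rEV32", "rEV31")
  if (all(comp %in% names(x))) {
    return(as.numeric(unlist(x[comp], use.names = FALSE)))
  }
  stop("ratio point must be a length-3 numeric or have rEV21/rEV32/rEV31")
}

#' Intra- and inter-archetype distance summary
#'
#' Computes all pairwise ratio-space distances and summarizes them per
#' (group, archetype) block: the familiar 8 x 8 heatmap layout for a
#' two-group, four-archetype cohort. Diagonal blocks are means over
#' unordered distinct pairs within the block (archetype compactness);
#' off-diagonal blocks are means over all cross pairs. Group-level pair
#' summaries (e.g. RNA--RNA, protein--protein, RNA--protein) report mean,
#' SD, and the 5th percentile (linear-interpolation quantile).
#'
#' @param points Data frame with columns `rEV21`, `rEV32`, `rEV31`,
#'   `archetype`, and a group column.
#' @param group_col Name of the group column (default `"group"`); `NULL`
#'   collapses all points into one group.
#' @return Object of class `distance_summary`: list with `block_mean` and
#'   `block_n` (square matrices over the group:archetype blocks; blocks with
#'   no pairs are `NA`), `group_pairs` (per group-pair mean/sd/q05/n), and
#'   `overall` (pooled mean/sd/q05).
#' @export
distance_summary <- function(points, group_col = "group") {
  stopifnot(is.data.frame(points),
            all(c("rEV21", "rEV32", "rEV31", "archetype") %in% names(points)))
  if (nrow(points) < 2L) stop("need at least 2 points")
  grp <- if (is.null(group_col)) {
    factor(rep("all", nrow(points)))
  } else {
    factor(as.character(points[[group_col]]))
  }
  arch <- factor(points$archetype, levels = archetype_levels())
  D <- as.matrix(dist(as.matrix(points[, c("rEV21", "rEV32", "rEV31")])))

  blocks <- expand.grid(archetype = archetype_levels(),
                        group = levels(grp), stringsAsFactors = FALSE)
  labels <- paste(blocks$group, blocks$archetype, sep = ":")
  idx <- lapply(seq_len(nrow(blocks)), function(i) {
    which(grp == blocks$group[i] & arch == blocks$archetype[i])
  })

  nb <- length(labels)
  block_mean <- matrix(NA_real_, nb, nb, dimnames = list(labels, labels))
  block_n <- matrix(0, nb, nb, dimnames = list(labels, labels))
  for (i in seq_len(nb)) {
    for (j in i:nb) {
      vals <- .block_distances(D, idx[[i]], idx[[j]], within = (i == j))
      block_n[i, j] <- block_n[j, i] <- length(vals)
      if (length(vals) > 0L) {
        block_mean[i, j] <- block_mean[j, i] <- mean(vals)
      }
    }
  }

  glev <- levels(grp)
  gp <- list()
  for (i in seq_along(glev)) {
    for (j in i:length(glev)) {
      vals <- .block_distances(D, which(grp == glev[i]), which(grp == glev[j]),
                               within = (i == j))
      gp[[length(gp) + 1L]] <- data.frame(
        pair = paste(glev[i], glev[j], sep = "-"),
        n_pairs = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1L) sd(vals) else NA_real_,
        q05 = if (length(vals)) unname(quantile(vals, 0.05)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  all_vals <- D[upper.tri(D)]
  structure(list(
    block_mean = block_mean, block_n = block_n,
    group_pairs = do.call(rbind, gp),
    overall = data.frame(n_pairs = length(all_vals), mean = mean(all_vals),
                         sd = sd(all_vals),
                         q05 = unname(quantile(all_vals, 0.05)))
  ), class = "distance_summary")
}

# Distances for one block: unordered distinct pairs when within, all cross
# pairs otherwise. Self-pairs never contribute.
.block_distances <- function(D, idx_i, idx_j, within) {
  if (within) {
    if (length(idx_i) < 2L) return(numeric(0))
    sub <- D[idx_i, idx_i, drop = FALSE]
    sub[upper.tri(sub)]
  } else {
    if (length(idx_i) == 0L || length(idx_j) == 0L) return(numeric(0))
    as.vector(D[idx_i, idx_j, drop = FALSE])
  }
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance_summary> block means (", nrow(x$block_mean), " x ",
      ncol(x$block_mean), "):\n", sep = "")
  print(round(x$block_mean, 3))
  cat("group pair summaries:\n")
  print(x$group_pairs, row.names = FALSE)
  invisible(x)
}

#' Export the block-mean matrix as a heatmap-ready CSV
#'
#' @param x A `distance_summary`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(x, path) {
  stopifnot(inherits(x, "distance_summary"))
  write.csv(x$block_mean, path, row.names = TRUE)
  invisible(path)
}
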