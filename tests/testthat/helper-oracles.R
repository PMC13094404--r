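# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Gyration tensor by explicit double loop over coordinate pairs.
oracle_gyration <- function(coords) {
  n <- nrow(coords)
  ctr <- colMeans(coords)
  out <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d <- coords[i, ] - ctr
    for (a in 1:3) {
      for (b in 1:3) out[a, b] <- out[a, b] + d[a] * d[b]
    }
  }
  out / n
}

# Archetype label by explicit nested conditionals.
oracle_classify <- function(r21, r32, m21, m32) {
  if (r21 >= m21) {
    if (r32 >= m32) "sphere" else "disk"
  } else {
    if (r32 >= m32) "rod" else "strongly_anisotropic"
  }
}

# ARI by explicit enumeration of all unordered item pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s_both <- s_a <- s_b <- 0
  npair <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      npair <- npair + 1
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      s_both <- s_both + (same_a && same_b)
      s_a <- s_a + same_a
      s_b <- s_b + same_b
    }
  }
  exp_idx <- s_a * s_b / npair
  max_idx <- (s_a + s_b) / 2
  (s_both - exp_idx) / (max_idx - exp_idx)
}

# Block-mean pairwise distances by O(n^2) double loop.
oracle_block_means <- function(ratios, block_of, labels) {
  n <- nrow(ratios)
  sums <- counts <- matrix(0, length(labels), length(labels),
                           dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((ratios[i, ] - ratios[j, ])^2))
      bi <- match(block_of[i], labels)
      bj <- match(block_of[j], labels)
      sums[bi, bj] <- sums[bi, bj] + d
      counts[bi, bj] <- counts[bi, bj] + 1
      if (bi != bj) {
        sums[bj, bi] <- sums[bj, bi] + d
        counts[bj, bi] <- counts[bj, bi] + 1
      }
    }
  }
  means <- sums / counts
  means[counts == 0] <- NA_real_
  means
}

# Pearson chi-square by explicit expected-count loops.
oracle_chisq <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  tot <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / tot
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  unname(stat)
}

# Minimal PDB writer for ad-hoc fixtures built in tests.
write_fixture_pdb <- function(atoms, path) {
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$het, "HETATM", "ATOM"), seq_len(nrow(atoms)),
    ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety), atoms$elety),
    substr(paste0(atoms$alt, " "), 1, 1),
    atoms$resid, atoms$chain, atoms$resno, " ",
    atoms$x, atoms$y, atoms$z, 1.0, 0.0, atoms$elesy)
  writeLines(c(lines, "END"), path)
  path
}

fixture_atom <- function(chain, resid, resno, elety, elesy, x, y, z,
                         het = FALSE, alt = "") {
  data.frame(chain = chain, resid = resid, resno = resno, elety = elety,
             elesy = elesy, x = x, y = y, z = z, het = het, alt = alt,
             stringsAsFactors = FALSE)
}

# Two-blob cohort in which every bootstrap-refit threshold reproduces the
# reference labels (wide gap, lower blob a minority in each stratum).
gap_separated_cohort <- function() {
  mk <- function(group, n_lo, n_hi) {
    data.frame(
      pocket_id = paste0(group, seq_len(n_lo + n_hi)),
      group = group,
      rEV21 = c(rep(0.30, n_lo), rep(0.80, n_hi)),
      rEV32 = c(rep(0.30, n_lo), rep(0.80, n_hi)),
      stringsAsFactors = FALSE)
  }
  out <- rbind(mk("RNA", 100, 200), mk("protein", 100, 200))
  out$rEV31 <- out$rEV21 * out$rEV32
  out
}
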