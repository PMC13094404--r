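#' Random 3-D rotation matrix
#'
#' Haar-uniform rotation via QR decomposition of a Gaussian matrix, with the
#' sign convention fixed so the result is a proper rotation (det = +1).
#'
#' @param seed Optional seed for reproducibility.
#' @return Orthonormal 3 x 3 matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  qr_dec <- qr(matrix(rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_dec)
  Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Sample a synthetic anisotropic pocket point cloud
#'
#' Draws `n_points` from a zero-mean distribution whose population
#' covariance is `R %*% diag(sigma) %*% t(R)` for rotation `R`, then
#' translates. Under the Gaussian model the expected gyration-tensor
#' eigenvalues are exactly `sigma`; under the bounded uniform-ellipsoid
#' model the eigenvalue *ratios* equal the same `sigma` ratios (squared
#' semi-axis ratios), so downstream shape tests are model-agnostic.
#'
#' @param n_points Number of points (>= 4).
#' @param sigma Target covariance eigenvalues `(s1, s2, s3)` in Angstrom^2,
#'   `s1 >= s2 >= s3 > 0`.
#' @param rotation Fixed 3 x 3 rotation, or `NULL` for a random one.
#' @param translation Length-3 offset added to every point.
#' @param noise_model `"gaussian"` or `"uniform_ellipsoid"`.
#' @param seed Optional seed; same seed gives identical coordinates.
#' @param pocket_id Identifier stored with the cloud.
#' @return A `pocket_cloud` whose `atoms` are synthetic carbon pseudo-atoms.
#' @export
sample_cloud <- function(n_points, sigma = c(9, 4, 1), rotation = NULL,
                         translation = c(0, 0, 0),
                         noise_model = c("gaussian", "uniform_ellipsoid"),
                         seed = NULL, pocket_id = "synthetic") {
  noise_model <- match.arg(noise_model)
  stopifnot(n_points >= 4L, length(sigma) == 3L, all(sigma > 0),
            !is.unsorted(rev(sigma)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(rotation)) rotation <- random_rotation()
  stopifnot(all(dim(rotation) == c(3L, 3L)),
            max(abs(crossprod(rotation) - diag(3))) < 1e-8)

  if (noise_model == "gaussian") {
    pts <- matrix(rnorm(3L * n_points), n_points, 3L) %*%
      diag(sqrt(sigma))
  } else {
    # uniform in a ball: covariance r^2/5 * I at r = 1, so semi-axes
    # sqrt(5 * sigma) give population covariance diag(sigma)
    u <- matrix(rnorm(3L * n_points), n_points, 3L)
    u <- u / sqrt(rowSums(u^2))
    r <- runif(n_points)^(1 / 3)
    pts <- (u * r) %*% diag(sqrt(5 * sigma))
  }
  pts <- pts %*% t(rotation)
  pts <- sweep(pts, 2L, -as.numeric(translation))

  atoms <- data.frame(chain = "A", resid = "SYN",
                      resno = seq_len(n_points), insert = "",
                      elety = "C", alt = "", elesy = "C",
                      x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                      het = FALSE, stringsAsFactors = FALSE)
  structure(list(structure_id = "synthetic", ligand_id = pocket_id,
                 level = "residue", cutoff = NA_real_, atoms = atoms,
                 member_residues = atoms[, c("chain", "resno", "insert",
                                             "resid")],
                 n_atoms = n_points, n_residues = n_points,
                 degenerate = FALSE),
            class = "pocket_cloud")
}

# Serialize an atom table to PDB records (no altloc collapsing).
.pdb_atom_lines <- function(at, start_serial = 1L) {
  sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$het, "HETATM", "ATOM"),
    start_serial + seq_len(nrow(at)) - 1L,
    ifelse(nchar(at$elety) < 4L, paste0(" ", at$elety), at$elety),
    substr(paste0(at$alt, " "), 1L, 1L),
    at$resid, at$chain, at$resno, substr(paste0(at$insert, " "), 1L, 1L),
    at$x, at$y, at$z, 1.0, 0.0, at$elesy)
}

.cif_atom_lines <- function(at, structure_id = "TOY") {
  c(paste0("data_", structure_id),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    sprintf("%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
            ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)), at$elesy,
            at$elety, ifelse(at$alt == "", ".", at$alt), at$resid, at$chain,
            at$resno, ifelse(at$insert == "", "?", at$insert),
            at$x, at$y, at$z, at$resno, at$resid, at$chain, at$elety))
}

.toy_atom <- function(chain, resid, resno, elety, elesy, x, y, z,
                      het = FALSE, alt = "") {
  data.frame(chain = chain, resid = resid, resno = resno, insert = "",
             elety = elety, alt = alt, elesy = elesy,
             x = x, y = y, z = z, het = het, stringsAsFactors = FALSE)
}

#' Write a designed toy macromolecule--ligand complex
#'
#' Emits a minimal, valid structure file with a HETATM ligand (residue VIB)
#' and macromolecular residues placed at designed distances. Each preset
#' exercises one preprocessing or extraction rule:
#' \describe{
#'   \item{`two_residue_threshold`}{residue 1 has heavy atoms at 5.9 and
#'     9.0 A from the ligand, residue 2 one atom at 6.1 A: residue-level
#'     extraction at 6 A keeps all of residue 1 and nothing of residue 2.}
#'   \item{`shell`}{single-atom residues on shells from 3 to 8 A, for
#'     cutoff-monotonicity checks.}
#'   \item{`altloc_case`}{atoms with alternate locations in both A-first
#'     and B-first listing order: preprocessing must keep the first listed
#'     conformer, not the one labelled "A".}
#'   \item{`hydrogen_case`}{residues with heavy atoms inside the cutoff and
#'     explicit hydrogens attached; membership must be decided on heavy
#'     atoms only. Geometry is jittered by `seed` so batches of distinct
#'     fixtures can be generated.}
#'   \item{`multimodel_case`}{two MODEL blocks with different coordinates;
#'     only the first must be read (PDB format only).}
#' }
#'
#' @param preset One of the preset names above.
#' @param path Output file path.
#' @param seed Seed controlling the jitter of `hydrogen_case` (ignored by
#'   the deterministic presets).
#' @param format `"pdb"` or `"cif"`.
#' @return Invisibly, `path`.
#' @export
write_toy_complex <- function(preset = c("two_residue_threshold", "shell",
                                         "altloc_case", "hydrogen_case",
                                         "multimodel_case"),
                              path, seed = 1L, format = c("pdb", "cif")) {
  preset <- match.arg(preset)
  format <- match.arg(format)
  lig <- .toy_atom("L", "VIB", 101L, "C1", "C", 0, 0, 0, het = TRUE)

  at <- switch(preset,
    two_residue_threshold = rbind(
      lig,
      .toy_atom("A", "ALA", 1L, "CA", "C", 5.9, 0, 0),
      .toy_atom("A", "ALA", 1L, "CB", "C", 9.0, 0, 0),
      .toy_atom("A", "ALA", 2L, "CA", "C", 0, 6.1, 0)),
    shell = {
      radii <- c(3, 3.5, 4, 4.5, 5, 5.5, 6, 7, 8)
      dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0),
                    c(0, -1, 0), c(0, 0, -1),
                    c(1, 1, 1) / sqrt(3), c(1, -1, 0) / sqrt(2),
                    c(-1, 0, 1) / sqrt(2))
      rbind(lig, do.call(rbind, lapply(seq_along(radii), function(i) {
        p <- radii[i] * dirs[i, ]
        .toy_atom("A", "GLY", i, "CA", "C", p[1L], p[2L], p[3L])
      })))
    },
    altloc_case = rbind(
      lig,
      .toy_atom("A", "ALA", 1L, "N", "N", 1.0, 1.0, 0),
      # CA: altloc A listed first, then B
      .toy_atom("A", "ALA", 1L, "CA", "C", 1.0, 0, 0, alt = "A"),
      .toy_atom("A", "ALA", 1L, "CA", "C", 2.0, 0, 0, alt = "B"),
      # CB: altloc B listed first, then A -- first listed must win
      .toy_atom("A", "ALA", 1L, "CB", "C", 3.0, 0, 0, alt = "B"),
      .toy_atom("A", "ALA", 1L, "CB", "C", 4.0, 0, 0, alt = "A"),
      .toy_atom("A", "ALA", 1L, "C", "C", 0, 1.5, 0),
      .toy_atom("A", "ALA", 1L, "O", "O", 0, 2.5, 0)),
    hydrogen_case = {
      set.seed(as.integer(seed))
      # per-seed anisotropy: heavy atoms from a random triaxial Gaussian
      # centred near the ligand, one hydrogen bonded ~1 A to each heavy atom
      sig <- sqrt(c(runif(1L, 4, 9), runif(1L, 1.5, 4), runif(1L, 0.3, 1.5)))
      R <- random_rotation()
      res <- do.call(rbind, lapply(1:4, function(r) {
        heavy <- do.call(rbind, lapply(1:10, function(k) {
          p <- as.numeric(R %*% (rnorm(3L) * sig))
          .toy_atom("A", "ALA", r, paste0("C", k), "C", p[1L], p[2L], p[3L])
        }))
        hs <- do.call(rbind, lapply(1:10, function(k) {
          u <- rnorm(3L)
          u <- u / sqrt(sum(u^2))
          p <- c(heavy$x[k], heavy$y[k], heavy$z[k]) + u
          .toy_atom("A", "ALA", r, paste0("H", k), "H", p[1L], p[2L], p[3L])
        }))
        rbind(heavy, hs)
      }))
      rbind(lig, res)
    },
    multimodel_case = rbind(
      lig,
      .toy_atom("A", "ALA", 1L, "CA", "C", 2.0, 0, 0),
      .toy_atom("A", "ALA", 1L, "CB", "C", 3.0, 0, 0),
      .toy_atom("A", "ALA", 1L, "N", "N", 2.0, 1.0, 0),
      .toy_atom("A", "ALA", 1L, "C", "C", 2.0, -1.0, 0)))

  if (preset == "multimodel_case") {
    if (format == "cif") stop("multimodel_case is PDB-only")
    at2 <- at
    at2$x <- at2$x + 9
    writeLines(c("MODEL        1", .pdb_atom_lines(at), "ENDMDL",
                 "MODEL        2", .pdb_atom_lines(at2), "ENDMDL", "END"),
               path)
  } else if (format == "pdb") {
    writeLines(c(.pdb_atom_lines(at), "END"), path)
  } else {
    writeLines(.cif_atom_lines(at, paste0("TOY_", toupper(preset))), path)
  }
  invisible(path)
}

#' Validate a cohort specification table
#'
#' A cohort spec has one row per (group, archetype) cell with the target
#' ratio centroids/spreads and size-descriptor distributions used by
#' [sample_cohort()].
#'
#' @param spec Data frame with columns `group`, `archetype`, `n`, `c21`,
#'   `c32` (centroids of rEV21/rEV32, in \[0,1\]), `s21`, `s32` (SDs),
#'   `atoms_mean`, `atoms_sd`, `rg_mean`, `rg_sd`.
#' @return The validated spec (invisibly usable as-is).
#' @export
cohort_spec <- function(spec) {
  need <- c("group", "archetype", "n", "c21", "c32", "s21", "s32",
            "atoms_mean", "atoms_sd", "rg_mean", "rg_sd")
  stopifnot(is.data.frame(spec), all(need %in% names(spec)))
  stopifnot(all(spec$n >= 0), all(spec$c21 >= 0 & spec$c21 <= 1),
            all(spec$c32 >= 0 & spec$c32 <= 1),
            all(spec$s21 >= 0), all(spec$s32 >= 0),
            all(spec$archetype %in% archetype_levels()))
  spec
}

#' Sample a synthetic descriptor cohort
#'
#' Draws per-pocket (rEV21, rEV32) around per-(group, archetype) centroids
#' with Gaussian spread, sets rEV31 to their product (so the algebraic
#' identity holds by construction), and draws size descriptors from the
#' stated normal distributions. Ratios falling outside \[0, 1\] are clipped
#' by default, or redrawn with `truncation = "resample"`.
#'
#' @param spec A [cohort_spec()] table; default [reference_cohort_spec()].
#' @param seed Seed for reproducibility.
#' @param truncation `"clip"` (default) or `"resample"`.
#' @return Data frame with columns `pocket_id`, `group`, `archetype_true`,
#'   `rEV21`, `rEV32`, `rEV31`, `n_atoms`, `Rg`.
#' @export
sample_cohort <- function(spec = reference_cohort_spec(), seed = 1L,
                          truncation = c("clip", "resample")) {
  spec <- cohort_spec(spec)
  truncation <- match.arg(truncation)
  set.seed(as.integer(seed))
  draw_ratio <- function(n, centre, spread) {
    if (spread == 0) return(rep(centre, n))
    x <- rnorm(n, centre, spread)
    if (truncation == "clip") {
      pmin(pmax(x, 0), 1)
    } else {
      bad <- which(x < 0 | x > 1)
      while (length(bad) > 0L) {
        x[bad] <- rnorm(length(bad), centre, spread)
        bad <- which(x < 0 | x > 1)
      }
      x
    }
  }
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    if (s$n == 0L) return(NULL)
    r21 <- draw_ratio(s$n, s$c21, s$s21)
    r32 <- draw_ratio(s$n, s$c32, s$s32)
    data.frame(
      pocket_id = sprintf("%s_%s_%03d", s$group, s$archetype, seq_len(s$n)),
      group = s$group, archetype_true = s$archetype,
      rEV21 = r21, rEV32 = r32, rEV31 = r21 * r32,
      n_atoms = pmax(4L, round(rnorm(s$n, s$atoms_mean, s$atoms_sd))),
      Rg = pmax(0.1, rnorm(s$n, s$rg_mean, s$rg_sd)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
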