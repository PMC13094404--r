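#' Read a macromolecular structure file
#'
#' Loads a PDB or mmCIF file into a `structure_model`: a flat atom table with
#' coordinates in Angstroms plus provenance. Only the first model of
#' multi-model (e.g. NMR) files is retained; all alternate-location variants
#' are kept as read and resolved later by [preprocess_structure()].
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"auto"` (default, by file extension), `"pdb"`, or `"cif"`.
#' @param structure_id Identifier stored with the model; defaults to the file
#'   name without extension.
#' @return An object of class `structure_model`: a list with elements
#'   `structure_id` and `atoms`, the latter a data frame with columns
#'   `chain`, `resid`, `resno`, `insert`, `elety` (atom name), `alt`
#'   (alternate-location indicator), `elesy` (element symbol), `x`, `y`, `z`,
#'   and `het` (HETATM flag).
#' @seealso [preprocess_structure()], [extract_pocket()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           structure_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      cif = "cif", mmcif = "cif",
      pdb = "pdb", ent = "pdb",
      "pdb")
  }
  raw <- if (format == "cif") {
    suppressWarnings(bio3d::read.cif(path))
  } else {
    # rm.alt = FALSE: altloc resolution is "first listed", not "altloc A",
    # and belongs to preprocess_structure()
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     hex = TRUE))
  }
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("no atoms parsed from ", path)
  }
  atoms <- data.frame(
    chain  = as.character(at$chain),
    resid  = toupper(as.character(at$resid)),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    elety  = as.character(at$elety),
    alt    = ifelse(is.na(at$alt), "", as.character(at$alt)),
    elesy  = .normalize_element(at$elesy, at$elety),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    het = as.character(at$type) == "HETATM",
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    stop("non-finite coordinates in ", path)
  }
  atoms$chain[is.na(atoms$chain)] <- ""
  if (is.null(structure_id)) {
    structure_id <- tools::file_path_sans_ext(basename(path))
  }
  structure(list(structure_id = structure_id, atoms = atoms),
            class = "structure_model")
}

# Element symbols: trust the file's element column when present, otherwise
# fall back to the leading alphabetic character of the atom name.
.normalize_element <- function(elesy, elety) {
  e <- toupper(trimws(as.character(elesy)))
  miss <- is.na(e) | e == ""
  if (any(miss)) {
    guess <- toupper(sub("^[0-9']*([A-Za-z]).*$", "\\1",
                         as.character(elety[miss])))
    e[miss] <- guess
  }
  e
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$structure_id, ": ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

#' Residue names removed as solvent and monoatomic ions
#'
#' Default residue-name lists used by [preprocess_structure()]. Waters cover
#' the common crystallographic names; the ion list contains monoatomic
#' species only -- polyatomic hetero groups (e.g. PO4, SO4) are retained.
#' @export
default_water_residues <- function() c("HOH", "WAT", "DOD")

#' @rdname default_water_residues
#' @export
default_ion_residues <- function() {
  c("NA", "K", "MG", "CA", "ZN", "CL", "MN", "FE", "NI", "CU", "CO", "CD",
    "BR", "IOD")
}

#' Clean a structure before pocket extraction
#'
#' Applies the standard preprocessing rules for pocket morphometrics:
#' removes solvent waters and monoatomic ions, drops hydrogen and deuterium
#' atoms (unless `keep_hydrogens`), and resolves alternate locations by
#' keeping only the first listed conformation of each atom.
#'
#' @param model A `structure_model` from [read_structure()].
#' @param keep_hydrogens Keep H/D atoms? Default `FALSE`. Used for the
#'   hydrogen-sensitivity analysis; pocket membership is always decided on
#'   heavy atoms regardless of this flag (see [extract_pocket()]).
#' @param water_residues,ion_residues Residue names removed as solvent and as
#'   monoatomic ions.
#' @param verbose Print a one-line removal summary.
#' @return A `structure_model` with attribute `"n_removed"` (named counts of
#'   atoms removed per rule).
#' @export
preprocess_structure <- function(model, keep_hydrogens = FALSE,
                                 water_residues = default_water_residues(),
                                 ion_residues = default_ion_residues(),
                                 verbose = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  n0 <- nrow(at)

  is_water <- at$resid %in% water_residues
  at <- at[!is_water, , drop = FALSE]
  n_water <- n0 - nrow(at)

  is_ion <- at$het & at$resid %in% ion_residues
  at <- at[!is_ion, , drop = FALSE]
  n_ion <- n0 - n_water - nrow(at)

  n_h <- 0L
  if (!keep_hydrogens) {
    is_h <- at$elesy %in% c("H", "D")
    at <- at[!is_h, , drop = FALSE]
    n_h <- sum(is_h)
  }

  # first listed altloc wins, per (chain, residue, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  dup <- duplicated(key)
  at <- at[!dup, , drop = FALSE]
  n_alt <- sum(dup)

  removed <- c(water = n_water, ion = n_ion, hydrogen = n_h, altloc = n_alt)
  if (verbose) {
    message(sprintf("preprocess %s: removed %d water, %d ion, %d H, %d altloc atoms (%d -> %d)",
                    model$structure_id, n_water, n_ion, n_h, n_alt, n0, nrow(at)))
  }
  if (nrow(at) == 0L) {
    warning("preprocessing removed all atoms of ", model$structure_id)
  }
  out <- structure(list(structure_id = model$structure_id, atoms = at),
                   class = "structure_model")
  attr(out, "n_removed") <- removed
  out
}

#' Select one ligand instance in a structure
#'
#' @param resname Ligand residue name, e.g. `"VIB"`.
#' @param chain Optional chain identifier to disambiguate multiple copies.
#' @param resno Optional residue sequence number.
#' @return An object of class `ligand_selector`.
#' @export
ligand_selector <- function(resname, chain = NULL, resno = NULL) {
  stopifnot(is.character(resname), length(resname) == 1L, nzchar(resname))
  structure(list(resname = toupper(resname), chain = chain,
                 resno = if (is.null(resno)) NULL else as.integer(resno)),
            class = "ligand_selector")
}

# All ligand instances matching a selector: one row per (chain, resno, insert).
.ligand_instances <- function(model, ligand) {
  at <- model$atoms
  hit <- at$het & at$resid == ligand$resname
  if (!is.null(ligand$chain)) hit <- hit & at$chain == ligand$chain
  if (!is.null(ligand$resno)) hit <- hit & at$resno == ligand$resno
  lat <- at[hit, , drop = FALSE]
  unique(lat[, c("chain", "resno", "insert", "resid")])
}

# Minimum distance from each row of a to the point set b (both Nx3 matrices).
.min_dist_to_set <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Extract the binding pocket around a ligand
#'
#' Defines the pocket by heavy-atom proximity to the ligand. In `"residue"`
#' mode (the default), every residue with at least one heavy atom within
#' `cutoff` Angstroms of any ligand heavy atom contributes *all* of its
#' atoms; in `"atom"` mode, only the individual heavy atoms within the
#' cutoff are returned. The distance test is inclusive (d <= cutoff) and is
#' always evaluated between heavy atoms, so pocket membership is identical
#' whether or not hydrogens were retained upstream.
#'
#' @param model A preprocessed `structure_model`.
#' @param ligand A [ligand_selector()], or a ligand residue name.
#' @param cutoff Proximity cutoff in Angstroms (default 6).
#' @param level `"residue"` (complete residues) or `"atom"` (individual
#'   heavy atoms).
#' @return An object of class `pocket_cloud`: list with `structure_id`,
#'   `ligand_id`, `level`, `cutoff`, `atoms` (data frame as in
#'   [read_structure()]), `member_residues`, `n_atoms`, `n_residues`, and
#'   `degenerate` (`TRUE` when fewer than 4 atoms, too few to define a 3-D
#'   shape).
#' @export
extract_pocket <- function(model, ligand, cutoff = 6.0,
                           level = c("residue", "atom")) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0)
  level <- match.arg(level)
  if (is.character(ligand)) ligand <- ligand_selector(ligand)
  stopifnot(inherits(ligand, "ligand_selector"))

  inst <- .ligand_instances(model, ligand)
  if (nrow(inst) == 0L) {
    stop("ligand ", ligand$resname, " not found in ", model$structure_id)
  }
  if (nrow(inst) > 1L) {
    stop("ligand ", ligand$resname, " is ambiguous in ", model$structure_id,
         "; candidates: ",
         paste(sprintf("%s:%s%d%s", inst$resid, inst$chain, inst$resno,
                       inst$insert), collapse = ", "),
         ". Disambiguate with ligand_selector(chain=, resno=).")
  }

  at <- model$atoms
  is_lig <- at$het & at$resid == inst$resid & at$chain == inst$chain &
    at$resno == inst$resno & at$insert == inst$insert
  is_h <- at$elesy %in% c("H", "D")

  lig_xyz <- as.matrix(at[is_lig & !is_h, c("x", "y", "z")])
  if (nrow(lig_xyz) == 0L) stop("ligand has no heavy atoms")

  cand <- !is_lig
  cand_heavy <- cand & !is_h
  if (!any(cand_heavy)) stop("no candidate heavy atoms outside the ligand")

  dmin <- .min_dist_to_set(as.matrix(at[cand_heavy, c("x", "y", "z")]),
                           lig_xyz)
  within <- dmin <= cutoff

  if (level == "atom") {
    keep_idx <- which(cand_heavy)[within]
  } else {
    rkey <- paste(at$chain, at$resno, at$insert, at$resid, sep = "\r")
    hit_res <- unique(rkey[cand_heavy][within])
    keep_idx <- which(cand & rkey %in% hit_res)
  }
  pocket_at <- at[keep_idx, , drop = FALSE]
  if (nrow(pocket_at) == 0L) {
    stop("degenerate pocket: no atoms within ", cutoff, " A of ",
         ligand$resname)
  }
  member <- unique(pocket_at[, c("chain", "resno", "insert", "resid")])
  rownames(member) <- rownames(pocket_at) <- NULL

  structure(list(
    structure_id = model$structure_id,
    ligand_id = sprintf("%s:%s%d%s", inst$resid, inst$chain, inst$resno,
                        inst$insert),
    level = level, cutoff = cutoff,
    atoms = pocket_at,
    member_residues = member,
    n_atoms = nrow(pocket_at),
    n_residues = nrow(member),
    degenerate = nrow(pocket_at) < 4L
  ), class = "pocket_cloud")
}

#' @export
print.pocket_cloud <- function(x, ...) {
  cat("<pocket_cloud> ", x$structure_id, " / ", x$ligand_id,
      " (", x$level, " level, ", x$cutoff, " A): ",
      x$n_atoms, " atoms in ", x$n_residues, " residues",
      if (isTRUE(x$degenerate)) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Coordinates of a pocket as an N x 3 matrix
#' @param x A `pocket_cloud` (or any object with an `atoms` data frame).
#' @return Numeric matrix with columns x, y, z (Angstroms).
#' @export
pocket_coords <- function(x) {
  at <- if (is.data.frame(x)) x else x$atoms
  as.matrix(at[, c("x", "y", "z"), drop = FALSE])
}

#' Write a pocket as a PDB subset plus a JSON provenance sidecar
#'
#' @param pocket A `pocket_cloud`.
#' @param path Output PDB path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return Invisibly, the PDB path.
#' @export
write_pocket_pdb <- function(pocket, path) {
  stopifnot(inherits(pocket, "pocket_cloud"))
  at <- pocket$atoms
  rec <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$het, "HETATM", "ATOM"),
    seq_len(nrow(at)),
    ifelse(nchar(at$elety) < 4L, paste0(" ", at$elety), at$elety),
    substr(paste0(at$alt, " "), 1L, 1L),
    at$resid, at$chain, at$resno, substr(paste0(at$insert, " "), 1L, 1L),
    at$x, at$y, at$z, 1.0, 0.0, at$elesy)
  writeLines(c(rec, "END"), path)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(structure_id = pocket$structure_id, ligand = pocket$ligand_id,
         cutoff = pocket$cutoff, level = pocket$level,
         n_atoms = pocket$n_atoms, n_residues = pocket$n_residues,
         degenerate = pocket$degenerate),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
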