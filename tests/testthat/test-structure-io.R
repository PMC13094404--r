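test_that("PDB round-trip preserves atoms and coordinates exactly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_complex("two_residue_threshold", path)
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 4L)
  lig <- m$atoms[m$atoms$het, ]
  expect_equal(lig$resid, "VIB")
  expect_equal(c(lig$x, lig$y, lig$z), c(0, 0, 0))
  r1 <- m$atoms[m$atoms$resno == 1 & !m$atoms$het, ]
  expect_equal(sort(r1$x), c(5.9, 9.0))
})

test_that("the same complex as PDB and mmCIF parses to identical atoms", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_toy_complex("two_residue_threshold", pdb, format = "pdb")
  write_toy_complex("two_residue_threshold", cif, format = "cif")
  a <- read_structure(pdb)$atoms
  b <- read_structure(cif)$atoms
  cols <- c("chain", "resid", "resno", "elety", "elesy", "x", "y", "z", "het")
  key <- function(at) at[order(at$chain, at$resno, at$elety), cols]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("only the first MODEL of a multi-model file is read", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_complex("multimodel_case", path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 5L)          # 1 ligand + 4 residue atoms
  expect_true(all(m$atoms$x < 9))          # MODEL 2 is shifted by +9
})

test_that("unreadable or empty input raises an error", {
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "not found")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(suppressWarnings(read_structure(empty)))
})

test_that("preprocessing removes waters, ions and hydrogens by rule", {
  at <- rbind(
    do.call(rbind, lapply(1:10, function(i) {
      fixture_atom("A", "ALA", i, "CA", "C", i, 0, 0)
    })),
    do.call(rbind, lapply(1:4, function(i) {
      fixture_atom("A", "ALA", i, "HA", "H", i, 1, 0)
    })),
    fixture_atom("W", "HOH", 201, "O", "O", 20, 0, 0, het = TRUE),
    fixture_atom("W", "HOH", 202, "O", "O", 21, 0, 0, het = TRUE),
    fixture_atom("I", "MG", 301, "MG", "MG", 22, 0, 0, het = TRUE))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(at, path)
  m <- read_structure(path)

  clean <- preprocess_structure(m)
  expect_equal(nrow(clean$atoms), 10L)
  expect_false(any(clean$atoms$elesy %in% c("H", "D")))
  expect_equal(unname(attr(clean, "n_removed")),
               c(2L, 1L, 4L, 0L), ignore_attr = TRUE)

  keep_h <- preprocess_structure(m, keep_hydrogens = TRUE)
  expect_equal(nrow(keep_h$atoms), 14L)
  expect_false(any(keep_h$atoms$resid == "HOH"))
})

test_that("the first listed altloc wins regardless of its letter", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_complex("altloc_case", path)
  m <- preprocess_structure(read_structure(path))
  ca <- m$atoms[m$atoms$elety == "CA" & !m$atoms$het, ]
  cb <- m$atoms[m$atoms$elety == "CB" & !m$atoms$het, ]
  expect_equal(nrow(ca), 1L)
  expect_equal(nrow(cb), 1L)
  expect_equal(ca$x, 1.0)  # A listed first
  expect_equal(cb$x, 3.0)  # B listed first: keep B, not "altloc A"
})

test_that("residue-level extraction keeps complete residues at the cutoff", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_complex("two_residue_threshold", path)
  m <- preprocess_structure(read_structure(path))

  p_res <- extract_pocket(m, "VIB", cutoff = 6, level = "residue")
  expect_equal(p_res$n_atoms, 2L)                 # both atoms of residue 1
  expect_equal(unique(p_res$atoms$resno), 1L)
  expect_true(9.0 %in% p_res$atoms$x)             # far atom dragged in
  expect_true(p_res$degenerate)                   # < 4 atoms

  p_atm <- extract_pocket(m, "VIB", cutoff = 6, level = "atom")
  expect_equal(p_atm$n_atoms, 1L)
  expect_equal(p_atm$atoms$x, 5.9)
})

test_that("atom count is monotone in cutoff and atom mode is a subset", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_complex("shell", path)
  m <- preprocess_structure(read_structure(path))
  lig_xyz <- c(0, 0, 0)
  prev <- 0L
  for (cut in c(4, 5, 6, 7)) {
    p <- extract_pocket(m, "VIB", cutoff = cut)
    # brute-force: count residue atoms within the shell by direct scan
    d <- sqrt(m$atoms$x^2 + m$atoms$y^2 + m$atoms$z^2)
    expected <- sum(d[!m$atoms$het] <= cut)
    expect_equal(p$n_atoms, expected)
    expect_gte(p$n_atoms, prev)
    prev <- p$n_atoms

    pa <- extract_pocket(m, "VIB", cutoff = cut, level = "atom")
    res_key <- with(p$atoms, paste(chain, resno, elety))
    atm_key <- with(pa$atoms, paste(chain, resno, elety))
    expect_true(all(atm_key %in% res_key))
  }
})

test_that("extraction is invariant under rigid-body motion of the complex", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_complex("shell", path)
  m <- preprocess_structure(read_structure(path))
  ref <- extract_pocket(m, "VIB", cutoff = 5.5)

  R <- random_rotation(seed = 42)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m2 <- m
  m2$atoms$x <- xyz[, 1] + 12.3
  m2$atoms$y <- xyz[, 2] - 4.5
  m2$atoms$z <- xyz[, 3] + 0.7
  rot <- extract_pocket(m2, "VIB", cutoff = 5.5)
  expect_equal(rot$member_residues, ref$member_residues)
})

test_that("ambiguous or missing ligands are reported with candidates", {
  at <- rbind(
    fixture_atom("A", "VIB", 101, "C1", "C", 0, 0, 0, het = TRUE),
    fixture_atom("B", "VIB", 102, "C1", "C", 10, 0, 0, het = TRUE),
    fixture_atom("A", "ALA", 1, "CA", "C", 2, 0, 0))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(at, path)
  m <- read_structure(path)
  expect_error(extract_pocket(m, "VIB"), "ambiguous")
  expect_error(extract_pocket(m, "XYZ"), "not found")
  p <- extract_pocket(m, ligand_selector("VIB", chain = "A"))
  expect_equal(p$ligand_id, "VIB:A101")
})

test_that("pocket PDB export round-trips with a JSON sidecar", {
  src <- withr::local_tempfile(fileext = ".pdb")
  write_toy_complex("shell", src)
  m <- preprocess_structure(read_structure(src))
  p <- extract_pocket(m, "VIB", cutoff = 6)

  out <- withr::local_tempfile(fileext = ".pdb")
  write_pocket_pdb(p, out)
  back <- read_structure(out)
  expect_equal(nrow(back$atoms), p$n_atoms)
  expect_equal(back$atoms$x, p$atoms$x)

  sidecar <- jsonlite::read_json(sub("\\.pdb$", ".json", out))
  expect_equal(sidecar$n_atoms, p$n_atoms)
  expect_equal(sidecar$cutoff, 6)
  expect_equal(sidecar$level, "residue")
})
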