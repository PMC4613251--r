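# PDB reading/writing, altloc and model handling, atom classification
# and the alanine mutation.

test_that("PDB write/read round-trips a built polyalanine chain", {
  h <- build_chain(chain_recipe(rep("ALA", 3), phi = -57, psi = -47))
  f <- tempfile(fileext = ".pdb")
  write_pdb(h, f)
  back <- read_pdb(f)
  expect_equal(n_residues(back), 3L)
  expect_equal(length(unique(back$chain)), 1L)
  expect_equal(nrow(back), nrow(h))
  ord <- match(paste(h$resno, h$name), paste(back$resno, back$name))
  expect_false(anyNA(ord))
  expect_equal(as.matrix(back[ord, c("x", "y", "z")]),
               as.matrix(h[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("HETATM-only files raise an empty-structure error", {
  f <- write_pdb_text(c(
    pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0, record = "HETATM"),
    pdb_atom_line(2, "O", "HOH", "A", 2, 3, 0, 0, record = "HETATM"),
    "END"))
  expect_error(read_pdb(f), class = "dipolecd_empty_structure")
})

test_that("multi-model files return the requested model's coordinates", {
  res_lines <- function(xoff) c(
    pdb_atom_line(1, "N", "ALA", "A", 1, xoff + 0.0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, xoff + 1.458, 0, 0),
    pdb_atom_line(3, "C", "ALA", "A", 1, xoff + 2.009, 1.42, 0),
    pdb_atom_line(4, "O", "ALA", "A", 1, xoff + 2.9, 1.75, 0.77))
  f <- write_pdb_text(c("MODEL        1", res_lines(0), "ENDMDL",
                        "MODEL        2", res_lines(10), "ENDMDL", "END"))
  m1 <- read_pdb(f, model = 1)
  m2 <- read_pdb(f, model = 2)
  expect_equal(m2$x, m1$x + 10, tolerance = 1e-6)
  expect_error(read_pdb(f, model = 3), class = "dipolecd_input_error")
})

test_that("altloc resolution keeps highest occupancy, ties alphabetical", {
  f <- write_pdb_text(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0, occ = 0.4,
                  altloc = "A"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, 1.50, 0, 0, occ = 0.6,
                  altloc = "B"),
    pdb_atom_line(4, "C", "ALA", "A", 1, 2.01, 1.42, 0, occ = 0.5,
                  altloc = "B"),
    pdb_atom_line(5, "C", "ALA", "A", 1, 2.05, 1.42, 0, occ = 0.5,
                  altloc = "A"),
    pdb_atom_line(6, "O", "ALA", "A", 1, 2.90, 1.75, 0.77),
    "END"))
  s <- read_pdb(f)
  expect_equal(nrow(s), 4L)
  expect_equal(s$x[s$name == "CA"], 1.50, tolerance = 1e-6)  # occupancy
  expect_equal(s$x[s$name == "C"], 2.05, tolerance = 1e-6)   # tie -> "A"
})

test_that("a residue missing backbone atoms is named in the error", {
  f <- write_pdb_text(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0),
    "END"))
  expect_error(read_pdb(f), class = "dipolecd_missing_atom")
  expect_error(read_pdb(f), regexp = "ALA A1")
})

test_that("classification counts one triad per peptide bond", {
  for (n in c(2L, 5L, 9L)) {
    h <- ideal_helix(n)
    cl <- classify_units(h)
    expect_equal(cl$q, n - 1L)
    expect_equal(cl$p, n)
  }
})

test_that("Ala-Ala without hydrogens classifies exactly as expected", {
  h <- build_chain(chain_recipe(rep("ALA", 2), phi = -57, psi = -47))
  cl <- classify_units(h)
  expect_equal(cl$q, 1L)
  # isotropic set: both CA and both CB, nothing else
  expect_setequal(paste0(cl$isotropic$name, cl$isotropic$resno),
                  c("CA1", "CA2", "CB1", "CB2"))
  expect_true(all(cl$isotropic$species == "C_aliphatic"))
  # terminal groups and the free amine are ignored with reasons
  ign <- paste0(cl$ignored$name, cl$ignored$resno)
  expect_true(all(c("N1", "C2", "O2") %in% ign))
})

test_that("methyl hydrogens are dropped but CB stays", {
  h <- build_chain(chain_recipe(rep("ALA", 2), phi = -57, psi = -47),
                   hydrogens = TRUE)
  cl <- classify_units(h, include_hydrogens = TRUE,
                       drop_methyl_hydrogens = TRUE)
  expect_true(any(cl$isotropic$name == "CB"))
  expect_false(any(grepl("^HB", cl$isotropic$name)))
  expect_true(any(grepl("methyl", cl$ignored$reason)))
  # amide H and HA survive as isotropic species
  expect_true("H_amide" %in% cl$isotropic$species)
  expect_true("H_aliphatic" %in% cl$isotropic$species)

  cl_keep <- classify_units(h, include_hydrogens = TRUE,
                            drop_methyl_hydrogens = FALSE)
  expect_true(any(grepl("^HB", cl_keep$isotropic$name)))

  cl_noh <- classify_units(h, include_hydrogens = FALSE)
  expect_false(any(grepl("^H", cl_noh$isotropic$element)))
})

test_that("chain breaks split the triad count", {
  a <- build_chain(chain_recipe(rep("ALA", 4), phi = -57, psi = -47))
  b <- build_chain(chain_recipe(rep("ALA", 3), phi = -57, psi = -47),
                   resno_start = 10L)
  b$x <- b$x + 30
  both <- new_protein_structure(dplyr::bind_rows(
    tibble::as_tibble(a), tibble::as_tibble(b)))
  cl <- classify_units(both)
  expect_equal(cl$p, 7L)
  expect_equal(cl$q, (4L - 1L) + (3L - 1L))  # no bond across the gap
})

test_that("classification is deterministic and leaves coordinates alone", {
  h <- ideal_helix(6)
  before <- as.matrix(h[, c("x", "y", "z")])
  cl1 <- classify_units(h)
  cl2 <- classify_units(h)
  expect_identical(cl1$triads, cl2$triads)
  expect_identical(cl1$isotropic, cl2$isotropic)
  expect_identical(as.matrix(h[, c("x", "y", "z")]), before)
})

test_that("alanize strips side chains beyond CB and renames", {
  h <- build_chain(chain_recipe(rep("ALA", 3), phi = -57, psi = -47))
  # dress residue 2 up as PHE with ring atoms, and residue 3 as SER
  extra <- tibble::tibble(
    name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OG"),
    element = c(rep("C", 6), "O"),
    resno = c(rep(2L, 6), 3L),
    resid = c(rep("PHE", 6), "SER"),
    chain = "A",
    x = 20 + seq_len(7), y = 0, z = 0, occupancy = 1, altloc = "")
  s <- tibble::as_tibble(h)
  s$resid[s$resno == 2] <- "PHE"
  s$resid[s$resno == 3] <- "SER"
  s <- new_protein_structure(dplyr::bind_rows(s, extra))

  out <- alanize(s)
  expect_true(all(out$resid == "ALA"))
  expect_false(any(out$name %in% c("CG", "CD1", "OG")))
  expect_true(all(table(out$name[out$name == "CB"]) == 3))
  # backbone and CB coordinates untouched
  expect_equal(out$x[out$name == "CA"], h$x[h$name == "CA"])

  # all-aliphatic chain passes through identically
  expect_identical(tibble::as_tibble(alanize(h)), tibble::as_tibble(h))
})
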