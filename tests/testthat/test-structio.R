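# Structure I/O: PDB round trips, selection, fragment registry.

pdb_lines <- function(...) paste0(...)

write_mini_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                      altloc = " ", icode = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), altloc, resname, chain, resno, icode,
          x, y, z, 1.0, 0.0, element)
}

test_that("a hand-written PDB file is parsed with exact coordinates", {
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(f, c(atom_line(1, "CA", "ALA", "A", 1, 1.0, 2.0, 3.0),
                      atom_line(2, "CB", "ALA", "A", 1, 4.5, -2.25, 0.125),
                      atom_line(3, "CA", "GLY", "B", 7, -11.5, 0.0, 99.999)))
  s <- read_pdb(f)
  expect_equal(n_atoms(s), 3)
  expect_equal(unname(coords(s)[1, ]), c(1, 2, 3))
  expect_equal(unname(coords(s)[3, ]), c(-11.5, 0, 99.999))
  expect_equal(s$atoms$chain, c("A", "A", "B"))
  expect_equal(s$atoms$resno, c(1L, 1L, 7L))
})

test_that("write/read round trip preserves atoms, order and coordinates", {
  h <- build_ideal_helix(helix_spec(n_residues = 8), chain = "Q")
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(h, f1)
  s1 <- read_pdb(f1)
  write_pdb(s1, f2)
  s2 <- read_pdb(f2)
  expect_equal(n_atoms(s1), n_atoms(h))
  expect_equal(s1$atoms$name, h$atoms$name)
  expect_equal(s1$atoms$chain, h$atoms$chain)
  expect_equal(s1$atoms$resno, h$atoms$resno)
  expect_lt(max(abs(coords(s1) - coords(h))), 1e-3)
  expect_equal(s1$atoms, s2$atoms)
})

test_that("a generated bundle survives a disk round trip", {
  f <- tempfile(fileext = ".pdb")
  write_pdb(fx_pair$short, f)
  s <- read_pdb(f)
  expect_equal(n_atoms(s), n_atoms(fx_pair$short))
  expect_lt(max(abs(coords(s) - coords(fx_pair$short))), 1e-3)
})

test_that("single-atom write produces fixed-column coordinates", {
  s <- mk_struct(1, 2, 3, name = "CA")
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  txt <- readLines(f)
  expect_true(any(grepl("1.000   2.000   3.000", txt, fixed = TRUE)))
  expect_true(any(grepl("^END", txt)))
})

test_that("empty structures are rejected on write and read", {
  s <- mk_struct(1, 2, 3)
  s$atoms <- s$atoms[0, ]
  expect_error(write_pdb(s, tempfile()), class = "groovedock_empty_error")
  f <- tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_pdb(f), class = "groovedock_empty_error")
  expect_error(read_pdb(tempfile("nope")), class = "groovedock_io_error")
})

test_that("altloc records other than blank/'A' are skipped with a warning", {
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(f, c(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, altloc = "A"),
                      atom_line(2, "CA", "ALA", "A", 2, 1, 1, 1, altloc = "B"),
                      atom_line(3, "CA", "ALA", "A", 3, 2, 2, 2)))
  expect_warning(s <- read_pdb(f), "altloc")
  expect_equal(n_atoms(s), 2)
})

test_that("insertion codes are rejected", {
  f <- tempfile(fileext = ".pdb")
  write_mini_pdb(f, c(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, icode = "A")))
  expect_error(read_pdb(f), class = "groovedock_value_error")
})

test_that("HETATM records are skipped by default", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
               sub("^ATOM  ", "HETATM", atom_line(2, "O", "HOH", "A", 2, 5, 5, 5)),
               "END"), f)
  expect_equal(n_atoms(read_pdb(f)), 1)
  expect_equal(n_atoms(read_pdb(f, keep_hetatm = TRUE)), 2)
})

test_that("select restricts to chain and residue range, preserving order", {
  s <- mk_struct(1:6, 0, 0, chain = rep(c("A", "B"), each = 3),
                 resno = c(10, 11, 12, 10, 11, 12), name = rep("CA", 6))
  a <- select_atoms(s, "A")
  expect_equal(a$atoms$chain, rep("A", 3))
  seg <- helix_segment("A", 11, 12)
  b <- select_atoms(s, "A", seg)
  expect_equal(b$atoms$resno, c(11L, 12L))
  # idempotence
  expect_equal(select_atoms(b, "A", seg)$atoms, b$atoms)
  expect_error(select_atoms(s, "Z"), class = "groovedock_lookup_error")
  expect_error(select_atoms(s, "A", helix_segment("A", 90, 99)),
               class = "groovedock_empty_error")
})

test_that("selecting an M4-like segment from a long chain returns 24 residues", {
  h <- build_ideal_helix(helix_spec(n_residues = 900, helix_radius = 30),
                         chain = "G", resno_start = 1L, cb_offset = NA)
  fb <- fragment_bounds("GluN1-M4")
  sel <- select_atoms(h, "G", helix_segment("G", fb[["start"]], fb[["end"]]))
  expect_equal(length(unique(sel$atoms$resno)), 24)
})

test_that("fragment registry holds the construct residue ranges", {
  expect_equal(unname(fragment_bounds("ND2-TM-6-8")), c(151L, 223L))
  expect_equal(unname(fragment_bounds("ND2-TM-7-8")), c(175L, 223L))
  expect_equal(unname(fragment_bounds("ND2-TM-6-8+loop")), c(151L, 240L))
  expect_equal(unname(fragment_bounds("ND2-TM-10-11")), c(250L, 347L))
  expect_equal(unname(fragment_bounds("ND2-TM-6-7")), c(151L, 200L))
  expect_equal(unname(fragment_bounds("ND2-TM-6-11")), c(151L, 347L))
  expect_equal(unname(fragment_bounds("GluN1-M4")), c(813L, 836L))
  expect_equal(unname(fragment_bounds("ND2-Src-anchor")), c(239L, 321L))
  reg <- fragment_registry()
  expect_true(all(reg$start <= reg$end))
  err <- tryCatch(fragment_bounds("nope"), error = function(e) conditionMessage(e))
  expect_match(err, "ND2-TM-6-8")   # error lists known labels
})

test_that("fragment tables load from tab-separated text", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "label\tchain\tstart\tend", "frag1\tA\t5\t9"), f)
  d <- read_fragment_table(f)
  expect_equal(d$label, "frag1")
  expect_equal(d$start, 5L)
})

test_that("duplicate atom identities are rejected", {
  expect_error(
    mk_struct(c(0, 1), 0, 0, name = c("CA", "CA"), resno = c(1, 1)),
    class = "groovedock_value_error")
})

test_that("the shipped example fragment table parses", {
  f <- system.file("extdata", "example_fragments.tsv", package = "groovedock")
  d <- read_fragment_table(f)
  expect_true(all(c("label", "chain", "start", "end") %in% names(d)))
  expect_true(all(d$start <= d$end))
})
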