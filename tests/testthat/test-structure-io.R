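test_that("model count equals MODEL records", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeTwoModelPdb(p)
  models <- readStructure(p)
  expect_length(models, 2)
  expect_equal(vapply(models, modelIndex, integer(1)), 1:2)
  expect_equal(nrow(atomTable(models[[1]])), 3)
})

test_that("PDB round-trip preserves coordinates to format precision", {
  m <- buildTetrad(g4BuildSpec(twist = 30))
  p <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m, p, "pdb")
  m2 <- readStructure(p)[[1]]
  expect_equal(nrow(atomTable(m2)), nrow(atomTable(m)))
  expect_equal(residueTable(m2)$resno, residueTable(m)$resno)
  a1 <- atomTable(m); a2 <- atomTable(m2)
  a2 <- a2[match(paste(a1$chain, a1$resno, a1$elety),
                 paste(a2$chain, a2$resno, a2$elety)), ]
  expect_lt(max(abs(cbind(a1$x, a1$y, a1$z) -
                    cbind(a2$x, a2$y, a2$z))), 1e-3 + 1e-9)
  ## write(read(write(x))) is idempotent
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m2, p2, "pdb")
  m3 <- readStructure(p2)[[1]]
  expect_identical(atomTable(m3)[, c("x", "y", "z")],
                   atomTable(m2)[, c("x", "y", "z")])
})

test_that("mmCIF round-trip preserves coordinates and names", {
  m <- buildTetrad(g4BuildSpec(twist = 30))
  p <- withr::local_tempfile(fileext = ".cif")
  writeStructure(m, p, "mmcif")
  m2 <- readStructure(p)[[1]]
  a1 <- atomTable(m); a2 <- atomTable(m2)
  expect_equal(nrow(a2), nrow(a1))
  expect_setequal(a2$elety[a2$resno == 1], a1$elety[a1$resno == 1])
  a2 <- a2[match(paste(a1$resno, a1$elety), paste(a2$resno, a2$elety)), ]
  expect_lt(max(abs(cbind(a1$x, a1$y, a1$z) -
                    cbind(a2$x, a2$y, a2$z))), 1e-4 + 1e-9)
})

test_that("own mmCIF reader agrees with bio3d on a single-model file", {
  m <- buildTetrad(g4BuildSpec(twist = 30))
  p <- withr::local_tempfile(fileext = ".cif")
  writeStructure(m, p, "mmcif")
  own <- atomTable(readStructure(p)[[1]])
  b3d <- suppressWarnings(bio3d::read.cif(p, verbose = FALSE))$atom
  expect_equal(nrow(own), nrow(b3d))
  expect_equal(own$x, b3d$x, tolerance = 1e-9)
  expect_equal(own$resno, b3d$resno)
})

test_that("multi-model mmCIF files keep every model", {
  m <- buildTetrad(g4BuildSpec(twist = 30))
  p <- withr::local_tempfile(fileext = ".cif")
  writeStructure(m, p, "mmcif")
  ## duplicate the atom_site rows as model 2
  lines <- readLines(p)
  rows <- grep("^ATOM ", lines, value = TRUE)
  rows2 <- sub(" 1$", " 2", rows)
  writeLines(c(lines[seq_len(max(grep("^ATOM ", lines)))], rows2, "#"), p)
  models <- readStructure(p)
  expect_length(models, 2)
  expect_equal(nrow(atomTable(models[[2]])), nrow(atomTable(m)))
})

test_that("star-dialect atom names are normalized to primes", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1*  DG A   1       1.000   2.000   3.000  1.00 10.00           C",
    "ATOM      2  O4*  DG A   1       2.000   2.000   3.000  1.00 10.00           O",
    "ATOM      3  O1P  DG A   1       3.000   2.000   3.000  1.00 10.00           O",
    "END"), p)
  a <- atomTable(readStructure(p)[[1]])
  expect_setequal(a$elety, c("C1'", "O4'", "OP1"))
})

test_that("alternate locations resolve to highest occupancy", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1'A DG A   1       1.000   2.000   3.000  0.40 10.00           C",
    "ATOM      2  C1'B DG A   1       9.000   2.000   3.000  0.60 10.00           C",
    "END"), p)
  a <- atomTable(readStructure(p)[[1]])
  expect_equal(nrow(a), 1)
  expect_equal(a$x, 9)
})

test_that("io errors are explicit", {
  expect_error(readStructure("/nonexistent/file.pdb"), "not found")
  empty <- withr::local_tempfile(fileext = ".cif")
  writeLines("data_x", empty)
  expect_error(readStructure(empty), "atom_site")
  m <- buildTetrad(g4BuildSpec(twist = 30))
  e <- StructureModel(atomTable(m)[0, ])
  expect_error(writeStructure(e, tempfile(), "pdb"), "empty")
  ## PDB capacity limit
  big <- atomTable(m)
  big <- big[rep(seq_len(nrow(big)), length.out = 100000), ]
  big$resno <- seq_len(nrow(big))
  bigm <- StructureModel(big)
  expect_error(writeStructure(bigm, tempfile(), "pdb"), "mmcif")
})

test_that("non-nucleotide entities are kept but tagged", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1'  DG A   1       1.000   2.000   3.000  1.00 10.00           C",
    "HETATM    2  K     K A 101       0.000   0.000   0.000  1.00 10.00           K",
    "HETATM    3  O   HOH A 201       5.000   5.000   5.000  1.00 10.00           O",
    "END"), p)
  a <- atomTable(readStructure(p)[[1]])
  expect_equal(nrow(a), 3)
  expect_equal(sum(a$is_nuc), 1)
})
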