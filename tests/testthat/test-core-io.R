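test_that("a minimal single-atom PDB parses to one atom, one residue", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  22.000  33.000  1.00  0.00           C",
    "END"), f)
  s <- readStructure(f)
  expect_equal(natoms(s), 1)
  expect_equal(length(residueKeys(s)), 1)
  expect_equal(atoms(s)$x, 11)
  expect_equal(residueKeys(s), "A:1:ALA")
})

test_that("a hand-written 3-model file of 5 atoms yields F=3, N=5 with frame 1 = template", {
  mk <- function(model, dz) c(
    sprintf("MODEL     %d", model),
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            1:5, paste0("C", 1:5), "LIG", "A", 1, seq(1, 5), rep(0, 5),
            rep(dz, 5), 1, 0),
    "ENDMDL")
  f <- tempfile(fileext = ".pdb")
  writeLines(c(mk(1, 0), mk(2, 1), mk(3, 2), "END"), f)
  tr <- readTrajectory(f)
  expect_equal(nframes(tr), 3)
  expect_equal(natoms(tr), 5)
  expect_equal(frameCoords(tr, 1), structureCoords(tr@template))
  expect_equal(frameCoords(tr, 3)[, 3], rep(2, 5))
})

test_that("malformed records and inconsistent model sizes error with diagnostics", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  22.000  33.000  1.00  0.00",
    "ATOM      2  CB  ALA A   1      11.0",
    "END"), f)
  expect_error(readStructure(f), "line 2")
  toy <- makeToyComplex()
  tr <- makeGaussianTrajectory(toy$structure, noise = 0.05, nFrames = 3, seed = 1)
  ft <- tempfile(fileext = ".pdb")
  writeStructure(tr, ft)
  lines <- readLines(ft)
  drop <- which(grepl("^ATOM", lines) & seq_along(lines) > grep("^MODEL", lines)[2])[1]
  writeLines(lines[-drop], ft)
  expect_error(readTrajectory(ft), "inconsistent atom count")
  expect_error(readStructure(tempfile()), "not found")
})

test_that("write/read round-trip preserves identity at PDB fixed-format precision", {
  toy <- makeToyComplex()
  s <- toy$structure
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  a1 <- atoms(s); a2 <- atoms(s2)
  expect_lt(max(abs(a1$x - a2$x), abs(a1$y - a2$y), abs(a1$z - a2$z)), 5.01e-4)
  expect_identical(a1$name, a2$name)
  expect_identical(a1$chain, a2$chain)
  expect_identical(a1$resno, a2$resno)
  # second write of the reread file is byte-identical (idempotence)
  f2 <- tempfile(fileext = ".pdb")
  writeStructure(s2, f2)
  s3 <- readStructure(f2)
  expect_identical(atoms(s2), atoms(s3))
})

test_that("a scalar column is written to the B-factor field, broadcasting per residue", {
  toy <- makeToyComplex()
  s <- toy$structure
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f, scalars = rep(0, natoms(s)))
  expect_true(all(atoms(readStructure(f))$b == 0))
  nres <- length(residueKeys(s))
  writeStructure(s, f, scalars = seq_len(nres))
  b <- atoms(readStructure(f))$b
  rk <- residueKeys(s, perAtom = TRUE)
  for (k in unique(rk)) expect_length(unique(b[rk == k]), 1)
  expect_error(writeStructure(s, f, scalars = 1:3), "per atom")
})

test_that("selection algebra is deterministic, sorted, and warns on absent chains", {
  toy <- makeToyComplex(nChains = 2, residuesPerChain = 11)
  s <- toy$structure
  sel <- selectAtoms(s, chain = "A", resno = 3:10)
  expect_equal(length(sel), 8 * 2)     # 8 residues x 2 atoms
  expect_identical(sel, sort(sel))
  expect_equal(length(selectAtoms(s, name = "CA", chain = "B")), 11)
  expect_warning(empty <- selectAtoms(s, chain = "Z"), "not present")
  expect_length(empty, 0)
  # complement and set algebra
  selA <- selectAtoms(s, chain = "A")
  expect_identical(invertSelection(s, selA), selectAtoms(s, chain = "B"))
  expect_identical(union(selA, selA), selA)           # idempotent
  expect_identical(intersect(selA, selectAtoms(s, name = "CA")),
                   selectAtoms(s, chain = "A", name = "CA"))
})

test_that("HETATM ligand records are retained and flagged", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "HETATM    3 MG    MG A 201       2.000   2.000   0.000  1.00  0.00          MG",
    "END"), f)
  s <- readStructure(f)
  expect_equal(sum(atoms(s)$het), 1)
  expect_identical(invertSelection(s, selectAtoms(s, het = FALSE)),
                   selectAtoms(s, het = TRUE))
})

test_that("altloc conformers collapse to the highest-occupancy copy", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_message(s <- readStructure(f), "alternate-location")
  expect_equal(natoms(s), 2)
  expect_equal(atoms(s)$x[atoms(s)$name == "CA"], 1)  # kept occupancy 0.6
})

test_that("exclusion topology follows the bond graph: 1-2/1-3 excluded, 1-4 scaled", {
  # ion pair: no bonds, no exclusions
  expect_equal(nrow(makeIonPair()@exclusions), 0)
  # 4-atom linear chain
  st <- ChaperoneDynamics:::.buildStructure(rep("A", 4), rep(1, 4), "LIG",
                                            paste0("C", 1:4),
                                            cbind((1:4) * 1.5, 0, 0))
  tab <- ChaperoneDynamics:::.paramTable(st, 0, 3, 0.1, 1.5, 0.8)
  sys <- loadParameters(st, tab, bonds = cbind(1:3, 2:4))
  expect_equal(apply(sys@exclusions, 1, paste, collapse = "-"),
               c("1-2", "1-3", "2-3", "2-4", "3-4"))
  expect_equal(unname(sys@scaled14), cbind(1L, 4L), ignore_attr = TRUE)
  # exclusions are symmetric-by-construction (stored i < j) with no self pairs
  expect_true(all(sys@exclusions[, 1] < sys@exclusions[, 2]))
  # missing parameter rows name the offending atoms
  expect_error(loadParameters(st, tab[-2, ]), "A:1:C2")
})

test_that("parameter and bond tables round-trip through their TSV formats", {
  toy <- makeToyComplex()
  pf <- tempfile(fileext = ".tsv"); bf <- tempfile(fileext = ".tsv")
  utils::write.table(toy$parameterTable, pf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(data.frame(serial_i = toy$bonds[, 1],
                                serial_j = toy$bonds[, 2]),
                     bf, sep = "\t", row.names = FALSE, quote = FALSE)
  sys <- loadParameters(toy$structure, pf, bf)
  expect_equal(sys@params, toy$system@params)
  expect_equal(sys@exclusions, toy$system@exclusions)
})

test_that("frames files round-trip coordinates and replica labels", {
  toy <- makeToyComplex()
  tr <- makeGaussianTrajectory(toy$structure, noise = 0.2, nFrames = 4,
                               nReplicas = 2, seed = 9)
  f <- tempfile()
  writeFrames(tr, f)
  tr2 <- readTrajectory(f, template = toy$structure)
  expect_lt(max(abs(tr@xyz - tr2@xyz)), 1e-6)
  expect_identical(replicaIds(tr2), replicaIds(tr))
})
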