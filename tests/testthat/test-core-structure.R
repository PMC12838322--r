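test_that("degenerate PDB input raises 'no atoms' errors", {
  expect_error(readPDB(text = ""), "no atoms")
  expect_error(readPDB(text = c("HEADER    X", "END")), "no atoms")
})

test_that("a one-residue Gly fixture parses to 1 residue, 4 atoms, 0 ions", {
  s <- readPDB(text = glyFixturePDB())
  expect_s4_class(s, "ProteinStructure")
  expect_equal(nrow(residueTable(s)), 1L)
  expect_equal(nrow(atoms(s)), 4L)
  expect_equal(nrow(ions(s)), 0L)
  expect_equal(atoms(s)$elety, c("N", "CA", "C", "O"))
})

test_that("metal HETATM records are routed to the ion table", {
  s <- readPDB(text = calciumFixturePDB())
  expect_equal(nrow(ions(s)), 1L)
  expect_equal(ions(s)$elem, "CA")
  expect_equal(nrow(atoms(s)), 4L)
})

test_that("hydrogens and waters are discarded", {
  lines <- c(
    glyFixturePDB()[1:4],
    "ATOM      5  H   GLY A   1       0.500   0.500   0.000  1.00  0.00           H",
    "HETATM    6  O   HOH A 301       5.000   5.000   5.000  1.00  0.00           O",
    "END")
  s <- readPDB(text = lines)
  expect_equal(nrow(atoms(s)), 4L)
})

test_that("altlocs resolve to highest occupancy, ties alphabetical", {
  lines <- c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BGLY A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AGLY A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   1       8.000   0.000   0.000  0.50  0.00           C",
    "END")
  s <- readPDB(text = lines)
  a <- atoms(s)
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$elety == "N"], 9.0)   # higher occupancy
  expect_equal(a$x[a$elety == "CA"], 1.0)  # tie -> altloc A
})

test_that("malformed coordinate fields are reported with line numbers", {
  bad <- glyFixturePDB()
  substr(bad[3], 31, 38) <- "  xx.xxx"
  expect_error(readPDB(text = bad), "line 3")
})

test_that("distance matches the componentwise oracle", {
  expect_equal(atomDistance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(atomDistance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(11)
  for (k in 1:20) {
    a <- rnorm(3, sd = 10); b <- rnorm(3, sd = 10)
    expect_equal(atomDistance(a, b),
                 sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2),
                 tolerance = 1e-12)
  }
})

test_that("dihedral follows the IUPAC sign convention", {
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), 0)
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, -1, 0)), 180)
  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)), "collinear")
})

test_that("distance and dihedral are rigid-transform invariant", {
  set.seed(7)
  p <- matrix(rnorm(12, sd = 5), 4, 3)
  d0 <- atomDistance(p[1, ], p[2, ])
  a0 <- dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
  for (k in 1:10) {
    R <- randomRotationMatrix(); t <- rnorm(3, sd = 20)
    q <- sweep(p %*% t(R), 2, t, "+")
    expect_equal(atomDistance(q[1, ], q[2, ]), d0, tolerance = 1e-9)
    expect_equal(dihedralAngle(q[1, ], q[2, ], q[3, ], q[4, ]), a0,
                 tolerance = 1e-9)
  }
})

test_that("write/parse round-trip preserves identity and coordinates", {
  s <- buildPeptide(dihedralSpec(c("GLY", "ASP", "GLY"),
                                 phi = -140, psi = 135))
  s2 <- readPDB(text = writePDB(s))
  expect_equal(atoms(s2)$elety, atoms(s)$elety)
  expect_equal(atoms(s2)$resid, atoms(s)$resid)
  expect_equal(atoms(s2)$resno, atoms(s)$resno)
  expect_lt(max(abs(as.matrix(atoms(s2)[, c("x", "y", "z")]) -
                      as.matrix(atoms(s)[, c("x", "y", "z")]))), 0.001)
  # idempotence of parse . write . parse
  s3 <- readPDB(text = writePDB(s2))
  expect_identical(atoms(s3), atoms(s2))
})

test_that("a bound calcium writes exactly one HETATM and survives re-parse", {
  cf <- makeCoordinationFixture(3, 2.4)
  txt <- writePDB(cf$structure)
  expect_equal(sum(grepl("^HETATM", txt)), 1L)
  s2 <- readPDB(text = txt)
  expect_equal(nrow(ions(s2)), 1L)
})

test_that("structures that cannot be written raise errors", {
  expect_error(validObject(new("ProteinStructure")), "no atoms")
  expect_error(writePDB(new("ProteinStructure")), "empty")
  s <- buildBackbone(dihedralSpec(c("GLY", "GLY"), phi = -140, psi = 135))
  far <- transformStructure(s, translation = c(20000, 0, 0))
  expect_error(writePDB(far), "fixed-width")
})

test_that("the parser agrees with bio3d on coordinates", {
  skip_if_not_installed("bio3d")
  s <- buildPeptide(dihedralSpec(c("GLY", "LYS", "GLY"),
                                 phi = -140, psi = 135))
  tf <- tempfile(fileext = ".pdb")
  writePDB(s, tf)
  ref <- bio3d::read.pdb(tf)
  ours <- readPDB(tf)
  expect_equal(nrow(atoms(ours)), nrow(ref$atom))
  expect_equal(as.matrix(atoms(ours)[, c("x", "y", "z")]),
               unname(as.matrix(ref$atom[, c("x", "y", "z")])),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(atoms(ours)$elety, ref$atom$elety)
})
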