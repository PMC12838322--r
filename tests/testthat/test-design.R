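predTab <- function(...) {
  rows <- list(...)
  paste(c("wt\tposition\tmut",
          vapply(rows, function(r) paste(r, collapse = "\t"), "")),
        collapse = "\n")
}

test_that("predictor tables merge by (position, wt, mut)", {
  rec <- parsePredictorTables(list(
    toolA = predTab(c("S", 182, "A"), c("Q", 20, "E")),
    toolB = predTab(c("S", 182, "A"))))
  expect_equal(nrow(rec), 2L)
  s182 <- rec[rec$position == 182, ]
  expect_equal(s182$support, 2L)
  expect_identical(s182$tools, "toolA,toolB")
  expect_equal(rec$support[rec$position == 20], 1L)
})

test_that("distinct substitutions at one position stay separate", {
  rec <- parsePredictorTables(list(
    toolA = predTab(c("S", 182, "A")),
    toolB = predTab(c("S", 182, "G"))))
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$support == 1L))
})

test_that("wild-type conflicts and malformed rows are errors", {
  expect_error(parsePredictorTables(list(
    toolA = predTab(c("S", 182, "A")),
    toolB = predTab(c("T", 182, "A")))), "position 182")
  expect_error(parsePredictorTables(list(
    toolA = paste("wt\tposition\tmut", "SS\t10\tA", sep = "\n"))),
    "line 2")
  expect_error(parsePredictorTables(list(
    toolA = predTab(c("A", 10, "A")))), "wt equal to mut")
})

test_that("consensus selection equals the brute-force filter", {
  set.seed(19)
  tools <- paste0("tool", 1:5)
  for (rep in 1:10) {
    tabs <- lapply(tools, function(t) {
      n <- sample(3:10, 1)
      pos <- sample(10:60, n)
      predTab2 <- paste(c("wt\tposition\tmut",
                          paste(LETTERS[(pos %% 6) + 1], pos,
                                "P", sep = "\t")), collapse = "\n")
      predTab2
    })
    names(tabs) <- tools
    rec <- parsePredictorTables(tabs)
    for (k in 1:5) {
      got <- consensusSelect(rec, k)
      ref <- rec[rec$support >= k, ]
      expect_setequal(mutationLabel(got$wt, got$position, got$mut),
                      mutationLabel(ref$wt, ref$position, ref$mut))
    }
    expect_equal(nrow(consensusSelect(rec, 1)), nrow(rec))
  }
})

test_that("a mutation predicted by all five tools survives k = 5", {
  tabs <- setNames(rep(list(predTab(c("S", 182, "A"))), 5),
                   paste0("tool", 1:5))
  tabs$tool1 <- predTab(c("S", 182, "A"), c("Q", 20, "E"))
  rec <- parsePredictorTables(tabs)
  top <- consensusSelect(rec, 5)
  expect_equal(nrow(top), 1L)
  expect_identical(mutationLabel(top$wt, top$position, top$mut), "S182A")
})

test_that("predictor merging is order-independent", {
  tabs <- list(a = predTab(c("S", 18, "A"), c("N", 9, "D")),
               b = predTab(c("S", 18, "A")),
               c = predTab(c("N", 9, "D"), c("S", 18, "T")))
  r1 <- parsePredictorTables(tabs)
  r2 <- parsePredictorTables(rev(tabs))
  expect_equal(r1[, c("position", "wt", "mut", "support")],
               r2[, c("position", "wt", "mut", "support")])
})

# Ser tripeptide facing a Lys tripeptide with an exact CB-NZ distance
serNearLys <- function(cbToNz) {
  serF <- buildPeptide(dihedralSpec(c("GLY", "SER", "GLY"),
                                    phi = -140, psi = 135), chain = "A")
  lysF <- buildPeptide(dihedralSpec(c("GLY", "LYS", "GLY"),
                                    phi = -140, psi = 135), chain = "B")
  aS <- atoms(serF); aL <- atoms(lysF)
  cb <- as.numeric(aS[aS$resno == 2 & aS$elety == "CB", c("x", "y", "z")])
  nz <- as.numeric(aL[aL$resno == 2 & aL$elety == "NZ", c("x", "y", "z")])
  lysF <- transformStructure(lysF,
                             translation = cb + c(0, cbToNz, 0) - nz)
  combineStructures(serF, lysF)
}

test_that("exposed residues near an unpaired basic residue are proposed", {
  s <- serNearLys(6)
  rasa <- setNames(rep(50, nrow(residueTable(s))), residueTable(s)$key)
  sc <- scanSurfaceAcidicCandidates(s, rasa, detectIonPairs(s))
  ser <- sc[sc$key == "A/2", ]
  expect_setequal(ser$proposed, c("ASP", "GLU"))
  expect_true(all(ser$partner_unpaired))
  expect_equal(ser$cb_to_charge, c(6, 6), tolerance = 1e-9)
})

test_that("buried residues and out-of-reach residues are not proposed", {
  s <- serNearLys(6)
  keys <- residueTable(s)$key
  buried <- setNames(rep(50, length(keys)), keys)
  buried["A/2"] <- 4
  sc <- scanSurfaceAcidicCandidates(s, buried, detectIonPairs(s))
  expect_false("A/2" %in% sc$key)

  far <- serNearLys(13)
  rasa <- setNames(rep(50, length(keys)), keys)
  scFar <- scanSurfaceAcidicCandidates(far, rasa, detectIonPairs(far))
  expect_false("A/2" %in% scFar$key)
  # 12 A: within Glu reach (8 + 3.9) but beyond Asp reach (8 + 2.5)
  mid <- serNearLys(11.5)
  scMid <- scanSurfaceAcidicCandidates(mid, rasa, detectIonPairs(mid))
  expect_identical(scMid$proposed[scMid$key == "A/2"], "GLU")
})

test_that("lowering the RASA threshold never removes a candidate", {
  s <- serNearLys(6)
  keys <- residueTable(s)$key
  set.seed(23)
  rasa <- setNames(runif(length(keys), 0, 60), keys)
  p <- detectIonPairs(s)
  hi <- scanSurfaceAcidicCandidates(s, rasa, p, rasaThreshold = 30)
  lo <- scanSurfaceAcidicCandidates(s, rasa, p, rasaThreshold = 10)
  idOf <- function(x) paste(x$key, x$proposed, x$partner_key)
  expect_true(all(idOf(hi) %in% idOf(lo)))
})

test_that("the report bundles stages and is byte-deterministic", {
  rec <- parsePredictorTables(list(a = predTab(c("S", 182, "A")),
                                   b = predTab(c("S", 182, "A"))))
  cons <- consensusSelect(rec, 2)
  rep1 <- generateReport(consensus = cons)
  expect_equal(nrow(rep1$candidates), 1L)
  expect_identical(rep1$candidates$category, "consensus")
  expect_error(generateReport(), "at least one")

  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  generateReport(consensus = cons, parameters = list(minSupport = 2),
                 jsonPath = f1)
  generateReport(consensus = cons, parameters = list(minSupport = 2),
                 jsonPath = f2)
  expect_identical(readLines(f1), readLines(f2))
})
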