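test_that("planted pairs classify by the 4/8 A limits", {
  expect_identical(detectIonPairs(
    makeSaltBridgeFixture("ASP", "LYS", 3.5)$structure)$category,
    "salt_bridge")
  expect_identical(detectIonPairs(
    makeSaltBridgeFixture("ASP", "LYS", 6.0)$structure)$category,
    "long_range")
  expect_equal(nrow(detectIonPairs(
    makeSaltBridgeFixture("ASP", "LYS", 9.0)$structure)), 0L)
})

test_that("the category boundaries are inclusive", {
  # classify with cutoffs set to the measured minimum distance itself:
  # d == saltCutoff is a salt bridge, d == longCutoff is still a pair
  s <- makeSaltBridgeFixture("GLU", "ARG", 5)$structure
  d <- detectIonPairs(s)$min_dist
  atSalt <- detectIonPairs(s, saltCutoff = d, longCutoff = 8)
  expect_identical(atSalt$category, "salt_bridge")
  atLong <- detectIonPairs(s, saltCutoff = 4, longCutoff = d)
  expect_identical(atLong$category, "long_range")
  below <- detectIonPairs(s, saltCutoff = 4, longCutoff = d - 1e-9)
  expect_equal(nrow(below), 0L)
})

test_that("perturbing a planted distance across 4 A flips the category", {
  lo <- detectIonPairs(makeSaltBridgeFixture("ASP", "ARG", 3.9)$structure)
  hi <- detectIonPairs(makeSaltBridgeFixture("ASP", "ARG", 4.1)$structure)
  expect_identical(lo$category, "salt_bridge")
  expect_identical(hi$category, "long_range")
})

# random cluster of charged tripeptides for oracle comparison
chargedCluster <- function(nFrag = 8, seed = 1) {
  set.seed(seed)
  resids <- sample(c("ASP", "GLU", "LYS", "ARG"), nFrag, TRUE)
  parts <- lapply(seq_len(nFrag), function(i) {
    f <- buildPeptide(dihedralSpec(c("GLY", resids[i], "GLY"),
                                   phi = -140, psi = 135),
                      chain = LETTERS[i])
    transformStructure(f, randomRotationMatrix(), runif(3, -9, 9))
  })
  do.call(combineStructures, parts)
}

test_that("the detector equals the exhaustive all-atom oracle", {
  for (seed in 1:4) {
    s <- chargedCluster(8, seed)
    expect_lte(nrow(atoms(s)), 500)
    got <- detectIonPairs(s)
    ref <- bruteIonPairs(s)
    keyG <- paste(got$acid_key, got$base_key)
    keyR <- paste(ref$acid_key, ref$base_key)
    expect_setequal(keyG, keyR)
    if (nrow(got)) {
      ref <- ref[match(keyG, keyR), ]
      expect_equal(got$min_dist, ref$min_dist, tolerance = 1e-12)
      expect_identical(got$category, ref$category)
    }
  }
})

test_that("pair output is sorted and reports each residue pair once", {
  s <- chargedCluster(10, 2)
  got <- detectIonPairs(s)
  expect_false(is.unsorted(got$acid_resno))
  expect_equal(anyDuplicated(paste(got$acid_key, got$base_key)), 0L)
})

test_that("network assembly finds chain, disconnected and cyclic shapes", {
  nw <- buildIonicNetworks(fakePairTable(c("a", "b"), c("B", "B")))
  # a-B, b-B share the basic residue -> one 3-residue, 2-pair network
  expect_length(nw$networks, 1L)
  expect_equal(nw$networks[[1]]$n_pairs, 2L)
  expect_length(nw$networks[[1]]$residues, 3L)

  nw2 <- buildIonicNetworks(fakePairTable(c("a", "c"), c("B", "D")))
  expect_length(nw2$networks, 0L)
  expect_length(nw2$singletons, 2L)

  nw3 <- buildIonicNetworks(fakePairTable(c("a", "a", "c", "e"),
                                          c("B", "D", "B", "F")))
  expect_length(nw3$networks, 1L)
  expect_equal(nw3$networks[[1]]$n_pairs, 3L)
  expect_length(nw3$singletons, 1L)
})

test_that("network assembly matches union-find on random graphs", {
  set.seed(9)
  for (k in 1:50) {
    m <- sample(2:12, 1)
    acid <- paste0("A", sample(8, m, TRUE))
    base <- paste0("B", sample(8, m, TRUE))
    tab <- fakePairTable(acid, base)
    tab <- tab[!duplicated(paste(acid, base)), ]
    nw <- buildIonicNetworks(tab)
    comp <- unionFindComponents(tab$acid_key, tab$base_key)
    compOf <- function(keys) unique(comp[keys])
    for (net in nw$networks) {
      expect_length(compOf(net$residues), 1L)
      expect_setequal(net$residues,
                      names(comp)[comp == compOf(net$residues)])
    }
    # pair counts per component must agree
    edgeComp <- comp[tab$acid_key]
    bigComps <- names(which(table(edgeComp) >= 2))
    expect_length(nw$networks, length(bigComps))
  }
})

test_that("network assembly is order-independent", {
  set.seed(13)
  tab <- fakePairTable(paste0("A", sample(6, 12, TRUE)),
                       paste0("B", sample(6, 12, TRUE)))
  tab <- tab[!duplicated(paste(tab$acid_key, tab$base_key)), ]
  nw1 <- buildIonicNetworks(tab)
  nw2 <- buildIonicNetworks(tab[sample(nrow(tab)), ])
  sets <- function(nw) lapply(nw$networks, `[[`, "residues")
  expect_setequal(vapply(sets(nw1), paste, "", collapse = ","),
                  vapply(sets(nw2), paste, "", collapse = ","))
})

test_that("exposure annotation averages member RASA, inclusive at 20%", {
  fx <- makeSaltBridgeFixture("ASP", "LYS", 3.5)
  p <- detectIonPairs(fx$structure)
  rasa <- setNames(c(30, 14), c(p$acid_key, p$base_key))
  out <- annotateExposure(p, rasa)
  expect_equal(out$pair_rasa, 22)
  expect_true(out$exposed)
  expect_false(annotateExposure(p, setNames(c(10, 10), names(rasa)))$exposed)
  expect_true(annotateExposure(p, setNames(c(20, 20), names(rasa)))$exposed)
  unk <- annotateExposure(p, setNames(30, p$acid_key))
  expect_true(is.na(unk$exposed))
})

test_that("unpaired basic residues are those outside any pair", {
  lysOnly <- buildPeptide(dihedralSpec(c("GLY", "LYS", "GLY"),
                                       phi = -140, psi = 135))
  up <- unpairedBasicResidues(lysOnly, detectIonPairs(lysOnly))
  expect_equal(up$resid, "LYS")

  fx <- makeSaltBridgeFixture("ASP", "LYS", 3.5)
  p <- detectIonPairs(fx$structure)
  up2 <- unpairedBasicResidues(fx$structure, p)
  expect_false(p$base_key %in% up2$key)
})
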