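test_that("KCF records parse with declared counts and verbatim atom types", {
  rec <- paste(
    "ATOM        2",
    "            1  C.alkyl  C",
    "            2  O.hydroxyl  O",
    "BOND        1",
    "            1  1  2  single", sep = "\n")
  g <- parseKCF(rec)
  expect_equal(atomCount(g), 2)
  expect_equal(bondCount(g), 1)
  expect_equal(atoms(g)$atom_type, c("C.alkyl", "O.hydroxyl"))

  benz <- paste(c(
    "NAME        benzene",
    "ATOM        6",
    sprintf("            %d  C.arom  C", 1:6),
    "BOND        6",
    sprintf("            %d  %d  %d  aromatic", 1:6, 1:6, c(2:6, 1))),
    collapse = "\n")
  b <- parseKCF(benz)
  expect_equal(atomCount(b), 6)
  expect_true(all(bonds(b)$order == "aromatic"))
  expect_true(graphsIsomorphic(b, parseSmiles("c1ccccc1")))
})

test_that("KCF parser rejects malformed records with a line number", {
  good <- writeKCF(parseSmiles("Oc1ccccc1", "phenol"))
  expect_s4_class(parseKCF(good), "MolecularGraph")
  expect_error(parseKCF("ATOM  x\n"), "malformed ATOM")
  expect_error(parseKCF(paste(
    "ATOM        2",
    "            1  C.alkyl  C",
    "            1  C.alkyl  C",
    "BOND        0", sep = "\n")), "duplicate atom index")
  expect_error(parseKCF(paste(
    "ATOM        1",
    "            1  C.alkyl  C",
    "BOND        1",
    "            1  1  5  single", sep = "\n")), "dangling bond")
  expect_error(parseKCF(paste(
    "ATOM        3",
    "            1  C.alkyl  C",
    "            2  C.alkyl  C",
    "BOND        0", sep = "\n")), "declares 3 atoms but 2")
  expect_error(parseKCF(paste(
    "ATOM        1",
    "            1  C.alkyl  C",
    "BOND        2",
    "            1  1  1  single", sep = "\n")), "distinct|declares")
})

test_that("KCF round-trips preserve isomorphism class for every fixture", {
  fx <- flavonoidFixtures()
  for (nm in names(fx)) {
    g2 <- parseKCF(writeKCF(fx[[nm]]))
    expect_true(graphsIsomorphic(fx[[nm]], g2), info = nm)
    expect_identical(canonicalKey(fx[[nm]]), canonicalKey(g2), info = nm)
  }
  empty <- molecularGraph(data.frame(index = integer(), element = character(),
                                     charge = integer()), NULL)
  expect_match(writeKCF(empty), "ATOM        0")
  expect_equal(atomCount(parseKCF(writeKCF(empty))), 0)
})

test_that("SMILES reader agrees with the standard interpretation", {
  w <- parseSmiles("O")
  expect_equal(atomCount(w), 1)
  expect_equal(atoms(w)$implicit_h, 2)

  b <- parseSmiles("c1ccccc1")
  expect_equal(atomCount(b), 6)
  expect_true(all(bonds(b)$order == "aromatic"))
  expect_equal(sum(atoms(b)$implicit_h), 6)

  nar <- parseSmiles("O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c12")
  expect_equal(atomCount(nar), 20)

  # independent toolkit oracle for heavy-atom counts and element multisets
  sdf <- ChemmineR::smiles2sdf("O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c12")
  ab <- ChemmineR::atomblock(sdf[[1]])
  expect_equal(atomCount(nar), nrow(ab))
  expect_equal(sort(atoms(nar)$element),
               sort(gsub("_.*", "", rownames(ab))))
  expect_equal(bondCount(nar), nrow(ChemmineR::bondblock(sdf[[1]])))

  expect_error(parseSmiles("C1CC"), "unclosed ring")
  expect_error(parseSmiles("C(C"), "unbalanced")
  expect_error(parseSmiles("C$"), "unexpected character")
})

test_that("Kekule and aromatic writings normalise to the same graph", {
  expect_identical(canonicalKey(parseSmiles("C1=CC=CC=C1")),
                   canonicalKey(parseSmiles("c1ccccc1")))
  expect_identical(canonicalKey(parseSmiles("OC1=CC=CC=C1")),
                   canonicalKey(parseSmiles("Oc1ccccc1")))
})

test_that("canonical keys are isomorphism invariants and separators", {
  b <- parseSmiles("c1ccccc1")
  ph <- parseSmiles("Oc1ccccc1")
  expect_false(canonicalKey(b) == canonicalKey(ph))
  nar <- parseSmiles("O=C1CC(c2ccc(O)cc2)Oc2cc(O)cc(O)c12", "naringenin")
  set.seed(42)
  for (k in 1:5) {
    perm <- sample(atomCount(nar))
    nar2 <- permute_atoms(nar, perm)
    expect_identical(canonicalKey(nar), canonicalKey(nar2))
    expect_true(graphsIsomorphic(nar, nar2))
  }
  fx <- flavonoidFixtures()
  # positional isomers must separate
  expect_false(canonicalKey(fx$isorhamnetin) == canonicalKey(fx$tamarixetin))
  expect_false(graphsIsomorphic(fx$isorhamnetin, fx$tamarixetin))
})

test_that("canonical-key equality coincides with brute-force isomorphism", {
  set.seed(7)
  graphs <- lapply(1:12, function(i) random_molgraph(sample(4:7, 1)))
  # add deliberate isomorphic relabelings
  graphs <- c(graphs, lapply(graphs[1:4], function(g)
    permute_atoms(g, sample(atomCount(g)))))
  keys <- vapply(graphs, canonicalKey, character(1))
  for (i in seq_along(graphs)) for (j in seq_along(graphs)) {
    if (j <= i) next
    brute <- brute_isomorphic(graphs[[i]], graphs[[j]])
    expect_equal(keys[i] == keys[j], brute, info = paste(i, j))
    expect_equal(graphsIsomorphic(graphs[[i]], graphs[[j]]), brute,
                 info = paste(i, j))
  }
})

test_that("graph validity catches structural defects", {
  expect_error(molecularGraph(
    data.frame(index = c(1L, 1L), element = "C", charge = 0L), NULL),
    "duplicate")
  expect_error(molecularGraph(
    data.frame(index = 1:2, element = "C", charge = 0L),
    data.frame(a1 = 1L, a2 = 3L, order = "single")), "resolve")
  expect_message(molecularGraph(
    data.frame(index = 1L, element = "C", atom_type = "C8y", charge = 0L),
    NULL), "outside the shipped vocabulary")
})
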