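# shared toy pair: benzene -> phenol with full ring mapping
make_hydroxylation_pair <- function() {
  benzene <- parseSmiles("c1ccccc1", "benzene")
  phenol_mapped <- molecularGraph(
    rbind(atoms(benzene)[, c("index", "element", "atom_type", "charge")],
          data.frame(index = 7L, element = "O", atom_type = "O.hydroxyl",
                     charge = 0L)),
    rbind(bonds(benzene), data.frame(a1 = 1L, a2 = 7L, order = "single")),
    name = "phenol")
  reactionPair("hydrox", benzene, phenol_mapped, cbind(1:6, 1:6),
               "1.14.13.39", reversible = TRUE)
}

test_that("derivation emits per-direction operators that round-trip", {
  rp <- make_hydroxylation_pair()
  ops <- deriveOperators(rp)
  expect_length(ops, 2)
  dirs <- vapply(ops, function(o) o@direction, character(1))
  expect_setequal(dirs, c("forward", "reverse"))
  fwd <- ops[[which(dirs == "forward")]]
  expect_equal(fwd@center_type, "C.arom")
  add_types <- vapply(Filter(function(e) e$type == "add_atom", fwd@edits),
                      `[[`, character(1), "atom_type")
  expect_equal(add_types, "O.hydroxyl")
  prod <- applyOperator(rp@reactant, fwd, fwd@source_site)
  expect_true(graphsIsomorphic(prod, rp@product))
  # reverse operator applied at its own source site regenerates benzene
  rev <- ops[[which(dirs == "reverse")]]
  back <- applyOperator(rp@product, rev, rev@source_site)
  expect_true(graphsIsomorphic(back, rp@reactant))
})

test_that("a pair isomorphic under its map yields no operators; an empty
           map is an error", {
  benzene <- parseSmiles("c1ccccc1")
  rp0 <- reactionPair("noop", benzene, benzene, cbind(1:6, 1:6), "1.1.1.1")
  expect_length(deriveOperators(rp0), 0)
  expect_error(
    reactionPair("bad", benzene, benzene, matrix(integer(), 0, 2),
                 "1.1.1.1") |> deriveOperators(),
    "unmappable")
})

test_that("site matching is exact on labels and deduplicates by symmetry", {
  fx <- flavonoidFixtures()
  pairs <- fixtureReactionPairs(fx)
  lib <- fixtureOperatorLibrary(pairs)
  ometh <- Filter(function(o) o@id == "op.o_methylation",
                  operators(lib))[[1]]
  # benzene has no hydroxyl: no label match anywhere
  expect_length(matchSites(fx$benzene, ometh), 0)
  # catechol's two hydroxyls are symmetric: one unique site
  sites_cat <- matchSites(fx$catechol, ometh)
  expect_length(sites_cat, 1)
  # quercetin: one site per distinct aromatic hydroxyl environment
  # (5-, 7-, 3'-, 4'-OH; the 3-OH sits on a non-aromatic carbon)
  sites_q <- matchSites(fx$quercetin, ometh)
  expect_length(sites_q, 4)
  # brute-force check that every site satisfies the pattern constraints
  for (s in sites_q) {
    expect_equal(atoms(fx$quercetin)$atom_type[
      match(s[["1"]], atoms(fx$quercetin)$index)], "O.hydroxyl")
  }
})

test_that("operator application produces the expected named compounds", {
  fx <- flavonoidFixtures()
  lib <- fixtureOperatorLibrary(fixtureReactionPairs(fx))
  ometh <- Filter(function(o) o@id == "op.o_methylation",
                  operators(lib))[[1]]
  sites <- matchSites(fx$catechol, ometh)
  expect_true(graphsIsomorphic(applyOperator(fx$catechol, ometh, sites[[1]]),
                               fx$guaiacol))
  prods <- lapply(matchSites(fx$quercetin, ometh), function(s)
    applyOperator(fx$quercetin, ometh, s))
  expect_true(any(vapply(prods, graphsIsomorphic, logical(1),
                         b = fx$isorhamnetin)))
  expect_true(any(vapply(prods, graphsIsomorphic, logical(1),
                         b = fx$tamarixetin)))
})

test_that("applying an operator then its reverse restores the substrate", {
  rp <- make_hydroxylation_pair()
  ops <- deriveOperators(rp)
  fwd <- Filter(function(o) o@direction == "forward", ops)[[1]]
  rev <- Filter(function(o) o@direction == "reverse", ops)[[1]]
  substrate <- parseSmiles("Cc1ccccc1", "toluene")
  sites <- matchSites(substrate, fwd)
  expect_gt(length(sites), 0)
  # the ipso site is valence-rejected; take the first chemically legal one
  once <- NULL
  for (s in sites) {
    once <- tryCatch(applyOperator(substrate, fwd, s),
                     flavopredict_valence_error = function(e) NULL)
    if (!is.null(once)) break
  }
  expect_false(is.null(once))
  back_sites <- matchSites(once, rev)
  backs <- lapply(back_sites, function(s) applyOperator(once, rev, s))
  expect_true(any(vapply(backs, graphsIsomorphic, logical(1), b = substrate)))
})

test_that("heavy-atom counts change exactly by the edit script's net adds
           and removes", {
  spec <- corpusSpec(101, n_scaffolds = 6, n_reactions = 12)
  co <- genReactionCorpus(spec)
  for (rp in co$pairs) {
    ops <- suppressMessages(deriveOperators(rp))
    for (op in ops) {
      net <- sum(vapply(op@edits, function(e) {
        if (e$type == "add_atom") 1L
        else if (e$type == "remove_atom") -1L else 0L
      }, integer(1)))
      substrate <- if (op@direction == "forward") rp@reactant else rp@product
      prod <- applyOperator(substrate, op, op@source_site)
      expect_equal(atomCount(prod) - atomCount(substrate), net)
    }
  }
})

test_that("valence-violating applications are rejected with a typed
           condition", {
  # force a methylation onto a hydroxyl whose oxygen is already saturated:
  # build an operator variant demanding only the O-C shell, then apply to
  # an ether-like site via a doctored pattern
  fx <- flavonoidFixtures()
  lib <- fixtureOperatorLibrary(fixtureReactionPairs(fx))
  ometh <- Filter(function(o) o@id == "op.o_methylation",
                  operators(lib))[[1]]
  # doctor the pattern to claim the center is an ether oxygen (2 bonds):
  bad <- ometh
  bad@pattern$atom_type[1] <- "O.ether"
  bad@edits <- Filter(function(e) e$type != "change_atom_type", bad@edits)
  sites <- matchSites(fx$guaiacol, bad)
  expect_gt(length(sites), 0)
  expect_error(applyOperator(fx$guaiacol, bad, sites[[1]]),
               class = "flavopredict_valence_error")
})
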