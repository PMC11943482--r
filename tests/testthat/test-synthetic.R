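test_that("generated corpora are reproducible and round-trip by
           construction", {
  spec <- corpusSpec(7, n_scaffolds = 5, n_reactions = 10)
  co <- genReactionCorpus(spec)
  expect_length(co$pairs, 10)
  co2 <- genReactionCorpus(corpusSpec(7, n_scaffolds = 5, n_reactions = 10))
  expect_identical(vapply(co$pairs, function(p) writeKCF(p@reactant),
                          character(1)),
                   vapply(co2$pairs, function(p) writeKCF(p@reactant),
                          character(1)))
  expect_identical(co$truth, co2$truth)
  # different seed, different decoration somewhere
  co3 <- genReactionCorpus(corpusSpec(8, n_scaffolds = 5, n_reactions = 10))
  expect_false(identical(
    vapply(co$pairs, function(p) writeKCF(p@reactant), character(1)),
    vapply(co3$pairs, function(p) writeKCF(p@reactant), character(1))))
  for (rp in co$pairs) {
    ops <- suppressMessages(deriveOperators(rp))
    fwd <- Filter(function(o) o@direction == "forward", ops)
    expect_length(fwd, 1)
    expect_identical(canonicalKey(applyOperator(rp@reactant, fwd[[1]],
                                                fwd[[1]]@source_site)),
                     canonicalKey(rp@product), info = rp@id)
  }
})

test_that("derivation over a corpus recovers exactly the planted patterns,
           decoys excluded via ground truth", {
  spec <- corpusSpec(23, n_scaffolds = 6, n_reactions = 18,
                     decoy_fraction = 1 / 3)
  co <- genReactionCorpus(spec)
  expect_equal(sum(co$truth$is_decoy), 6)
  sigs <- character(); decoy_sigs <- character()
  for (i in seq_along(co$pairs)) {
    s <- vapply(suppressMessages(deriveOperators(co$pairs[[i]])),
                operatorSignature, character(1))
    if (co$truth$is_decoy[i]) decoy_sigs <- c(decoy_sigs, s)
    else sigs <- c(sigs, s)
  }
  planted_sigs <- vapply(co$planted, operatorSignature, character(1))
  expect_setequal(unique(sigs), unique(planted_sigs))
  # per direction
  fwd_planted <- planted_sigs[grepl("^forward", planted_sigs)]
  expect_setequal(unique(sigs[grepl("^forward", sigs)]), unique(fwd_planted))
  # decoys derive to patterns outside the planted set
  expect_length(intersect(unique(decoy_sigs), unique(planted_sigs)), 0)
})

test_that("organism-matrix generation plants carriers exactly", {
  m0 <- genOrganismMatrix(3, n_strains = 10, background_density = 0,
                          planted = list("2.3.1.74" = c(1L, 4L, 7L)))
  # zero background: only planted ECs anywhere
  expect_setequal(unique(unlist(ecSets(m0))), "2.3.1.74")
  expect_identical(organismsFor("2.3.1.99", m0),
                   sort(strains(m0)[c(1, 4, 7)]))
  # background classes never collide with planted classes at 3 digits
  m1 <- genOrganismMatrix(3, n_strains = 10, background_density = 1,
                          planted = list("2.3.1.74" = c(2L)))
  expect_identical(organismsFor("2.3.1.1", m1), strains(m1)[2])
})

test_that("homolog generation hits its identity targets", {
  hs <- genHomologSet(29, reference_length = 100,
                      target_identities = c(100, 90))
  expect_identical(unname(hs$candidates[1]), hs$reference)
  v1 <- strsplit(hs$reference, "")[[1]]
  v2 <- strsplit(hs$candidates[[2]], "")[[1]]
  expect_equal(sum(v1 != v2), 10)
  expect_equal(globalIdentity(hs$reference, hs$candidates[[2]]), 90,
               tolerance = 0.011)
  expect_error(genHomologSet(1, target_identities = c(0)), "TRUE")
  # same seed, same sequences
  hs2 <- genHomologSet(29, reference_length = 100,
                       target_identities = c(100, 90))
  expect_identical(hs, hs2)
})

test_that("every fixture parses, keys stably, and the panel is complete", {
  fx <- flavonoidFixtures()
  expect_gte(length(aglyconeNames()), 15)
  expect_true(all(aglyconeNames() %in% names(fx)))
  keys <- vapply(fx, canonicalKey, character(1))
  keys2 <- vapply(flavonoidFixtures(), canonicalKey, character(1))
  expect_identical(keys, keys2)
  expect_false(anyDuplicated(keys) > 0)
  # the ring-opening fixture operator sends naringenin to the chalcone
  lib <- fixtureOperatorLibrary(fixtureReactionPairs(fx))
  ro <- Filter(function(o) o@id == "op.ring_open", operators(lib))[[1]]
  sites <- matchSites(fx$naringenin, ro)
  expect_length(sites, 1)
  expect_true(graphsIsomorphic(applyOperator(fx$naringenin, ro, sites[[1]]),
                               fx$naringenin_chalcone))
})
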