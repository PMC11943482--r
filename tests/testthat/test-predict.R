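test_that("an empty library predicts nothing", {
  fx <- flavonoidFixtures()
  rec <- predictMetabolites(fx$naringenin, operatorLibrary(list()), 2)
  expect_equal(nrow(rec), 0)
})

test_that("the naringenin fixture pathway unfolds over two rounds", {
  fx <- flavonoidFixtures()
  lib <- fixtureOperatorLibrary(fixtureReactionPairs(fx))
  ids <- vapply(operators(lib), function(o) o@id, character(1))
  core <- operatorLibrary(operators(lib)[ids %in% c(
    "op.ring_open", "op.chalcone_reduction", "op.retro_claisen")])
  k <- function(nm) canonicalKey(fx[[nm]])
  rec <- predictMetabolites(fx$naringenin, core, rounds = 2,
                            policy = defaultFilterPolicy())
  expect_true(any(rec$round == 1 & rec$product_key == k("naringenin_chalcone")))
  expect_true(any(rec$round == 2 & rec$product_key == k("phloretin")))
  # 3,4-HPPA needs a third step on this route: absent
  expect_false(any(rec$product_key == k("hppa")))

  # the direct flavanone-cleaving reduction shortcuts one step:
  # phloretin arrives in round 1 and ring fission reaches 3,4-HPPA and
  # phloroglucinol by round 2
  with_direct <- operatorLibrary(operators(lib)[ids != "op.o_methylation"])
  rec2 <- predictMetabolites(fx$naringenin, with_direct, rounds = 2,
                             policy = defaultFilterPolicy())
  expect_true(any(rec2$round == 1 & rec2$product_key == k("phloretin")))
  expect_true(any(rec2$round == 2 & rec2$product_key == k("hppa")))
  expect_true(any(rec2$product_key == k("phloroglucinol")))

  # blocklisted keys never appear
  pol <- filterPolicy(blocklist = c(canonicalKey(parseSmiles("O")),
                                    canonicalKey(parseSmiles("O=C=O")),
                                    k("phloroglucinol")))
  rec3 <- predictMetabolites(fx$naringenin, with_direct, rounds = 2,
                             policy = pol)
  expect_false(any(rec3$product_key %in% pol@blocklist))
  expect_true(any(rec3$product_key == k("hppa")))
})

test_that("two-round prediction equals one round composed with itself", {
  fx <- flavonoidFixtures()
  lib <- fixtureOperatorLibrary(fixtureReactionPairs(fx))
  empty <- filterPolicy()
  r12 <- predictMetabolites(fx$naringenin, lib, rounds = 2, policy = empty)
  r1 <- predictMetabolites(fx$naringenin, lib, rounds = 1, policy = empty)
  manual <- r1
  for (pk in sort(unique(r1$product_key))) {
    g <- r1$product[[which(r1$product_key == pk)[1]]]
    ri <- predictMetabolites(g, lib, rounds = 1, policy = empty)
    if (nrow(ri)) { ri$round <- 2L; manual <- rbind(manual, ri) }
  }
  sig <- function(df) sort(paste(df$substrate_key, df$operator_id,
                                 df$product_key, df$round))
  expect_identical(sig(r12), unique(sig(manual)))
})

test_that("filterProducts implements blocklist-then-catalog set arithmetic", {
  fx <- flavonoidFixtures()
  lib <- fixtureOperatorLibrary(fixtureReactionPairs(fx))
  rec <- predictMetabolites(fx$naringenin, lib, rounds = 2)
  expect_identical(filterProducts(rec, filterPolicy()), rec)
  kphl <- canonicalKey(fx$phloretin)
  blocked <- filterProducts(rec, filterPolicy(blocklist = kphl))
  expect_false(any(blocked$product_key == kphl))
  expect_equal(nrow(blocked), nrow(rec) - sum(rec$product_key == kphl))
  only <- filterProducts(rec, filterPolicy(catalog = kphl))
  expect_true(all(only$product_key == kphl))
  # blocklist wins over catalog
  none <- filterProducts(rec, filterPolicy(blocklist = kphl,
                                           catalog = kphl))
  expect_equal(nrow(none), 0)
})

test_that("growing the library and loosening the policy are monotone", {
  fx <- flavonoidFixtures()
  lib <- fixtureOperatorLibrary(fixtureReactionPairs(fx))
  ids <- vapply(operators(lib), function(o) o@id, character(1))
  small <- operatorLibrary(operators(lib)[1:2])
  big <- lib
  sig <- function(df) paste(df$operator_id, df$product_key, df$round)
  rec_small <- predictMetabolites(fx$naringenin, small, 2)
  rec_big <- predictMetabolites(fx$naringenin, big, 2)
  expect_true(all(sig(rec_small) %in% sig(rec_big)))
  # tightening the policy never adds records
  rec_tight <- predictMetabolites(fx$naringenin, big, 2,
                                  policy = defaultFilterPolicy())
  expect_true(all(sig(rec_tight) %in% sig(rec_big)))
})

test_that("rounds outside the two-round cap are refused", {
  fx <- flavonoidFixtures()
  lib <- fixtureOperatorLibrary(fixtureReactionPairs(fx))
  expect_error(predictMetabolites(fx$naringenin, lib, rounds = 3), "rounds")
  expect_error(predictMetabolites(fx$naringenin, lib, rounds = 0), "rounds")
})
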