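test_that("three-digit EC matching ignores the substrate field only", {
  expect_true(ecMatch3("2.3.1.74", "2.3.1.12"))
  expect_false(ecMatch3("2.3.1.74", "2.3.2.74"))
  expect_true(ecMatch3("1.14.13.-", "1.14.13.39"))
  expect_error(ecMatch3("2.3.1", "2.3.1.74"), "malformed")
  expect_error(ecMatch3("2.-.1.74", "2.3.1.74"), "malformed")
  # equivalence-relation sanity on well-formed ECs, superset of equality
  ecs <- c("2.3.1.74", "2.3.1.12", "1.14.13.39", "1.14.13.-")
  for (a in ecs) {
    expect_true(ecMatch3(a, a))
    for (b in ecs) expect_equal(ecMatch3(a, b), ecMatch3(b, a))
  }
})

test_that("organismsFor returns exactly the three-digit carriers", {
  m1 <- organismEnzymeMatrix("s1", list("2.3.1.12"),
                             data.frame(phylum = "Firmicutes",
                                        family = "f", genus = "g"))
  expect_equal(organismsFor("2.3.1.74", m1), "s1")
  expect_equal(organismsFor(character(), m1), character())
  m <- genOrganismMatrix(21, n_strains = 10,
                         planted = list("2.3.1.74" = c(2L, 5L, 9L)))
  got <- organismsFor("2.3.1.12", m)
  # brute-force scan oracle over the raw sets
  ref3 <- function(e) sub("^(\\d+\\.\\d+\\.\\d+)\\..*", "\\1", e)
  want <- sort(strains(m)[vapply(ecSets(m), function(e)
    "2.3.1" %in% ref3(e), logical(1))])
  expect_identical(got, want)
  expect_identical(got, sort(strains(m)[c(2, 5, 9)]))
})

test_that("capability tables equal hand recounts and normalise per strain", {
  m <- genOrganismMatrix(33, n_strains = 12,
                         planted = list("2.3.1.74" = c(1L, 2L),
                                        "2.3.1.12" = c(2L,  7L),
                                        "3.7.1.4" = c(4L)))
  classes <- list("C-ring cleavage" = c("2.3.1.74"),
                  "hydrolysis" = c("3.7.1.4"))
  tab <- capabilityTable(classes, m, "phylum")
  ref3 <- function(e) sub("^(\\d+\\.\\d+\\.\\d+)\\..*", "\\1", e)
  for (r in seq_len(nrow(tab))) {
    members <- which(taxonomy(m)$phylum == tab$taxon[r])
    q3 <- unique(ref3(classes[[tab$reaction_class[r]]]))
    n_enz <- sum(vapply(members, function(i)
      sum(ref3(ecSets(m)[[i]]) %in% q3), numeric(1)))
    expect_equal(tab$n_strains[r], length(members))
    expect_equal(tab$value[r], n_enz / length(members))
  }
  # a strain with k matching isozymes contributes k incidences:
  # strain 2 carries both 2.3.1.74 and 2.3.1.12, which share a 3-digit class
  ph2 <- taxonomy(m)$phylum[2]
  row2 <- tab[tab$taxon == ph2 & tab$reaction_class == "C-ring cleavage", ]
  expect_gte(row2$n_enzymes, 2)
  # zero-match taxa give zero cells
  expect_true(all(tab$value[tab$n_enzymes == 0] == 0))
})

test_that("capability values are invariant to strain order and genus-level
           cells aggregate exactly to phylum level", {
  m <- genOrganismMatrix(44, n_strains = 15,
                         planted = list("2.1.1.6" = c(1L, 3L, 8L)))
  classes <- list(methylation = "2.1.1.6")
  tab_p <- capabilityTable(classes, m, "phylum")
  # reorder strains and re-tabulate
  ord <- rev(seq_along(strains(m)))
  m2 <- organismEnzymeMatrix(strains(m)[ord], ecSets(m)[ord],
                             taxonomy(m)[ord, ])
  tab_p2 <- capabilityTable(classes, m2, "phylum")
  expect_equal(tab_p, tab_p2)
  # strain-count-weighted genus means equal the phylum cells
  tab_g <- capabilityTable(classes, m, "genus")
  gen2phy <- tapply(taxonomy(m)$phylum, taxonomy(m)$genus,
                    function(x) unique(x))
  for (r in seq_len(nrow(tab_p))) {
    gg <- tab_g[gen2phy[tab_g$taxon] == tab_p$taxon[r], ]
    expect_equal(sum(gg$value * gg$n_strains) / sum(gg$n_strains),
                 tab_p$value[r])
    expect_equal(sum(gg$n_strains), tab_p$n_strains[r])
  }
  expect_error(capabilityTable(classes, m, "kingdom"), "unknown")
})

test_that("organism matrices survive a TSV round trip", {
  m <- genOrganismMatrix(55, n_strains = 8,
                         planted = list("5.5.1.6" = c(1L, 8L)))
  path <- tempfile(fileext = ".tsv")
  writeOrganismMatrix(m, path)
  m2 <- readOrganismMatrix(path)
  expect_identical(strains(m), strains(m2))
  expect_identical(ecSets(m), ecSets(m2))
  expect_identical(taxonomy(m)$genus, taxonomy(m2)$genus)
  expect_identical(capabilityTable(list(x = "5.5.1.6"), m, "phylum"),
                   capabilityTable(list(x = "5.5.1.6"), m2, "phylum"))
})
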