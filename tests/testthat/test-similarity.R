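apd <- function(feats, cap = 7) {
  structure(list(features = sort(unique(feats)), cap = as.integer(cap)),
            class = "AtomPairDescriptor")
}

test_that("atom-pair descriptors enumerate capped shortest-path features", {
  single <- molecularGraph(data.frame(index = 1L, element = "C",
                                      charge = 0L), NULL, perceive = TRUE)
  expect_length(atomPairDescriptor(single)$features, 0)
  two <- parseSmiles("CO")
  d2 <- atomPairDescriptor(two)
  expect_equal(d2$features, "C.alkyl|O.hydroxyl|1")
  # benzene, cap 3: one feature per distance 1..3 (brute-force APSP oracle)
  b <- parseSmiles("c1ccccc1")
  d3 <- atomPairDescriptor(b, cap = 3)
  expect_setequal(d3$features, sprintf("C.arom|C.arom|%d", 1:3))
  # cap cuts the enumeration: linear chain C8 has distances up to 7
  chain <- parseSmiles("CCCCCCCC")
  expect_setequal(atomPairDescriptor(chain, cap = 4)$features,
                  sprintf("C.alkyl|C.alkyl|%d", 1:4))
  # disconnected input is refused
  disc <- molecularGraph(data.frame(index = 1:2, element = "C",
                                    charge = 0L), NULL, perceive = TRUE)
  expect_error(atomPairDescriptor(disc), "disconnected")
})

test_that("tanimoto obeys range, symmetry and the set formula", {
  a <- apd(c("x", "y", "z")); b <- apd(c("y", "z", "w"))
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, apd(c("p", "q"))), 0)
  expect_equal(tanimoto(apd(character()), apd(character())), 1)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_error(tanimoto(a, apd("x", cap = 5)), "cap")
})

test_that("pairwise dissimilarity equals elementwise 1 - Tanimoto", {
  fx <- flavonoidFixtures()
  panel <- fx[c("benzene", "phenol", "catechol", "naringenin", "quercetin")]
  d <- pairwiseDissimilarity(panel)
  assertDissimilarity(d)
  desc <- lapply(panel, atomPairDescriptor, cap = 7)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], 1 - tanimoto(desc[[i]], desc[[j]]))
  }
  # duplicated item: off-diagonal zero; equal rows
  d2 <- pairwiseDissimilarity(list(a = fx$benzene, b = fx$phenol,
                                   c = fx$benzene))
  expect_equal(d2["a", "c"], 0)
  expect_equal(unname(d2["a", ]), unname(d2["c", ]))
})

test_that("single linkage reproduces hand agglomeration and the MST
           oracle", {
  d2 <- matrix(c(0, .3, .3, 0), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  h2 <- singleLinkage(d2)
  expect_equal(h2$height, .3)
  # 1-D points {0, 1, 10}: merges at 1 then 9 (scaled into [0,1] by /10)
  pts <- c(0, 1, 10) / 10
  d3 <- abs(outer(pts, pts, "-"))
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  h3 <- singleLinkage(d3)
  expect_equal(h3$height, c(.1, .9))
  set.seed(99)
  for (k in 1:200) {
    n <- sample(3:7, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
    m <- m + t(m)
    dimnames(m) <- list(paste0("i", 1:n), paste0("i", 1:n))
    h <- singleLinkage(m)
    expect_equal(sort(h$height), mst_weights(m), tolerance = 1e-12)
  }
})

test_that("co-clustering returns the query's component at the cut", {
  fx <- flavonoidFixtures()
  mk <- function(id, g) reactionPair(id, g, g, cbind(1L, 1L), "1.1.1.1")
  rpairs <- list(mk("dup_naringenin", fx$naringenin),
                 mk("near_eriodictyol", fx$eriodictyol),
                 mk("far_benzene", fx$benzene))
  # cut 0: only exact-descriptor duplicates of the query
  expect_equal(coclusterCandidates(fx$naringenin, rpairs, 0),
               "dup_naringenin")
  # cut 1: everything lands in one cluster
  expect_setequal(coclusterCandidates(fx$naringenin, rpairs, 1),
                  c("dup_naringenin", "near_eriodictyol", "far_benzene"))
  # intermediate cut: the planted near-duplicate joins, benzene stays out
  d <- pairwiseDissimilarity(list(q = fx$naringenin, e = fx$eriodictyol,
                                  b = fx$benzene))
  mid <- (d["q", "e"] + min(d["q", "b"], d["e", "b"])) / 2
  got <- coclusterCandidates(fx$naringenin, rpairs, mid)
  expect_true("near_eriodictyol" %in% got)
  expect_false("far_benzene" %in% got)
})

test_that("reaction-profile dissimilarity is 1 - Jaccard over operator
           sets", {
  prof <- list(a = c("op1", "op2"), b = c("op2", "op3"),
               c = c("op1", "op2"), d = c("op9"), e = character())
  d <- reactionProfileDissimilarity(prof)
  expect_equal(d["a", "b"], 1 - 1 / 3)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)
  expect_equal(d["e", "e"], 0)
  assertDissimilarity(d)
})

test_that("classical MDS embeds exact distances and flags impossible
           dimensions", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  emb0 <- classicalMds(z, 2)
  expect_true(all(emb0$coordinates == 0))
  # collinear points at 0, 3, 7: pairwise distances {3, 4, 7} recovered in 1-D
  x <- c(0, 3, 7)
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(paste0("p", 1:3), paste0("p", 1:3))
  e1 <- classicalMds(d, 1)
  got <- as.vector(dist(e1$coordinates))
  expect_equal(sort(got), c(3, 4, 7), tolerance = 1e-8)
  expect_error(classicalMds(d, 3), "exceeds")
  # 2-D recovery up to rigid motion
  set.seed(5)
  X <- matrix(rnorm(20 * 2), 20)
  D <- as.matrix(dist(X))
  emb <- classicalMds(D, 2)
  expect_lt(procrustes_rmsd(X, emb$coordinates), 1e-8)
})

test_that("dissimilarity correlation: exact limits, seeding, and null
           calibration", {
  set.seed(1)
  n <- 10
  a <- matrix(0, n, n); a[upper.tri(a)] <- runif(n * (n - 1) / 2)
  a <- a + t(a)
  dimnames(a) <- list(paste0("x", 1:n), paste0("x", 1:n))
  res_same <- dissimilarityCorrelation(a, a, permutations = 99, seed = 4)
  expect_equal(res_same$r, 1)
  expect_equal(res_same$slope, 1)
  flip <- 1 - a; diag(flip) <- 0
  res_flip <- dissimilarityCorrelation(a, flip, permutations = 99, seed = 4)
  expect_equal(res_flip$r, -1)
  b <- a[c(2, 1, 3:n), c(2, 1, 3:n)]
  expect_error(dissimilarityCorrelation(a, b, permutations = 99, seed = 4),
               "labels")
  # seeded runs are reproducible
  r1 <- dissimilarityCorrelation(a, flip, permutations = 199, seed = 7)
  r2 <- dissimilarityCorrelation(a, flip, permutations = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  # under the null (independent matrices), small p-values stay near the
  # nominal rate
  set.seed(11)
  pvals <- replicate(20, {
    m1 <- matrix(0, 8, 8); m1[upper.tri(m1)] <- runif(28); m1 <- m1 + t(m1)
    m2 <- matrix(0, 8, 8); m2[upper.tri(m2)] <- runif(28); m2 <- m2 + t(m2)
    dimnames(m1) <- dimnames(m2) <- list(paste0("i", 1:8), paste0("i", 1:8))
    dissimilarityCorrelation(m1, m2, permutations = 199,
                             seed = sample.int(1e6, 1))$p_value
  })
  expect_lte(mean(pvals < 0.05), 0.25)
  expect_gt(mean(pvals), 0.2)
})

test_that("dissimilarity matrices and dendrograms survive their exports", {
  fx <- flavonoidFixtures()
  d <- pairwiseDissimilarity(fx[c("benzene", "phenol", "catechol",
                                  "guaiacol")])
  path <- tempfile(fileext = ".tsv")
  writeDissimilarity(d, path)
  expect_equal(readDissimilarity(path), d, tolerance = 1e-12)
  h <- singleLinkage(d)
  out <- writeDendrogram(h, tempfile(), tempfile())
  expect_equal(out$merges$height, h$height)
  expect_match(out$newick, "benzene")
})
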