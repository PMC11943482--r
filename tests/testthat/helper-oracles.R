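# Independent oracles used across the suite. These deliberately avoid the
# package's own matching/canonicalisation code paths.

# all permutations of 1..n (n <= 8)
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) {
    for (k in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# brute-force labelled-graph isomorphism over all atom permutations
brute_isomorphic <- function(a, b) {
  na <- nrow(atoms(a)); nb <- nrow(atoms(b))
  if (na != nb || nrow(bonds(a)) != nrow(bonds(b))) return(FALSE)
  la <- paste(atoms(a)$atom_type, atoms(a)$charge)
  lb <- paste(atoms(b)$atom_type, atoms(b)$charge)
  if (!identical(sort(la), sort(lb))) return(FALSE)
  ia <- atoms(a)$index; ib <- atoms(b)$index
  eb <- bonds(b)
  bset_b <- paste(pmin(match(eb$a1, ib), match(eb$a2, ib)),
                  pmax(match(eb$a1, ib), match(eb$a2, ib)), eb$order)
  ea <- bonds(a)
  p1 <- match(ea$a1, ia); p2 <- match(ea$a2, ia)
  for (p in perms_of(na)) {   # p: position in a -> position in b
    if (!identical(la, lb[p])) next
    bset_a <- paste(pmin(p[p1], p[p2]), pmax(p[p1], p[p2]), ea$order)
    if (setequal(bset_a, bset_b)) return(TRUE)
  }
  FALSE
}

# sorted minimum-spanning-tree edge weights (Prim), the single-linkage
# merge-height oracle
mst_weights <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  w <- numeric(0)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    w <- c(w, best[v])
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  unname(sort(w))
}

# Gotoh affine-gap global alignment score (maximisation), Biostrings
# conventions: a gap of length L costs gapOpening + L * gapExtension
nw_score <- function(a, b, mat, gap_open = 10, gap_ext = 0.5) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  n <- length(sa); m <- length(sb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_ext
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[sa[i - 1], sb[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# random connected valence-safe molecular graph (tree + single bonds)
random_molgraph <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  els <- c("C", "C", "C", "N", "O")
  cap <- c(C = 4L, N = 3L, O = 2L)
  el <- sample(els, n, replace = TRUE)
  deg <- integer(n)
  b <- NULL
  for (i in seq_len(n)[-1]) {
    cands <- which(deg[seq_len(i - 1)] < cap[el[seq_len(i - 1)]])
    if (!length(cands)) { el[i] <- "C"; cands <- which(deg[seq_len(i - 1)] < 4) }
    j <- if (length(cands) == 1) cands else sample(cands, 1)
    b <- rbind(b, data.frame(a1 = j, a2 = i, order = "single"))
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
  }
  molecularGraph(data.frame(index = seq_len(n), element = el, charge = 0L),
                 b, name = sprintf("rand%d", n), perceive = TRUE)
}

# relabel a graph's atom indices by a permutation (new index = perm[position])
permute_atoms <- function(g, perm) {
  a <- atoms(g); b <- bonds(g)
  old <- a$index
  new_idx <- perm
  a$index <- new_idx[match(a$index, old)]
  b$a1 <- new_idx[match(b$a1, old)]
  b$a2 <- new_idx[match(b$a2, old)]
  a <- a[order(a$index), ]
  molecularGraph(a[, c("index", "element", "atom_type", "charge")], b,
                 name = g@name, normalize = FALSE)
}

# Procrustes-style RMSD after optimal rigid alignment (centering + SVD
# rotation/reflection, no scaling), independent of vegan
procrustes_rmsd <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  R <- s$u %*% t(s$v)
  D <- Yc - Xc %*% R
  sqrt(mean(rowSums(D^2)))
}
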