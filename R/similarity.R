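#' Atom-pair descriptor of a molecular graph
#'
#' Enumerates all unordered heavy-atom pairs with topological (shortest
#' path) distance between 1 and \code{cap} bonds and records the binary
#' presence of each (atom type, atom type, distance) feature, the type pair
#' ordered lexicographically. Binary presence rather than counts keeps the
#' descriptor reproducible across implementations; the cap (default 7
#' bonds) is configurable.
#'
#' @param g a connected \code{MolecularGraph}.
#' @param cap maximum topological distance (>= 1).
#' @return object of class \code{"AtomPairDescriptor"}: list with
#'   \code{features} (sorted character vector) and \code{cap}.
#' @export
atomPairDescriptor <- function(g, cap = 7) {
  stopifnot(cap >= 1)
  if (nrow(g@atoms) > 1) {
    comp <- .components(g)
    if (length(comp) > 1)
      stop("atom-pair descriptor undefined for a disconnected graph",
           call. = FALSE)
  }
  feats <- character()
  if (nrow(g@atoms) > 1) {
    d <- .topoDistances(g)
    idx <- as.integer(rownames(d))
    ty <- g@atoms$atom_type[match(idx, g@atoms$index)]
    n <- length(idx)
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    dd <- d[pairs]
    keep <- dd >= 1 & dd <= cap
    pairs <- pairs[keep, , drop = FALSE]; dd <- dd[keep]
    t1 <- ty[pairs[, 1]]; t2 <- ty[pairs[, 2]]
    feats <- sort(unique(sprintf("%s|%s|%d", pmin(t1, t2), pmax(t1, t2),
                                 as.integer(dd))))
  }
  structure(list(features = feats, cap = as.integer(cap)),
            class = "AtomPairDescriptor")
}

#' Tanimoto coefficient of two atom-pair descriptors
#'
#' Intersection over union of the binary feature sets; defined as 1 when
#' both sets are empty. Descriptors must share the same distance cap.
#'
#' @param a,b \code{AtomPairDescriptor} objects.
#' @return numeric in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "AtomPairDescriptor"),
            inherits(b, "AtomPairDescriptor"))
  if (a$cap != b$cap)
    stop("descriptors computed with different distance caps", call. = FALSE)
  u <- union(a$features, b$features)
  if (!length(u)) return(1)
  length(intersect(a$features, b$features)) / length(u)
}

#' Pairwise structural dissimilarity matrix
#'
#' Entry (i, j) is 1 minus the atom-pair Tanimoto coefficient of items i
#' and j; symmetric with zero diagonal. This is the built-in substitute for
#' an externally supplied structural dissimilarity matrix (any such matrix
#' can be passed to \code{\link{classicalMds}} directly).
#'
#' @param items named list of \code{MolecularGraph} (>= 2).
#' @param cap distance cap for \code{\link{atomPairDescriptor}}.
#' @return symmetric numeric matrix with item names as dimnames.
#' @export
pairwiseDissimilarity <- function(items, cap = 7) {
  stopifnot(length(items) >= 2)
  nms <- names(items)
  if (is.null(nms)) nms <- paste0("item", seq_along(items))
  desc <- lapply(items, atomPairDescriptor, cap = cap)
  n <- length(items)
  d <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - tanimoto(desc[[i]], desc[[j]])
  }
  d
}

#' Validate a dissimilarity matrix
#'
#' @param d numeric matrix; must be square, symmetric, zero-diagonal, with
#'   values in [0, 1] (within tolerance).
#' @return \code{d}, invisibly; errors otherwise.
#' @export
assertDissimilarity <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-12) stop("matrix is not symmetric")
  if (max(abs(diag(d))) > 1e-12) stop("diagonal is not zero")
  if (min(d) < -1e-12 || max(d) > 1 + 1e-12) stop("values outside [0, 1]")
  invisible(d)
}

#' Single-linkage clustering of a dissimilarity matrix
#'
#' Standard agglomeration where the distance between clusters is the
#' minimum pairwise dissimilarity; merge heights then equal the sorted
#' minimum-spanning-tree edge weights. Delegates to
#' \code{stats::hclust(method = "single")}.
#'
#' @param d symmetric dissimilarity matrix with labels as dimnames.
#' @return an \code{hclust} object.
#' @export
singleLinkage <- function(d) {
  assertDissimilarity(d)
  stats::hclust(stats::as.dist(d), method = "single")
}

#' Reaction pairs co-clustered with a query compound
#'
#' Computes atom-pair descriptors for the query and for the chosen side of
#' each reaction pair, and returns the ids of pairs falling in the query's
#' single-linkage cluster at the given cut height (clusters at cut h are
#' the connected components of the graph joining items with dissimilarity
#' <= h; cutting at 0 therefore returns exact-descriptor duplicates and
#' cutting at 1 returns everything). The visual inspection step that
#' follows in practice is out of scope: this is the candidate list.
#'
#' @param query a \code{MolecularGraph}.
#' @param rpairs list of \code{ReactionPair}.
#' @param cut_height numeric in [0, 1].
#' @param side which side of each pair to describe: \code{"reactant"}
#'   (default) or \code{"product"}.
#' @param cap descriptor distance cap.
#' @return character vector of reaction-pair ids (sorted).
#' @export
coclusterCandidates <- function(query, rpairs, cut_height,
                                side = c("reactant", "product"), cap = 7) {
  side <- match.arg(side)
  ids <- vapply(rpairs, function(rp) rp@id, character(1))
  graphs <- c(list(.query. = query),
              stats::setNames(lapply(rpairs, function(rp)
                if (side == "reactant") rp@reactant else rp@product), ids))
  d <- pairwiseDissimilarity(graphs, cap = cap)
  adj <- d <= cut_height + 1e-12
  n <- nrow(adj)
  # connected component containing the query
  seen <- c(TRUE, rep(FALSE, n - 1))
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  sort(setdiff(rownames(d)[seen], ".query."))
}

#' Reaction-profile dissimilarity
#'
#' Entry (i, j) is 1 minus the Jaccard index of the two items'
#' applicable-operator id sets (their predicted reaction patterns); two
#' empty profiles have dissimilarity 0.
#'
#' @param profiles named list: item -> character vector of operator ids.
#' @return symmetric numeric matrix.
#' @export
reactionProfileDissimilarity <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  nms <- names(profiles)
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    u <- union(profiles[[i]], profiles[[j]])
    jac <- if (!length(u)) 1
           else length(intersect(profiles[[i]], profiles[[j]])) / length(u)
    d[i, j] <- d[j, i] <- 1 - jac
  }
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering eigen-decomposition via \code{stats::cmdscale};
#' negative eigenvalues are truncated and coordinates are centered at the
#' origin. Requesting more dimensions than there are positive eigenvalues
#' is an error, except for an (all-zero) degenerate matrix, which embeds
#' every item at the origin.
#'
#' @param d symmetric dissimilarity/distance matrix.
#' @param dim embedding dimension (default 2).
#' @return list of class \code{"MdsEmbedding"}: \code{coordinates} (items
#'   by dim matrix) and \code{eigenvalues} (descending).
#' @export
classicalMds <- function(d, dim = 2) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), dim >= 1)
  n <- nrow(d)
  if (max(abs(d)) < 1e-12) {
    coords <- matrix(0, n, dim, dimnames = list(rownames(d), NULL))
    return(structure(list(coordinates = coords,
                          eigenvalues = rep(0, n - 1)),
                     class = "MdsEmbedding"))
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = min(dim, n - 1), eig = TRUE)
  npos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (dim > npos)
    stop(sprintf("dim = %d exceeds the %d positive eigenvalue(s)", dim,
                 npos), call. = FALSE)
  coords <- fit$points[, seq_len(dim), drop = FALSE]
  coords <- sweep(coords, 2, colMeans(coords))
  structure(list(coordinates = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE)),
            class = "MdsEmbedding")
}

#' Correlation between two dissimilarity matrices
#'
#' Pearson correlation over the strict upper triangles, a least-squares
#' linear fit (b on a), and a Mantel-style permutation p-value (labels of
#' one matrix permuted; delegated to \code{vegan::mantel}, seeded).
#'
#' @param a,b dissimilarity matrices with identical labels in identical
#'   order.
#' @param permutations number of Mantel permutations (default 9999).
#' @param seed mandatory RNG seed for the permutation test.
#' @return list: \code{r}, \code{slope}, \code{intercept}, \code{p_value},
#'   \code{permutations}.
#' @export
dissimilarityCorrelation <- function(a, b, permutations = 9999, seed) {
  if (missing(seed)) stop("seed is mandatory for the permutation test",
                          call. = FALSE)
  if (!identical(dimnames(a), dimnames(b)) || !identical(dim(a), dim(b)))
    stop("matrices must share labels and order", call. = FALSE)
  ua <- a[upper.tri(a)]; ub <- b[upper.tri(b)]
  r <- stats::cor(ua, ub)
  fit <- stats::lm(ub ~ ua)
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                      method = "pearson", permutations = permutations)
  list(r = r, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = mt$signif, permutations = permutations)
}

#' @export
print.MdsEmbedding <- function(x, ...) {
  cat("MdsEmbedding:", nrow(x$coordinates), "items in",
      ncol(x$coordinates), "dimensions\n")
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 4), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.AtomPairDescriptor <- function(x, ...) {
  cat("AtomPairDescriptor:", length(x$features), "features (cap",
      x$cap, "bonds)\n")
  invisible(x)
}

# ---- TSV / Newick exports -------------------------------------------------

#' Write a square dissimilarity matrix as TSV (and read it back)
#'
#' @param d matrix with dimnames.
#' @param path file path.
#' @return the path (write) or the matrix (read).
#' @export
writeDissimilarity <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDissimilarity
#' @export
readDissimilarity <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}

#' Export a dendrogram as a merge-list TSV and Newick string
#'
#' @param h an \code{hclust} object.
#' @param path_tsv,path_newick output paths (either may be NULL to skip).
#' @return invisibly, a list with the merge data.frame and the Newick
#'   string.
#' @export
writeDendrogram <- function(h, path_tsv = NULL, path_newick = NULL) {
  mg <- data.frame(step = seq_len(nrow(h$merge)),
                   a = h$merge[, 1], b = h$merge[, 2], height = h$height)
  nwk <- ape::write.tree(ape::as.phylo(h))
  if (!is.null(path_tsv))
    utils::write.table(mg, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_newick)) writeLines(nwk, path_newick)
  invisible(list(merges = mg, newick = nwk))
}
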